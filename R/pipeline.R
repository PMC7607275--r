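# One-shot pipeline driver: simulate (optional) -> DE -> qPCR (optional)
# -> enrichment -> ceRNA network, with a machine-readable manifest.

pipeline_defaults <- function() {
  list(
    outdir = "circnet_run",
    simulate = FALSE,
    seed = 1,
    # stage inputs (paths); ignored when simulate = TRUE
    expression = NULL, design = NULL, ct = NULL, gmt = NULL,
    gmt_category = "PATHWAY", target_circ = NULL, target_gene = NULL,
    target_universe = NULL, gene_map = NULL, candidates = NULL,
    # analysis parameters
    variant = "moderated", fc_threshold = 1.5, p_threshold = 0.05,
    adjust = "none", qpcr_reference = "GAPDH", qpcr_alpha = 0.01,
    enrich_p_cutoff = 0.05, enrich_adjust = "none",
    min_common = 1, cerna_p_cutoff = 0.05,
    network_formats = c("edge_tsv", "sif", "graphml"),
    # simulation sizes (simulate = TRUE)
    sim_n_probes = 2000, sim_de_fraction = 0.05, sim_n_case = 4,
    sim_n_control = 3, sim_noise_sd = 0.5, sim_log2fc_low = 1,
    sim_log2fc_high = 4, sim_n_terms = 200, sim_enriched_terms = 10,
    sim_enrich_boost = 0.5
  )
}

#' Read and validate a pipeline configuration
#'
#' Configuration is a flat YAML map; unknown keys are rejected, missing
#' keys take documented defaults (see the fields of the returned list).
#'
#' @param path YAML file path, or a named list of settings.
#' @return a complete, validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) {
    user <- list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  check_fraction(cfg$p_threshold, "p_threshold")
  check_fraction(cfg$enrich_p_cutoff, "enrich_p_cutoff")
  check_fraction(cfg$cerna_p_cutoff, "cerna_p_cutoff")
  check_fraction(cfg$qpcr_alpha, "qpcr_alpha")
  if (cfg$fc_threshold < 1) {
    stop("`fc_threshold` must be >= 1", call. = FALSE)
  }
  if (!cfg$variant %in% c("moderated", "welch", "pooled")) {
    stop("`variant` must be moderated, welch or pooled", call. = FALSE)
  }
  if (!cfg$adjust %in% c("none", "BH") ||
      !cfg$enrich_adjust %in% c("none", "BH")) {
    stop("`adjust` must be none or BH", call. = FALSE)
  }
  cfg$seed <- check_count(cfg$seed, "seed", min = 0)
  cfg
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[circnet] ", line)
  cat(line, "\n", file = state$log, sep = "", append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages for which inputs are available — differential
#' expression (quantile normalization, per-probe test, fold-change/p
#' filter, hierarchical ordering of the DE set), qRT-PCR relative
#' quantification, gene-set over-representation, and ceRNA pair screening
#' with network export — writing one TSV per stage plus a JSON manifest
#' (parameters, seed, input checksums) and a log into the run directory.
#' With `simulate = TRUE` all inputs are first generated with planted
#' ground truth (written alongside as `truth.tsv`).  Two runs with an
#' identical configuration produce byte-identical stage outputs.
#'
#' @param config a configuration list or YAML path
#'   (see [read_pipeline_config()]).
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list(log = file.path(outdir, "run.log"))
  cat("", file = state$log)
  truth <- list()

  if (isTRUE(cfg$simulate)) {
    indir <- file.path(outdir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    pipeline_log(state, "simulating inputs (seed %d)", cfg$seed)
    sim <- simulate_expression(cfg$sim_n_probes, cfg$sim_n_case,
                               cfg$sim_n_control, cfg$sim_de_fraction,
                               cfg$sim_log2fc_low, cfg$sim_log2fc_high,
                               cfg$sim_noise_sd, seed = cfg$seed)
    cfg$expression <- file.path(indir, "expression.tsv")
    cfg$design <- file.path(indir, "design.tsv")
    write_expression(sim$matrix, cfg$expression)
    write_design(sim$design, cfg$design)
    truth$de_probes <- sim$truth$de_probes

    planted <- head(sim$truth$de_probes, 4)
    if (length(planted) == 0) {
      planted <- c(validation_target_1 = 1.5)
    }
    ct <- simulate_ct_table(planted, reference_id = cfg$qpcr_reference,
                            n_case = cfg$sim_n_case,
                            n_control = cfg$sim_n_control,
                            seed = cfg$seed + 1)
    cfg$ct <- file.path(indir, "ct_table.tsv")
    write_ct_table(ct, cfg$ct)

    ann <- simulate_annotations(cfg$sim_n_terms,
                                universe = rownames(sim$matrix),
                                enriched_terms = cfg$sim_enriched_terms,
                                de_genes = names(sim$truth$de_probes),
                                enrich_boost = cfg$sim_enrich_boost,
                                category = cfg$gmt_category,
                                seed = cfg$seed + 2)
    cfg$gmt <- file.path(indir, "annotations.gmt")
    write_gmt(ann$annotations, cfg$gmt)
    truth$enriched_terms <- ann$truth$enriched_terms

    tm <- simulate_target_map(seed = cfg$seed + 3)
    cfg$target_circ <- file.path(indir, "circ_mirna.tsv")
    cfg$target_gene <- file.path(indir, "mirna_gene.tsv")
    cfg$target_universe <- file.path(indir, "mirna_universe.txt")
    write_target_map(tm$target_map, cfg$target_circ, cfg$target_gene,
                     cfg$target_universe)
    truth$planted_pairs <- tm$truth$planted_pairs
    write_sim_truth(truth, file.path(indir, "truth.tsv"))
  }

  outputs <- character(0)
  de <- NULL

  if (!is.null(cfg$expression) && !is.null(cfg$design)) {
    pipeline_log(state,
                 "DE stage: variant=%s fc_threshold=%g p_threshold=%g adjust=%s",
                 cfg$variant, cfg$fc_threshold, cfg$p_threshold, cfg$adjust)
    mat <- quantile_normalize(read_expression(cfg$expression))
    design <- read_design(cfg$design)
    fc <- group_log2fc(mat, design)
    fc$p_value <- unname(probe_test(mat, design, variant = cfg$variant))
    de <- call_de(fc, cfg$fc_threshold, cfg$p_threshold, cfg$adjust)
    f <- file.path(outdir, "de_table.tsv")
    write_de_table(de, f)
    outputs <- c(outputs, f)
    de_ids <- de$probe_id[de$direction != "none"]
    pipeline_log(state, "DE stage: %d up, %d down of %d probes",
                 sum(de$direction == "up"), sum(de$direction == "down"),
                 nrow(de))
    if (length(de_ids) >= 2) {
      ord <- hclust_order(mat[de_ids, , drop = FALSE])
      f <- file.path(outdir, "de_hclust_order.txt")
      writeLines(ord$order, f)
      outputs <- c(outputs, f)
    }
  }

  if (!is.null(cfg$ct)) {
    pipeline_log(state, "qPCR stage: reference=%s alpha=%g",
                 cfg$qpcr_reference, cfg$qpcr_alpha)
    ct <- read_ct_table(cfg$ct)
    rel <- relative_expression(collapse_replicates(ct), cfg$qpcr_reference)
    rel <- classify_validation(rel, alpha = cfg$qpcr_alpha)
    f <- file.path(outdir, "qpcr_results.tsv")
    write.table(format_numeric_cols(rel), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <- c(outputs, f)
  }

  if (!is.null(cfg$gmt) && !is.null(de)) {
    de_ids <- de$probe_id[de$direction != "none"]
    de_genes <- if (!is.null(cfg$gene_map)) {
      gm <- read.delim(cfg$gene_map, stringsAsFactors = FALSE,
                       colClasses = "character")
      unique(gm[[2]][gm[[1]] %in% de_ids])
    } else {
      de_ids
    }
    if (length(de_genes)) {
      pipeline_log(state, "enrichment stage: %d DE genes, p_cutoff=%g",
                   length(de_genes), cfg$enrich_p_cutoff)
      ann <- read_gmt(cfg$gmt, category = cfg$gmt_category)
      enr <- enrich_terms(de_genes, ann, p_cutoff = cfg$enrich_p_cutoff,
                          adjust = cfg$enrich_adjust)
      f <- file.path(outdir, "enrichment.tsv")
      write.table(format_numeric_cols(enr), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs <- c(outputs, f)
    } else {
      pipeline_log(state, "enrichment stage skipped: no DE genes")
    }
  }

  if (!is.null(cfg$target_circ) && !is.null(cfg$target_gene)) {
    map <- read_target_map(cfg$target_circ, cfg$target_gene,
                           cfg$target_universe)
    candidates <- if (!is.null(cfg$candidates)) {
      x <- readLines(cfg$candidates)
      x[nzchar(x)]
    } else {
      names(map$circ_to_mirna)
    }
    pipeline_log(state,
                 "ceRNA stage: %d candidates, min_common=%d, p_cutoff=%g",
                 length(candidates), cfg$min_common, cfg$cerna_p_cutoff)
    pairs <- screen_cerna_pairs(map, candidates, cfg$min_common,
                                cfg$cerna_p_cutoff)
    ptab <- pairs[, c("id_a", "id_b", "N", "K", "n", "c", "p_value")]
    f <- file.path(outdir, "cerna_pairs.tsv")
    write.table(format_numeric_cols(ptab), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs <- c(outputs, f)
    net <- build_cerna_network(pairs, map)
    assert_tripartite(net)
    pipeline_log(state, "ceRNA stage: %d pairs retained; network %d/%d/%d",
                 nrow(pairs), sum(net$nodes$kind == "circRNA"),
                 sum(net$nodes$kind == "miRNA"),
                 sum(net$nodes$kind == "gene"))
    ext <- c(edge_tsv = "edges.tsv", sif = "network.sif",
             graphml = "network.graphml")
    for (fmt in cfg$network_formats) {
      f <- file.path(outdir, ext[[fmt]])
      export_network(net, f, format = fmt)
      outputs <- c(outputs, f)
    }
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("expression", "design", "ct", "gmt", "target_circ",
                         "target_gene", "target_universe", "gene_map",
                         "candidates")])
  manifest <- list(
    package = "circnet",
    parameters = cfg[setdiff(names(cfg), "outdir")],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  pipeline_log(state, "run complete: %d output files", length(outputs))
  invisible(outdir)
}
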