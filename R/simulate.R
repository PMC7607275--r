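#' Simulate a two-group circRNA microarray intensity matrix
#'
#' Generates log-normal probe intensities for a small two-group plasma
#' microarray design with a planted fraction of truly differential probes.
#' Per-probe baseline log2 intensity is drawn uniformly from \[6, 14\]
#' (typical array dynamic range); a fraction `de_fraction` of probes carry
#' a planted log2 fold change of magnitude uniform in
#' \[`log2fc_low`, `log2fc_high`\] with a random sign, applied to the case
#' group; Gaussian noise of sd `noise_sd` is added on the log2 scale and
#' intensities are returned as `2^log2value`, guaranteeing positivity.
#'
#' Defaults reflect the profiled study conditions: 4 case vs 3 control
#' samples, 5% differential probes, planted magnitudes spanning the fold
#' changes typically reported for plasma circRNA arrays, and a between-
#' subject log2 noise sd of 0.5.
#'
#' @param n_probes number of probes.
#' @param n_case,n_control samples per group (each must be >= 2 so that
#'   downstream per-probe tests are defined).
#' @param de_fraction fraction of probes with a planted effect, in \[0, 1\].
#' @param log2fc_low,log2fc_high bounds of the planted |log2 fold change|;
#'   `log2fc_low` must be > 0 when any probe is planted.
#' @param noise_sd log2-scale noise standard deviation (> 0).
#' @param seed integer seed; same parameters + seed give bit-identical
#'   output.
#' @return list with elements `matrix` (probe-by-sample intensity matrix),
#'   `design` (data frame `sample_id`, `group`), and `truth` (list with
#'   `de_probes`, a named numeric vector of planted log2 fold changes).
#' @export
simulate_expression <- function(n_probes, n_case = 4, n_control = 3,
                                de_fraction = 0.05, log2fc_low = 1,
                                log2fc_high = 4, noise_sd = 0.5, seed = 1) {
  n_probes <- check_count(n_probes, "n_probes")
  n_case <- check_count(n_case, "n_case", min = 2)
  n_control <- check_count(n_control, "n_control", min = 2)
  de_fraction <- check_fraction(de_fraction, "de_fraction")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be a positive number", call. = FALSE)
  }
  if (log2fc_low > log2fc_high) {
    stop("`log2fc_low` must not exceed `log2fc_high`", call. = FALSE)
  }
  n_de <- round(n_probes * de_fraction)
  if (n_de > 0 && log2fc_low <= 0) {
    stop("`log2fc_low` must be > 0 when probes are planted", call. = FALSE)
  }

  probe_ids <- sprintf("probe_%06d", seq_len(n_probes))
  sample_ids <- c(sprintf("case_%d", seq_len(n_case)),
                  sprintf("ctrl_%d", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))

  with_seed(seed, {
    baseline <- runif(n_probes, 6, 14)
    de_idx <- sort(sample.int(n_probes, n_de))
    lfc <- numeric(0)
    effect <- numeric(n_probes)
    if (n_de > 0) {
      lfc <- runif(n_de, log2fc_low, log2fc_high) *
        sample(c(-1, 1), n_de, replace = TRUE)
      effect[de_idx] <- lfc
    }
    log2m <- matrix(baseline, n_probes, n_case + n_control)
    log2m[, seq_len(n_case)] <- log2m[, seq_len(n_case)] + effect
    log2m <- log2m + matrix(rnorm(length(log2m), sd = noise_sd),
                            nrow(log2m), ncol(log2m))
    mat <- 2^log2m
    dimnames(mat) <- list(probe_ids, sample_ids)
    list(matrix = mat,
         design = data.frame(sample_id = sample_ids, group = group,
                             stringsAsFactors = FALSE),
         truth = list(de_probes = setNames(lfc, probe_ids[de_idx])))
  })
}

#' Simulate a technical-replicate qRT-PCR Ct table
#'
#' Builds a Ct table for a set of target transcripts plus one reference
#' gene so that, with `ct_noise_sd = 0`, the case-minus-control difference
#' of mean delta-Ct for each target equals exactly minus the planted log2
#' fold change; the downstream 2^-ddCt analysis then recovers the planted
#' fold change exactly.  Each sample gets a random loading shift applied
#' to all its wells (reference included), which the delta-Ct subtraction
#' cancels.
#'
#' @param targets named numeric vector: target ids -> planted log2 fold
#'   change (case over control).
#' @param reference_id reference (housekeeping) gene id; must not appear
#'   among the targets.
#' @param n_case,n_control samples per group.
#' @param n_replicates technical replicates per well (>= 1; assays are
#'   conventionally run in triplicate).
#' @param ct_noise_sd per-replicate Ct noise sd in cycles (>= 0).
#' @param seed integer seed.
#' @return data frame with columns `sample_id`, `group`, `target_id`,
#'   `replicate`, `ct`.
#' @export
simulate_ct_table <- function(targets, reference_id = "GAPDH", n_case = 4,
                              n_control = 3, n_replicates = 3,
                              ct_noise_sd = 0.25, seed = 1) {
  if (length(targets) == 0 || is.null(names(targets)) ||
      any(!nzchar(names(targets)))) {
    stop("`targets` must be a named numeric vector of planted log2 fold changes",
         call. = FALSE)
  }
  if (reference_id %in% names(targets)) {
    stop("`reference_id` must not be among the targets", call. = FALSE)
  }
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (!is.numeric(ct_noise_sd) || ct_noise_sd < 0) {
    stop("`ct_noise_sd` must be non-negative", call. = FALSE)
  }

  sample_ids <- c(sprintf("case_%d", seq_len(n_case)),
                  sprintf("ctrl_%d", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  target_ids <- c(reference_id, names(targets))
  lfc <- c(0, unname(targets))            # reference carries no effect
  ref_ct <- 18                            # abundant housekeeping transcript

  with_seed(seed, {
    base_ct <- c(ref_ct, runif(length(targets), 22, 28))
    shift <- runif(length(sample_ids), -1, 1)
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        target = seq_along(target_ids),
                        sample = seq_along(sample_ids))
    is_case <- group[grid$sample] == "case"
    ct <- base_ct[grid$target] + shift[grid$sample] -
      ifelse(is_case, lfc[grid$target], 0)
    if (ct_noise_sd > 0) {
      ct <- ct + rnorm(length(ct), sd = ct_noise_sd)
    }
    data.frame(sample_id = sample_ids[grid$sample],
               group = group[grid$sample],
               target_id = target_ids[grid$target],
               replicate = grid$replicate,
               ct = ct,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-layer miRNA target map with planted ceRNA pairs
#'
#' Generates circRNA -> miRNA-response-element (MRE) sets drawn uniformly
#' without replacement from a miRNA universe, plants `planted_pairs`
#' circRNA pairs that share a forced core of `planted_overlap` miRNAs
#' (remaining slots filled independently), and assigns every miRNA that
#' appears in any MRE set at least one downstream gene target.
#'
#' Defaults describe a screening scenario of 200 candidate circRNAs with
#' 5 MREs each against a prediction universe of 10,000 miRNAs, with 20
#' planted pairs of fully shared MRE sets.
#'
#' @param n_circ number of circRNAs (candidate transcripts).
#' @param n_mirna size of the miRNA universe used for target prediction.
#' @param n_gene size of the downstream gene pool.
#' @param mre_per_circ MRE-set size per circRNA (<= `n_mirna`).
#' @param planted_pairs number of planted ceRNA pairs (>= 0; uses the
#'   first `2 * planted_pairs` circRNAs).
#' @param planted_overlap forced shared-miRNA count per planted pair
#'   (<= `mre_per_circ`).
#' @param seed integer seed.
#' @return list with `target_map` (see [read_target_map()] for the
#'   structure: `circ_to_mirna`, `mirna_to_gene`, `mirna_universe`) and
#'   `truth` (list with `planted_pairs`, a data frame `id_a`, `id_b`,
#'   `overlap`).
#' @export
simulate_target_map <- function(n_circ = 200, n_mirna = 10000, n_gene = 500,
                                mre_per_circ = 5, planted_pairs = 20,
                                planted_overlap = 5, seed = 1) {
  n_circ <- check_count(n_circ, "n_circ")
  n_mirna <- check_count(n_mirna, "n_mirna")
  n_gene <- check_count(n_gene, "n_gene")
  mre_per_circ <- check_count(mre_per_circ, "mre_per_circ")
  planted_pairs <- check_count(planted_pairs, "planted_pairs", min = 0)
  planted_overlap <- check_count(planted_overlap, "planted_overlap")
  if (planted_overlap > mre_per_circ) {
    stop("`planted_overlap` must not exceed `mre_per_circ`", call. = FALSE)
  }
  if (mre_per_circ > n_mirna) {
    stop("`mre_per_circ` must not exceed `n_mirna`", call. = FALSE)
  }
  if (2 * planted_pairs > n_circ) {
    stop("need `n_circ` >= 2 * `planted_pairs`", call. = FALSE)
  }

  circ_ids <- sprintf("circ_%04d", seq_len(n_circ))
  universe <- sprintf("miR_%05d", seq_len(n_mirna))
  gene_ids <- sprintf("gene_%04d", seq_len(n_gene))

  with_seed(seed, {
    sets <- vector("list", n_circ)
    names(sets) <- circ_ids
    k <- 0L
    if (planted_pairs > 0) {
      for (p in seq_len(planted_pairs)) {
        core <- sample(universe, planted_overlap)
        rest <- setdiff(universe, core)
        n_fill <- mre_per_circ - planted_overlap
        sets[[k + 1L]] <- c(core, if (n_fill > 0) sample(rest, n_fill))
        sets[[k + 2L]] <- c(core, if (n_fill > 0) sample(rest, n_fill))
        k <- k + 2L
      }
    }
    for (i in seq_len(n_circ - k)) {
      sets[[k + i]] <- sample(universe, mre_per_circ)
    }
    used <- sort(unique(unlist(sets, use.names = FALSE)))
    n_targets <- sample(1:3, length(used), replace = TRUE)
    mirna_to_gene <- lapply(n_targets, function(m) sample(gene_ids, m))
    names(mirna_to_gene) <- used

    truth_pairs <- if (planted_pairs > 0) {
      data.frame(id_a = circ_ids[seq(1, 2 * planted_pairs, by = 2)],
                 id_b = circ_ids[seq(2, 2 * planted_pairs, by = 2)],
                 overlap = planted_overlap,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id_a = character(0), id_b = character(0),
                 overlap = integer(0), stringsAsFactors = FALSE)
    }
    list(target_map = target_map(sets, mirna_to_gene, universe),
         truth = list(planted_pairs = truth_pairs))
  })
}

#' Simulate gene-set annotations with planted enriched terms
#'
#' Draws `n_terms` gene sets of size uniform in
#' \[`term_size_low`, `term_size_high`\] from `universe`.  The first
#' `enriched_terms` terms draw a fraction `enrich_boost` of their members
#' from `de_genes` (the differential gene list) and the remainder from the
#' rest of the universe; all other terms are sampled uniformly, so their
#' over-representation p-values are null.
#'
#' @param n_terms number of terms to generate.
#' @param universe character vector of gene ids (the annotation universe).
#' @param term_size_low,term_size_high bounds on term size (inclusive).
#' @param enriched_terms number of planted enriched terms (>= 0).
#' @param de_genes character vector of differential gene ids; must be a
#'   subset of `universe`.
#' @param enrich_boost fraction of an enriched term's members drawn from
#'   `de_genes`, in \[0, 1\].
#' @param category gene-set category label (`"BP"`, `"CC"`, `"MF"` or
#'   `"PATHWAY"`) applied to all generated terms.
#' @param seed integer seed.
#' @return list with `annotations` (annotation collection; data frame with
#'   columns `term_id`, `term_name`, `category` and list-column `genes`)
#'   and `truth` (list with `enriched_terms`, a character vector).
#' @export
simulate_annotations <- function(n_terms, universe, term_size_low = 20,
                                 term_size_high = 100, enriched_terms = 0,
                                 de_genes = character(0), enrich_boost = 0.5,
                                 category = "BP", seed = 1) {
  n_terms <- check_count(n_terms, "n_terms")
  term_size_low <- check_count(term_size_low, "term_size_low")
  term_size_high <- check_count(term_size_high, "term_size_high")
  enriched_terms <- check_count(enriched_terms, "enriched_terms", min = 0)
  enrich_boost <- check_fraction(enrich_boost, "enrich_boost")
  if (term_size_low > term_size_high) {
    stop("`term_size_low` must not exceed `term_size_high`", call. = FALSE)
  }
  if (term_size_high > length(universe)) {
    stop("term sizes must not exceed the universe size", call. = FALSE)
  }
  if (!all(de_genes %in% universe)) {
    stop("`de_genes` must be a subset of `universe`", call. = FALSE)
  }
  if (enriched_terms > n_terms) {
    stop("`enriched_terms` must not exceed `n_terms`", call. = FALSE)
  }

  term_ids <- sprintf("term_%04d", seq_len(n_terms))
  with_seed(seed, {
    sizes <- if (term_size_low == term_size_high) {
      rep(term_size_low, n_terms)
    } else {
      sample(term_size_low:term_size_high, n_terms, replace = TRUE)
    }
    genes <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      if (i <= enriched_terms) {
        n_hit <- min(round(enrich_boost * sizes[i]), length(de_genes))
        hit <- if (n_hit > 0) sample(de_genes, n_hit) else character(0)
        pool <- setdiff(universe, hit)
        genes[[i]] <- c(hit, sample(pool, sizes[i] - n_hit))
      } else {
        genes[[i]] <- sample(universe, sizes[i])
      }
    }
    ann <- annotation_collection(term_ids,
                                 term_name = paste("synthetic term", term_ids),
                                 category = category, genes = genes)
    list(annotations = ann,
         truth = list(enriched_terms = term_ids[seq_len(enriched_terms)]))
  })
}

#' Write planted ground truth to a TSV file
#'
#' Serializes the `truth` component of any simulator to a three-column
#' table (`entity_id`, `truth_kind`, `planted_value`) so a pipeline run
#' can carry its ground truth alongside the generated inputs.
#'
#' @param truth a `truth` list as returned by the `simulate_*` generators.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  rows <- list()
  if (!is.null(truth$de_probes) && length(truth$de_probes)) {
    rows[[length(rows) + 1L]] <-
      data.frame(entity_id = names(truth$de_probes), truth_kind = "log2fc",
                 planted_value = unname(truth$de_probes),
                 stringsAsFactors = FALSE)
  }
  if (!is.null(truth$enriched_terms) && length(truth$enriched_terms)) {
    rows[[length(rows) + 1L]] <-
      data.frame(entity_id = truth$enriched_terms, truth_kind = "enriched_term",
                 planted_value = 1, stringsAsFactors = FALSE)
  }
  if (!is.null(truth$planted_pairs) && nrow(truth$planted_pairs)) {
    pp <- truth$planted_pairs
    rows[[length(rows) + 1L]] <-
      data.frame(entity_id = paste(pp$id_a, pp$id_b, sep = "|"),
                 truth_kind = "cerna_pair", planted_value = pp$overlap,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(entity_id = character(0), truth_kind = character(0),
               planted_value = numeric(0), stringsAsFactors = FALSE)
  }
  write.table(format_numeric_cols(out), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
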