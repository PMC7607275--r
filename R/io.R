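# Readers and writers for the tab-separated formats the pipeline touches.
# Every reader validates the invariants of its type and reports the file
# and line of the first offending record; every writer/reader pair
# round-trips.  Floats are serialized with 12 significant digits.

stop_at_line <- function(path, line, msg) {
  stop(sprintf("%s (%s, line %d)", msg, path, line), call. = FALSE)
}

#' Read a probe-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids with `probe_id` as the first
#' column.
#'
#' @param path TSV file path.
#' @return numeric matrix with probe row names and sample column names.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "probe_id") {
    stop(sprintf("%s: expected a probe_id column followed by sample columns",
                 path), call. = FALSE)
  }
  dup <- which(duplicated(df$probe_id))
  if (length(dup)) {
    stop_at_line(path, dup[1] + 1L,
                 sprintf("duplicate probe id '%s'", df$probe_id[dup[1]]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop(sprintf("%s: non-numeric intensity values", path), call. = FALSE)
  }
  rownames(m) <- df$probe_id
  validate_expression(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param matrix expression matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  df <- data.frame(probe_id = rownames(matrix),
                   formatC(matrix, digits = 12, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-group sample design from TSV
#'
#' @param path TSV with columns `sample_id`, `group` (case/control).
#' @return design data frame.
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop(sprintf("%s: expected columns sample_id, group", path),
         call. = FALSE)
  }
  dup <- which(duplicated(df$sample_id))
  if (length(dup)) {
    stop_at_line(path, dup[1] + 1L,
                 sprintf("duplicate sample id '%s'", df$sample_id[dup[1]]))
  }
  validate_design(df)
  df
}

#' Write a sample design to TSV
#' @param design design data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  write.table(design[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a technical-replicate Ct table from TSV
#'
#' @param path TSV with columns `sample_id`, `group`, `target_id`,
#'   `replicate`, `ct` (empty or NA ct marks a failed well).
#' @return Ct table data frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "target_id", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(df$ct)) {
    bad <- which(!is.na(df$ct) & is.na(suppressWarnings(as.numeric(df$ct))))
    if (length(bad)) {
      stop_at_line(path, bad[1] + 1L, "non-numeric Ct value")
    }
    df$ct <- as.numeric(df$ct)
  }
  df
}

#' Write a Ct table to TSV
#' @param table Ct table data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ct_table <- function(table, path) {
  write.table(format_numeric_cols(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Standard GMT dialect: one term per line,
#' `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path.
#' @param category category label assigned to every term in the file
#'   (GMT itself carries none); one of `BP`, `CC`, `MF`, `PATHWAY`.
#' @return an [annotation_collection()].
#' @export
read_gmt <- function(path, category = "PATHWAY") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop_at_line(path, short[1],
                 "GMT line needs term, description and >= 1 gene")
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop_at_line(path, dup[1], sprintf("duplicate term id '%s'", ids[dup[1]]))
  }
  annotation_collection(
    term_id = ids,
    term_name = vapply(parts, `[[`, character(1), 2),
    category = category,
    genes = lapply(parts, function(x) x[-(1:2)]))
}

#' Write an annotation collection to GMT
#' @param annotations an [annotation_collection()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_collection"))
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    paste(c(annotations$term_id[i], annotations$term_name[i],
            annotations$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-layer target map from TSV files
#'
#' @param circ_path TSV with columns `circRNA_id`, `miRNA_id` (one
#'   predicted MRE per row).
#' @param gene_path TSV with columns `miRNA_id`, `gene_id`.
#' @param universe_path optional file with one miRNA id per line — the
#'   full prediction universe (the `N` of the pair test).  When omitted,
#'   the universe defaults to the miRNAs observed in the two maps, which
#'   understates `N` if prediction covered more miRNAs; a message notes
#'   this.
#' @return a [target_map()].
#' @export
read_target_map <- function(circ_path, gene_path, universe_path = NULL) {
  cm <- read.delim(circ_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("circRNA_id", "miRNA_id") %in% names(cm))) {
    stop(sprintf("%s: expected columns circRNA_id, miRNA_id", circ_path),
         call. = FALSE)
  }
  mg <- read.delim(gene_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("miRNA_id", "gene_id") %in% names(mg))) {
    stop(sprintf("%s: expected columns miRNA_id, gene_id", gene_path),
         call. = FALSE)
  }
  circ_to_mirna <- lapply(split(cm$miRNA_id, cm$circRNA_id), unique)
  mirna_to_gene <- lapply(split(mg$gene_id, mg$miRNA_id), unique)
  universe <- if (!is.null(universe_path)) {
    u <- readLines(universe_path)
    u[nzchar(u)]
  } else {
    message("no universe file supplied; using observed miRNAs as universe")
    unique(c(cm$miRNA_id, mg$miRNA_id))
  }
  target_map(circ_to_mirna, mirna_to_gene, universe)
}

#' Write a target map to TSV files
#'
#' @param map a [target_map()].
#' @param circ_path,gene_path,universe_path output paths for the
#'   circRNA-miRNA pairs, miRNA-gene pairs and miRNA universe.
#' @return invisibly, the three paths.
#' @export
write_target_map <- function(map, circ_path, gene_path, universe_path) {
  stopifnot(inherits(map, "target_map"))
  cm <- data.frame(
    circRNA_id = rep(names(map$circ_to_mirna), lengths(map$circ_to_mirna)),
    miRNA_id = unlist(map$circ_to_mirna, use.names = FALSE),
    stringsAsFactors = FALSE)
  mg <- data.frame(
    miRNA_id = rep(names(map$mirna_to_gene), lengths(map$mirna_to_gene)),
    gene_id = unlist(map$mirna_to_gene, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(cm, circ_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mg, gene_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(map$mirna_universe, universe_path)
  invisible(c(circ_path, gene_path, universe_path))
}

#' Write a differential-expression table to TSV
#'
#' Columns `probe_id`, `log2fc`, `fc_abs`, `p_value`, `adj_p`,
#' `regulation` — the analytic columns of a published DE circRNA table.
#'
#' @param de data frame from [call_de()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(probe_id = de$probe_id, log2fc = de$log2fc,
                    fc_abs = de$fc_abs, p_value = de$p_value,
                    adj_p = de$adj_p, regulation = de$direction,
                    stringsAsFactors = FALSE)
  write.table(format_numeric_cols(out), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Published top differentially expressed plasma circRNAs
#'
#' The bundled example table of the 10 most upregulated and 10 most
#' downregulated circRNAs from a plasma circRNA microarray profile of
#' migraine patients vs healthy controls, with per-probe p-value,
#' absolute fold change, regulation direction, host gene symbol and the
#' top five predicted miRNA response elements.  `log2fc` is reconstructed
#' from the printed absolute fold change and direction.
#'
#' @return data frame with columns `circRNA`, `alias`, `chrom`,
#'   `p_value`, `fc_abs`, `log2fc`, `regulation`, `circRNA_type`,
#'   `gene_symbol`, `MRE1`..`MRE5`.
#' @export
top_circrnas <- function() {
  path <- system.file("extdata", "top_circrnas.tsv", package = "circnet",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$log2fc <- ifelse(df$regulation == "Up", 1, -1) * log2(df$fc_abs)
  df[, c("circRNA", "alias", "chrom", "p_value", "fc_abs", "log2fc",
         "regulation", "circRNA_type", "gene_symbol",
         paste0("MRE", 1:5))]
}

#' Read a differential-expression table from TSV
#' @param path TSV written by [write_de_table()].
#' @return data frame with the DE-table columns.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "log2fc", "fc_abs", "p_value", "regulation")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}
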