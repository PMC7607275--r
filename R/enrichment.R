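#' Construct an annotation collection
#'
#' A light container for gene-set annotations: a data frame with columns
#' `term_id`, `term_name`, `category` (one of `BP`, `CC`, `MF`,
#' `PATHWAY`) and a list-column `genes` of character vectors.
#'
#' @param term_id unique term identifiers.
#' @param term_name human-readable term names.
#' @param category per-term category (recycled if length 1).
#' @param genes list of character vectors of member gene ids (non-empty).
#' @return an `annotation_collection` data frame.
#' @export
annotation_collection <- function(term_id, term_name = term_id,
                                  category = "BP", genes) {
  if (anyDuplicated(term_id)) {
    stop("duplicate term ids", call. = FALSE)
  }
  if (length(genes) != length(term_id)) {
    stop("`genes` must have one entry per term", call. = FALSE)
  }
  if (any(lengths(genes) == 0)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  category <- rep_len(as.character(category), length(term_id))
  bad <- setdiff(unique(category), c("BP", "CC", "MF", "PATHWAY"))
  if (length(bad)) {
    stop(sprintf("unknown category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(term_id = as.character(term_id),
                    term_name = rep_len(as.character(term_name),
                                        length(term_id)),
                    category = category, stringsAsFactors = FALSE)
  out$genes <- lapply(genes, as.character)
  class(out) <- c("annotation_collection", "data.frame")
  out
}

#' Enrichment factor of a gene set
#'
#' The ratio of differential genes found in a term to the term's size,
#' `k / M` — the quantity plotted on the x axis of enrichment dot plots.
#'
#' @param k number of differential genes in the term (0 <= k <= M).
#' @param M term size within the universe (> 0).
#' @return `k / M`.
#' @export
enrichment_factor <- function(k, M) {
  if (any(M <= 0)) {
    stop("`M` must be positive", call. = FALSE)
  }
  if (any(k < 0 | k > M)) {
    stop("need 0 <= k <= M", call. = FALSE)
  }
  k / M
}

#' Gene-set over-representation analysis
#'
#' Tests each annotation term for over-representation of a differential
#' gene list against a gene universe.  With `N_u` universe genes, `M` of
#' them in the term, and `n` differential genes of which `k` fall in the
#' term, the p-value is the one-sided hypergeometric upper tail
#' `P(X >= k)`, identical to the one-sided Fisher exact test of the
#' corresponding 2x2 table.  Terms with p (or BH-adjusted p when
#' `adjust = "BH"`) at or below `p_cutoff` are retained, sorted by
#' ascending p with ties broken by term id.
#'
#' @param de_genes character vector of differential gene ids (non-empty,
#'   a subset of the universe).
#' @param annotations an [annotation_collection()].
#' @param universe character vector of background gene ids; defaults to
#'   the union of all genes in `annotations`.
#' @param p_cutoff retention cutoff on the p-value (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame `term_id`, `term_name`, `category`, `k`, `M`, `n`,
#'   `N_u`, `p_value`, `adj_p`, `enrichment_factor`, one row per retained
#'   term.
#' @export
enrich_terms <- function(de_genes, annotations, universe = NULL,
                         p_cutoff = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!inherits(annotations, "annotation_collection")) {
    stop("`annotations` must be an annotation_collection", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(annotations$genes, use.names = FALSE)))
  }
  universe <- unique(as.character(universe))
  de_genes <- unique(as.character(de_genes))
  if (length(universe) == 0) {
    stop("empty universe", call. = FALSE)
  }
  if (length(de_genes) == 0) {
    stop("empty differential gene list", call. = FALSE)
  }
  if (!all(de_genes %in% universe)) {
    stop("`de_genes` must be a subset of the universe", call. = FALSE)
  }
  p_cutoff <- check_fraction(p_cutoff, "p_cutoff")

  N_u <- length(universe)
  n <- length(de_genes)
  term_genes <- lapply(annotations$genes, function(g) {
    intersect(unique(g), universe)
  })
  M <- lengths(term_genes)
  k <- vapply(term_genes, function(g) sum(g %in% de_genes), integer(1))
  keep <- M > 0
  p <- rep(1, length(M))
  p[keep] <- phyper(k[keep] - 1, M[keep], N_u - M[keep], n,
                    lower.tail = FALSE)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  adj_p <- if (adjust == "BH") p.adjust(p, method = "BH")
           else rep(NA_real_, length(p))

  out <- data.frame(term_id = annotations$term_id,
                    term_name = annotations$term_name,
                    category = annotations$category,
                    k = k, M = M, n = n, N_u = N_u,
                    p_value = p, adj_p = adj_p,
                    enrichment_factor = ifelse(M > 0, k / M, NA_real_),
                    stringsAsFactors = FALSE)
  gate <- if (adjust == "BH") out$adj_p else out$p_value
  out <- out[keep & gate <= p_cutoff, ]
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
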