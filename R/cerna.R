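#' Construct a two-layer miRNA target map
#'
#' Holds the predicted interaction sets consumed by ceRNA screening:
#' circRNA -> miRNA-response-element (MRE) sets, miRNA -> downstream gene
#' targets, and the full miRNA universe used for prediction (the `N` of
#' the pair test — the total number of miRNAs used to predict targets,
#' not merely those observed in MRE sets).
#'
#' @param circ_to_mirna named list: circRNA id -> character vector of
#'   miRNA ids (its MREs).
#' @param mirna_to_gene named list: miRNA id -> character vector of gene
#'   ids it targets.
#' @param mirna_universe character vector of all miRNA ids used for
#'   prediction; every miRNA referenced in the two maps must be in it.
#' @return a `target_map` object.
#' @export
target_map <- function(circ_to_mirna, mirna_to_gene, mirna_universe) {
  mirna_universe <- unique(as.character(mirna_universe))
  if (length(circ_to_mirna) && is.null(names(circ_to_mirna))) {
    stop("`circ_to_mirna` must be a named list", call. = FALSE)
  }
  if (length(mirna_to_gene) && is.null(names(mirna_to_gene))) {
    stop("`mirna_to_gene` must be a named list", call. = FALSE)
  }
  used <- unique(c(unlist(circ_to_mirna, use.names = FALSE),
                   names(mirna_to_gene)))
  if (!all(used %in% mirna_universe)) {
    stop("all referenced miRNAs must be in `mirna_universe`", call. = FALSE)
  }
  structure(list(circ_to_mirna = lapply(circ_to_mirna, as.character),
                 mirna_to_gene = lapply(mirna_to_gene, as.character),
                 mirna_universe = mirna_universe),
            class = "target_map")
}

#' Hypergeometric significance of a candidate ceRNA pair
#'
#' The shared-miRNA test for a candidate ceRNA pair: given `N` miRNAs used
#' for target prediction, of which `K` interact with one transcript and
#' `n` with the other, the probability of observing `c` or more common
#' miRNAs by chance is the hypergeometric upper tail
#' \deqn{P = \sum_{i=c}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} /
#'       \binom{N}{n},}
#' with the observed overlap included in the tail and impossible terms
#' contributing zero.  The two MRE-set sizes are exchangeable.  Computed
#' in log space via [stats::phyper]; `c = 0` gives `P = 1`.
#'
#' @param N total number of miRNAs used for prediction.
#' @param K,n MRE-set sizes of the two transcripts (each <= `N`).
#' @param c observed number of common miRNAs (0 <= c <= min(K, n)).
#' @return the upper-tail probability, in (0, 1\].  Vectorized over all
#'   arguments.
#' @export
cerna_pair_pvalue <- function(N, K, n, c) {
  if (any(N < 0 | K < 0 | n < 0 | c < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(K > N) || any(n > N)) {
    stop("`K` and `n` must not exceed `N`", call. = FALSE)
  }
  if (any(c > pmin(K, n))) {
    stop("`c` must not exceed min(K, n)", call. = FALSE)
  }
  p <- phyper(c - 1, K, N - K, n, lower.tail = FALSE)
  pmax(pmin(p, 1), .Machine$double.xmin)
}

# Resolve the MRE set of a candidate: circRNAs from circ_to_mirna, genes
# from the inverted miRNA -> gene map (same set interface for both).
candidate_mre_sets <- function(map, candidates) {
  sets <- map$circ_to_mirna[intersect(candidates, names(map$circ_to_mirna))]
  genes <- setdiff(candidates, names(sets))
  if (length(genes)) {
    pairs_m <- rep(names(map$mirna_to_gene), lengths(map$mirna_to_gene))
    pairs_g <- unlist(map$mirna_to_gene, use.names = FALSE)
    for (g in genes) {
      sets[[g]] <- unique(pairs_m[pairs_g == g])
    }
  }
  sets[candidates]
}

#' Screen transcript pairs as ceRNA candidates
#'
#' For every unordered pair of candidate transcripts, counts the common
#' miRNAs between their MRE sets and evaluates [cerna_pair_pvalue()]
#' against the prediction universe.  Pairs passing both filters — at
#' least `min_common` shared miRNAs and `p <= p_cutoff` — are retained,
#' sorted by ascending p with lexicographic `(id_a, id_b)` tie-break.
#' Candidates may be circRNAs (keys of `circ_to_mirna`) or genes (the
#' gene's MRE set is the set of miRNAs targeting it), so circRNA-circRNA
#' and circRNA-gene pairs are screened through the same interface.
#'
#' @param map a [target_map()].
#' @param candidates character vector of candidate transcript ids.
#' @param min_common minimum shared-miRNA count (default 1).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return data frame `id_a`, `id_b`, `N`, `K`, `n`, `c`, `p_value`, plus
#'   a list-column `common_mirnas`, one row per retained pair.
#' @export
screen_cerna_pairs <- function(map, candidates, min_common = 1,
                               p_cutoff = 0.05) {
  if (!inherits(map, "target_map")) {
    stop("`map` must be a target_map", call. = FALSE)
  }
  N <- length(map$mirna_universe)
  if (N == 0) {
    stop("empty miRNA universe", call. = FALSE)
  }
  min_common <- check_count(min_common, "min_common", min = 0)
  p_cutoff <- check_fraction(p_cutoff, "p_cutoff")
  candidates <- sort(unique(as.character(candidates)))
  sets <- candidate_mre_sets(map, candidates)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("skipping candidate(s) with empty MRE set: %s",
                    paste(candidates[empty], collapse = ", ")),
            call. = FALSE)
    sets <- sets[!empty]
    candidates <- candidates[!empty]
  }
  empty_result <- data.frame(id_a = character(0), id_b = character(0),
                             N = integer(0), K = integer(0), n = integer(0),
                             c = integer(0), p_value = numeric(0),
                             stringsAsFactors = FALSE)
  empty_result$common_mirnas <- list()
  if (length(candidates) < 2) {
    return(empty_result)
  }
  isets <- lapply(sets, function(s) sort(match(s, map$mirna_universe)))
  sizes <- lengths(isets)
  idx <- combn(length(candidates), 2)
  cc <- integer(ncol(idx))
  common <- vector("list", ncol(idx))
  for (j in seq_len(ncol(idx))) {
    shared <- isets[[idx[1, j]]][isets[[idx[1, j]]] %in% isets[[idx[2, j]]]]
    cc[j] <- length(shared)
    common[[j]] <- shared
  }
  K <- sizes[idx[1, ]]
  n <- sizes[idx[2, ]]
  p <- cerna_pair_pvalue(N, K, n, cc)
  keep <- cc >= min_common & p <= p_cutoff
  if (!any(keep)) {
    return(empty_result)
  }
  out <- data.frame(id_a = candidates[idx[1, keep]],
                    id_b = candidates[idx[2, keep]],
                    N = N, K = unname(K[keep]), n = unname(n[keep]),
                    c = cc[keep], p_value = p[keep],
                    stringsAsFactors = FALSE)
  out$common_mirnas <- lapply(common[keep], function(s) {
    map$mirna_universe[s]
  })
  ord <- order(out$p_value, out$id_a, out$id_b)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Assemble the circRNA-miRNA-mRNA network from screened pairs
#'
#' Merges the common miRNAs of all retained ceRNA pairs into one
#' tripartite network: the paired transcripts connect to each shared
#' miRNA, and each shared miRNA connects to its downstream gene targets.
#' Edges are only circRNA-miRNA or miRNA-gene; nodes and edges are
#' deduplicated and sorted deterministically.
#'
#' @param pairs retained pairs from [screen_cerna_pairs()].
#' @param map the [target_map()] used for screening.
#' @return a `cerna_network`: list with `nodes` (data frame `id`, `kind`
#'   with kind in circRNA / miRNA / gene) and `edges` (data frame `from`,
#'   `to`, `kind` with kind `circ-miRNA` or `miRNA-gene`).  An empty pair
#'   list yields an empty network.
#' @export
build_cerna_network <- function(pairs, map) {
  if (!inherits(map, "target_map")) {
    stop("`map` must be a target_map", call. = FALSE)
  }
  circ_edges <- list()
  gene_edges <- list()
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      shared <- pairs$common_mirnas[[i]]
      for (id in c(pairs$id_a[i], pairs$id_b[i])) {
        if (id %in% names(map$circ_to_mirna)) {
          circ_edges[[length(circ_edges) + 1L]] <-
            data.frame(from = id, to = shared, stringsAsFactors = FALSE)
        } else {
          # gene-side pair member: its link to the shared miRNAs is a
          # miRNA-gene edge, keeping the network tripartite
          gene_edges[[length(gene_edges) + 1L]] <-
            data.frame(from = shared, to = id, stringsAsFactors = FALSE)
        }
      }
      for (m in shared) {
        tg <- map$mirna_to_gene[[m]]
        if (length(tg)) {
          gene_edges[[length(gene_edges) + 1L]] <-
            data.frame(from = m, to = tg, stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind_unique <- function(lst, kind) {
    if (!length(lst)) {
      return(data.frame(from = character(0), to = character(0),
                        kind = character(0), stringsAsFactors = FALSE))
    }
    e <- unique(do.call(rbind, lst))
    e$kind <- kind
    e
  }
  ce <- bind_unique(circ_edges, "circ-miRNA")
  ge <- bind_unique(gene_edges, "miRNA-gene")
  edges <- rbind(ce, ge)
  edges <- edges[order(edges$kind, edges$from, edges$to), ]
  rownames(edges) <- NULL

  mirna_ids <- c(ce$to, ge$from)
  nodes <- unique(rbind(
    data.frame(id = ce$from, kind = rep("circRNA", length(ce$from)),
               stringsAsFactors = FALSE),
    data.frame(id = mirna_ids, kind = rep("miRNA", length(mirna_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = ge$to, kind = rep("gene", length(ge$to)),
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$kind, nodes$id), ]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Convert a ceRNA network to an igraph graph
#'
#' @param net a `cerna_network`.
#' @return an [igraph::igraph] graph with vertex attribute `kind` and
#'   edge attribute `kind`.
#' @export
cerna_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a ceRNA network to disk
#'
#' Formats: `edge_tsv` (source, target, edge_kind, source_kind,
#' target_kind; round-trip safe via [read_network_edges()]), `sif`
#' (Cytoscape simple-interaction format) and `graphml` (via igraph).
#'
#' @param net a `cerna_network`.
#' @param path output file path.
#' @param format one of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "sif",
                                                 "graphml")) {
  stopifnot(inherits(net, "cerna_network"))
  format <- match.arg(format)
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  if (format == "edge_tsv") {
    out <- data.frame(source = net$edges$from, target = net$edges$to,
                      edge_kind = net$edges$kind,
                      source_kind = unname(kind_of[net$edges$from]),
                      target_kind = unname(kind_of[net$edges$to]),
                      stringsAsFactors = FALSE)
    if (!nrow(out)) {
      out <- out[0, ]
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      paste(net$edges$from, net$edges$kind, net$edges$to, sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
  } else {
    igraph::write_graph(cerna_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a ceRNA network back from an edge TSV
#'
#' Inverse of [export_network()] with `format = "edge_tsv"`.
#'
#' @param path edge TSV path.
#' @return a `cerna_network`.
#' @export
read_network_edges <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("source", "target", "edge_kind", "source_kind", "target_kind")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  edges <- data.frame(from = df$source, to = df$target, kind = df$edge_kind,
                      stringsAsFactors = FALSE)
  nodes <- unique(rbind(
    data.frame(id = df$source, kind = df$source_kind,
               stringsAsFactors = FALSE),
    data.frame(id = df$target, kind = df$target_kind,
               stringsAsFactors = FALSE)))
  edges <- edges[order(edges$kind, edges$from, edges$to), ]
  nodes <- nodes[order(nodes$kind, nodes$id), ]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Assert that a network is tripartite
#'
#' Checks the structural invariants of a ceRNA network: node kinds are
#' circRNA / miRNA / gene, edges connect only circRNA-miRNA or
#' miRNA-gene, there are no self-loops, and every miRNA node has degree
#' >= 1.
#'
#' @param net a `cerna_network`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
assert_tripartite <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  if (!all(net$nodes$kind %in% c("circRNA", "miRNA", "gene"))) {
    stop("unknown node kind", call. = FALSE)
  }
  if (nrow(net$edges)) {
    if (any(net$edges$from == net$edges$to)) {
      stop("self-loop in network", call. = FALSE)
    }
    fk <- kind_of[net$edges$from]
    tk <- kind_of[net$edges$to]
    ok <- (net$edges$kind == "circ-miRNA" & fk == "circRNA" & tk == "miRNA") |
      (net$edges$kind == "miRNA-gene" & fk == "miRNA" & tk == "gene")
    if (!all(ok)) {
      stop("edge violates tripartite structure", call. = FALSE)
    }
  }
  mirnas <- net$nodes$id[net$nodes$kind == "miRNA"]
  touched <- unique(c(net$edges$from, net$edges$to))
  if (!all(mirnas %in% touched)) {
    stop("miRNA node with degree 0", call. = FALSE)
  }
  invisible(TRUE)
}
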