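# Independent oracles used across the test suite.  These stay deliberately
# naive (exact integer enumeration, brute-force agglomeration) and never
# call the code paths they check.

# Exact hypergeometric upper tail P(X >= c) by direct summation of
# binomial coefficients (integer-exact for the small N used in tests).
oracle_hyper_tail <- function(N, K, n, c) {
  i <- seq(c, min(K, n))
  if (length(i) == 0 || c > min(K, n)) {
    return(if (c <= 0) 1 else 0)
  }
  terms <- choose(K, i) * choose(N - K, n - i)   # impossible terms give 0
  sum(terms) / choose(N, n)
}

# Brute-force UPGMA (average linkage) agglomeration on a dissimilarity
# matrix with labelled rows.  Returns one row per merge: the two cluster
# member sets (as collapsed sorted strings) and the merge height.
oracle_upgma <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- sort(clusters[[best[1]]])
    b <- sort(clusters[[best[2]]])
    # canonical unordered pair of member-set signatures
    sig <- sort(c(paste(a, collapse = "+"), paste(b, collapse = "+")))
    merges[[length(merges) + 1L]] <- data.frame(set_a = sig[1],
                                                set_b = sig[2],
                                                height = best_h,
                                                stringsAsFactors = FALSE)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  do.call(rbind, merges)
}

# Decode an hclust tree into the same per-merge signature table.
hclust_merges <- function(tree, labels) {
  members <- list()
  out <- list()
  for (s in seq_len(nrow(tree$merge))) {
    get <- function(idx) {
      if (idx < 0) labels[-idx] else members[[idx]]
    }
    a <- sort(get(tree$merge[s, 1]))
    b <- sort(get(tree$merge[s, 2]))
    members[[s]] <- c(a, b)
    sig <- sort(c(paste(a, collapse = "+"), paste(b, collapse = "+")))
    out[[s]] <- data.frame(set_a = sig[1], set_b = sig[2],
                           height = tree$height[s],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Small two-group design helper matching the simulators' sample ids.
make_design <- function(n_case, n_control) {
  data.frame(
    sample_id = c(sprintf("case_%d", seq_len(n_case)),
                  sprintf("ctrl_%d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE)
}

# Wrap a plain numeric matrix with probe/sample names.
named_matrix <- function(x, n_case = NULL) {
  x <- as.matrix(x)
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  x
}
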