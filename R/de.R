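#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' across-sample mean of sorted columns.  After normalization each column,
#' when sorted, equals the reference; tied intensities within a column all
#' receive the mean of the reference values at the rank positions the tie
#' group occupies.  Probe and sample order are preserved.
#'
#' @param matrix probe-by-sample matrix of positive intensities.
#' @return normalized matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  validate_expression(matrix)
  if (ncol(matrix) == 1L) {
    return(matrix)
  }
  ref <- rowMeans(apply(matrix, 2, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    v <- numeric(length(x))
    v[order(x)] <- ref
    # ties: average the reference values over the ranks the group occupies
    out[, j] <- stats::ave(v, match(x, x), FUN = mean)
  }
  out
}

#' Per-probe log2 fold change between case and control
#'
#' Fold change is the ratio of geometric means: the difference of group
#' means of log2 intensities, case minus control.  `fc_abs` is
#' `2^|log2fc|`, the absolute fold change as conventionally reported.
#'
#' @param matrix probe-by-sample intensity matrix (normalized).
#' @param design sample design (`sample_id`, `group`).
#' @return data frame `probe_id`, `log2fc`, `fc_abs` in probe order.
#' @export
group_log2fc <- function(matrix, design) {
  validate_expression(matrix)
  validate_design(design, colnames(matrix))
  g <- design_groups(design, colnames(matrix))
  lm2 <- log2(matrix)
  lfc <- rowMeans(lm2[, g$case, drop = FALSE]) -
    rowMeans(lm2[, g$control, drop = FALSE])
  data.frame(probe_id = rownames(matrix), log2fc = unname(lfc),
             fc_abs = 2^abs(unname(lfc)), stringsAsFactors = FALSE)
}

# Row means and unbiased row variances for a log2 submatrix.
row_stats <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1)
  list(n = n, mean = m, var = v)
}

# Two-sided p from t and df, honouring the degenerate-variance conventions:
# zero standard error with equal means -> p = 1; with unequal means the
# p-value is clamped to the smallest positive double so it stays in (0, 1].
t_to_p <- function(tstat, df, diff, se) {
  p <- 2 * pt(-abs(tstat), df)
  degen <- !is.finite(tstat)
  p[degen & diff == 0] <- 1
  p[degen & diff != 0] <- .Machine$double.xmin
  pmax(p, .Machine$double.xmin)
}

#' Per-probe two-sample test on log2 intensities
#'
#' Computes a two-sided p-value per probe comparing case vs control on the
#' log2 scale.  Variants:
#' \describe{
#'   \item{`moderated`}{empirical-Bayes moderated t (the default): per-probe
#'     pooled variances are shrunk toward a common prior,
#'     `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`, with the prior
#'     degrees of freedom `d0` and prior variance `s0^2` estimated by
#'     method of moments on the log sample variances; the t statistic uses
#'     `d0 + d` degrees of freedom.  This is the variant of choice for
#'     very small group sizes.}
#'   \item{`welch`}{Welch t with Welch-Satterthwaite degrees of freedom.}
#'   \item{`pooled`}{equal-variance two-sample t.}
#' }
#'
#' @param matrix probe-by-sample intensity matrix.
#' @param design sample design; each group must have >= 2 samples.
#' @param variant `"moderated"`, `"welch"` or `"pooled"`.
#' @param prior_df optional override of the moderated prior degrees of
#'   freedom `d0` (mainly for testing; `prior_df = 0` reduces the
#'   moderated variant to the pooled t exactly).
#' @return named numeric vector of p-values in (0, 1\], one per probe.
#' @export
probe_test <- function(matrix, design,
                       variant = c("moderated", "welch", "pooled"),
                       prior_df = NULL) {
  variant <- match.arg(variant)
  validate_expression(matrix)
  validate_design(design, colnames(matrix))
  g <- design_groups(design, colnames(matrix))
  if (length(g$case) < 2 || length(g$control) < 2) {
    stop("each group needs >= 2 samples for a per-probe test", call. = FALSE)
  }
  lm2 <- log2(matrix)
  a <- row_stats(lm2[, g$case, drop = FALSE])
  b <- row_stats(lm2[, g$control, drop = FALSE])
  diff <- a$mean - b$mean

  if (variant == "welch") {
    se2 <- a$var / a$n + b$var / b$n
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
    p <- t_to_p(tstat, df, diff, sqrt(se2))
  } else {
    d <- a$n + b$n - 2
    s2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / d
    scale <- 1 / a$n + 1 / b$n
    if (variant == "pooled") {
      tstat <- diff / sqrt(s2 * scale)
      p <- t_to_p(tstat, d, diff, sqrt(s2 * scale))
    } else {
      if (is.null(prior_df)) {
        prior <- estimate_var_prior(s2, d)
      } else {
        prior <- list(df_prior = prior_df,
                      var_prior = if (prior_df > 0)
                        estimate_var_prior(s2, d)$var_prior else 1)
      }
      d0 <- prior$df_prior
      s2_tilde <- if (is.finite(d0)) {
        (d0 * prior$var_prior + d * s2) / (d0 + d)
      } else {
        rep(prior$var_prior, length(s2))
      }
      tstat <- diff / sqrt(s2_tilde * scale)
      # total df cannot exceed the pooled residual df of all probes
      df_total <- min(d0 + d, d * length(s2))
      p <- t_to_p(tstat, df_total, diff, sqrt(s2_tilde * scale))
    }
  }
  setNames(p, rownames(matrix))
}

# Method-of-moments fit of the scaled inverse chi-square prior for
# per-probe variances: log s^2 follows (up to constants) a log-F
# distribution whose first two moments identify (d0, s0^2).
estimate_var_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2) {
    return(list(df_prior = 0, var_prior = 1))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e)
  excess <- evar - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: variances are exchangeable,
    # so the prior is a point mass at the mean sample variance
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(df_prior = d0, var_prior = s02)
}

# Solve trigamma(y) = x by Newton iteration (monotone, convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Call differentially expressed probes by fold-change and p-value filter
#'
#' Applies the standard dual filter: a probe is called `up` when
#' `fc_abs >= fc_threshold`, its (optionally BH-adjusted) p-value is below
#' `p_threshold`, and `log2fc > 0`; `down` analogously for `log2fc < 0`;
#' `none` otherwise.  Input order is preserved.
#'
#' @param records data frame with columns `probe_id`, `log2fc`, `p_value`.
#' @param fc_threshold absolute fold-change cutoff (>= 1; default 1.5).
#' @param p_threshold p-value cutoff (default 0.05).
#' @param adjust `"none"` (filter on raw p, the default) or `"BH"`
#'   (filter on Benjamini-Hochberg adjusted p).
#' @return data frame `probe_id`, `log2fc`, `fc_abs`, `p_value`, `adj_p`,
#'   `direction` (`up` / `down` / `none`).
#' @export
call_de <- function(records, fc_threshold = 1.5, p_threshold = 0.05,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.data.frame(records) ||
      !all(c("probe_id", "log2fc", "p_value") %in% names(records))) {
    stop("`records` needs columns probe_id, log2fc, p_value", call. = FALSE)
  }
  if (!is.numeric(fc_threshold) || fc_threshold < 1) {
    stop("`fc_threshold` must be >= 1", call. = FALSE)
  }
  p_threshold <- check_fraction(p_threshold, "p_threshold")
  fc_abs <- 2^abs(records$log2fc)
  adj_p <- if (adjust == "BH") p.adjust(records$p_value, method = "BH")
           else rep(NA_real_, nrow(records))
  p_use <- if (adjust == "BH") adj_p else records$p_value
  pass <- fc_abs >= fc_threshold & p_use < p_threshold
  direction <- ifelse(pass & records$log2fc > 0, "up",
                      ifelse(pass & records$log2fc < 0, "down", "none"))
  data.frame(probe_id = records$probe_id, log2fc = records$log2fc,
             fc_abs = fc_abs, p_value = records$p_value, adj_p = adj_p,
             direction = direction, stringsAsFactors = FALSE)
}

#' Hierarchically cluster probe expression profiles
#'
#' Agglomerative clustering of probes on the dissimilarity
#' `d = 1 - Pearson correlation` of log2 expression profiles with average
#' (UPGMA) linkage, as used for expression heatmap ordering.  Probes are
#' pre-sorted lexicographically by id before clustering so the result is
#' deterministic under ties.  A probe profile with zero variance has an
#' undefined correlation; its dissimilarity to every other probe is
#' defined as 1.
#'
#' @param matrix probe-by-sample intensity matrix with >= 2 probes
#'   (a single probe yields a degenerate one-leaf result).
#' @return list with `order` (probe ids in dendrogram leaf order) and
#'   `tree` (the [stats::hclust] merge tree, or `NULL` for one probe).
#' @export
hclust_order <- function(matrix) {
  validate_expression(matrix)
  m <- matrix[order(rownames(matrix)), , drop = FALSE]
  if (nrow(m) == 1L) {
    return(list(order = rownames(m), tree = NULL))
  }
  prof <- log2(m)
  cc <- suppressWarnings(cor(t(prof)))
  cc[!is.finite(cc)] <- 0        # zero-variance profiles: d = 1
  diag(cc) <- 1
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = "average")
  list(order = rownames(m)[tree$order], tree = tree)
}
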