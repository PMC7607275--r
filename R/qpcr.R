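#' Collapse technical qPCR replicates to mean Ct
#'
#' Averages the non-missing replicate Ct values for each (sample, target)
#' well.  A well whose replicates are all missing is an error naming the
#' offending pair.
#'
#' @param table Ct table: data frame with columns `sample_id`, `group`,
#'   `target_id`, `replicate`, `ct` (cycles; `NA` for failed wells).
#' @return data frame `sample_id`, `group`, `target_id`, `ct` with one row
#'   per (sample, target).
#' @export
collapse_replicates <- function(table) {
  need <- c("sample_id", "group", "target_id", "replicate", "ct")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("Ct table needs columns sample_id, group, target_id, replicate, ct",
         call. = FALSE)
  }
  key <- interaction(table$sample_id, table$target_id, drop = TRUE)
  n_ok <- tapply(!is.na(table$ct), key, sum)
  if (any(n_ok == 0)) {
    bad <- names(n_ok)[which(n_ok == 0)[1]]
    stop(sprintf("all replicates missing for (sample, target) pair '%s'", bad),
         call. = FALSE)
  }
  out <- aggregate(ct ~ sample_id + group + target_id, data = table,
                   FUN = mean, na.rm = TRUE, na.action = NULL)
  out <- out[order(out$target_id, out$sample_id), ]
  rownames(out) <- NULL
  out[, c("sample_id", "group", "target_id", "ct")]
}

#' Relative expression by the 2^-ddCt method
#'
#' For each target, per-sample `dCt = Ct(target) - Ct(reference)`;
#' `ddCt = mean dCt(case) - mean dCt(control)`; the relative expression of
#' the case group over control is `fold_change = 2^-ddCt` (a value below 1
#' denotes downregulation).  The group difference is tested by a
#' two-sided Welch t on the per-sample dCt values.  If both groups have
#' zero dCt variance the p-value is 1 for equal means and is clamped to
#' the smallest positive double otherwise.
#'
#' @param mean_ct collapsed Ct table as returned by
#'   [collapse_replicates()] (columns `sample_id`, `group`, `target_id`,
#'   `ct`).
#' @param reference_id the reference (housekeeping) gene id; must be
#'   present for every sample.
#' @param design optional sample design (`sample_id`, `group`) overriding
#'   the `group` column of `mean_ct`.
#' @return data frame `target_id`, `ddct`, `fold_change`, `p_value`, one
#'   row per non-reference target.
#' @export
relative_expression <- function(mean_ct, reference_id, design = NULL) {
  need <- c("sample_id", "group", "target_id", "ct")
  if (!is.data.frame(mean_ct) || !all(need %in% names(mean_ct))) {
    stop("collapsed table needs columns sample_id, group, target_id, ct",
         call. = FALSE)
  }
  if (!is.null(design)) {
    validate_design(design)
    mean_ct$group <- setNames(design$group, design$sample_id)[mean_ct$sample_id]
  }
  if (!all(mean_ct$group %in% c("case", "control")) ||
      !all(c("case", "control") %in% mean_ct$group)) {
    stop("both groups must be present and labelled case/control",
         call. = FALSE)
  }
  ref <- mean_ct[mean_ct$target_id == reference_id, ]
  samples <- unique(mean_ct$sample_id)
  if (!all(samples %in% ref$sample_id)) {
    missing <- setdiff(samples, ref$sample_id)
    stop(sprintf("reference '%s' missing for sample(s): %s", reference_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ref_ct <- setNames(ref$ct, ref$sample_id)

  targets <- setdiff(unique(mean_ct$target_id), reference_id)
  res <- lapply(targets, function(tg) {
    sub <- mean_ct[mean_ct$target_id == tg, ]
    dct <- sub$ct - ref_ct[sub$sample_id]
    case <- dct[sub$group == "case"]
    ctrl <- dct[sub$group == "control"]
    ddct <- mean(case) - mean(ctrl)
    p <- welch_p(case, ctrl)
    data.frame(target_id = tg, ddct = ddct, fold_change = 2^(-ddct),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Two-sided Welch t p-value on two numeric vectors, with the degenerate
# zero-variance conventions used across the package.
welch_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) {
    return(NA_real_)
  }
  vx <- var(x)
  vy <- var(y)
  se2 <- vx / nx + vy / ny
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    return(if (diff == 0) 1 else .Machine$double.xmin)
  }
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  max(2 * pt(-abs(tstat), df), .Machine$double.xmin)
}

#' Classify a qPCR validation result
#'
#' A target is validated `up` when its fold change exceeds 1 with
#' `p < alpha`, `down` when below 1 with `p < alpha`, and
#' `not_significant` otherwise.
#'
#' @param rel relative-expression table from [relative_expression()].
#' @param alpha significance level (default 0.01, the conventional
#'   two-star validation threshold).
#' @return `rel` with an added `call` column
#'   (`up` / `down` / `not_significant`).
#' @export
classify_validation <- function(rel, alpha = 0.01) {
  if (!is.data.frame(rel) ||
      !all(c("fold_change", "p_value") %in% names(rel))) {
    stop("`rel` needs columns fold_change and p_value", call. = FALSE)
  }
  alpha <- check_fraction(alpha, "alpha")
  sig <- rel$p_value < alpha
  rel$call <- ifelse(sig & rel$fold_change > 1, "up",
                     ifelse(sig & rel$fold_change < 1, "down",
                            "not_significant"))
  rel
}
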