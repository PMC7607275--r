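# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

#' Validate a probe-by-sample expression matrix
#'
#' An expression matrix is a numeric matrix of strictly positive
#' fluorescence intensities with unique probe ids as row names and unique
#' sample ids as column names.
#'
#' @param matrix numeric matrix to validate.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must have probe row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate probe ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(matrix))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  }
  if (any(matrix <= 0)) {
    stop("expression matrix contains non-positive intensities", call. = FALSE)
  }
  invisible(matrix)
}

#' Validate a two-group sample design
#'
#' @param design data frame with columns `sample_id` and `group`
#'   (`"case"` or `"control"`).
#' @param sample_ids optional character vector of sample ids the design
#'   must cover exactly (each exactly once, both groups non-empty).
#' @return the design, invisibly, if valid.
#' @export
validate_design <- function(design, sample_ids = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "group") %in% names(design))) {
    stop("design must be a data frame with columns sample_id and group",
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  if (!all(design$group %in% c("case", "control"))) {
    stop("design groups must be 'case' or 'control'", call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    if (!setequal(design$sample_id, sample_ids)) {
      stop("design samples do not match matrix samples", call. = FALSE)
    }
  }
  if (!all(c("case", "control") %in% design$group)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  invisible(design)
}

# Split sample ids by group, in matrix column order.
design_groups <- function(design, sample_ids) {
  grp <- setNames(design$group, design$sample_id)[sample_ids]
  list(case = sample_ids[grp == "case"],
       control = sample_ids[grp == "control"])
}

# Format numeric columns with 12 significant digits for reproducible TSVs.
format_numeric_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 12, format = "g")
    }
  }
  df
}
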