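#' @title Preprocessing transforms for microbial features and metabolites
#' @name preprocess
#' @description
#' Per-table transforms applied before association testing. Microbial
#' relative abundances go through `zeros_to_missing()`, `arcsine_sqrt()`,
#' iterative `grubbs_filter()` and `standardize()`; metabolite intensities
#' through `runday_median_scale()`, `log_transform()` and (faecal only)
#' `standardize()`. All table-level functions preserve shape and
#' sample/feature identity; only values change.
NULL

#' Recode exact zeros as missing
#'
#' A zero relative abundance is interpreted as "not detected" rather than
#' true absence, so downstream models treat it as missing.
#'
#' @param x numeric vector or matrix of relative abundances.
#' @return object of the same shape with every exact 0 replaced by `NA`.
#' @export
zeros_to_missing <- function(x) {
  x[!is.na(x) & x == 0] <- NA_real_
  x
}

#' Arcsine square-root transform for proportions
#'
#' @param x numeric vector or matrix with values in \[0, 1\] (or `NA`).
#' @return `asin(sqrt(x))`; missing values are preserved.
#' @export
arcsine_sqrt <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("arcsine_sqrt: values must lie in [0, 1]")
  }
  out <- x
  out[!is.na(x)] <- asin(sqrt(x[!is.na(x)]))
  out
}

#' Two-sided Grubbs critical value
#'
#' @param n number of non-missing observations.
#' @param alpha significance level.
#' @return critical value for G = max|x - mean| / sd.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) return(Inf)
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier filter
#'
#' Repeatedly removes the single most extreme value while the two-sided
#' Grubbs statistic exceeds its critical value at `alpha`. Removed entries
#' become `NA`. At most `floor(n/2)` points are ever removed.
#'
#' @param x numeric vector (may contain `NA`).
#' @param alpha significance level of the test (default 0.05).
#' @return `x` with detected outliers set to `NA`.
#' @export
grubbs_filter <- function(x, alpha = 0.05) {
  idx <- which(!is.na(x))
  if (length(idx) < 3) {
    warning("grubbs_filter: fewer than 3 non-missing values; returned unchanged")
    return(x)
  }
  max_remove <- floor(length(idx) / 2)
  removed <- 0L
  out <- x
  repeat {
    keep <- which(!is.na(out))
    n <- length(keep)
    if (n < 3 || removed >= max_remove) break
    v <- out[keep]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) break
    dev <- abs(v - mean(v))
    g <- max(dev) / s
    if (g <= grubbs_critical(n, alpha)) break
    out[keep[which.max(dev)]] <- NA_real_
    removed <- removed + 1L
  }
  out
}

#' Standardize to zero mean and unit variance
#'
#' Uses the sample standard deviation (n - 1 denominator). Missing values
#' are preserved.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return standardized vector.
#' @export
standardize <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) stop("standardize: need >= 2 non-missing values")
  s <- stats::sd(v)
  if (s == 0) stop("standardize: constant vector")
  (x - mean(v)) / s
}

#' PCA-based sample outlier detection
#'
#' Flags samples whose absolute score exceeds `sd_mult` standard deviations
#' on any of the first `n_pcs` principal components (single pass, centred
#' PCA without variance scaling; zero-variance components are skipped).
#'
#' @param x samples x features numeric matrix (no missing values).
#' @param n_pcs number of leading components to inspect (default 10).
#' @param sd_mult score threshold in SD units (default 3).
#' @return character vector of flagged sample ids (rownames of `x`).
#' @export
pca_sample_outliers <- function(x, n_pcs = 10, sd_mult = 3) {
  if (n_pcs < 1) stop("pca_sample_outliers: n_pcs must be >= 1")
  if (nrow(x) < 2) stop("pca_sample_outliers: need more than one sample")
  if (anyNA(x)) stop("pca_sample_outliers: missing values not allowed")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  flagged <- rep(FALSE, nrow(x))
  for (j in seq_len(k)) {
    s <- stats::sd(pc$x[, j])
    if (!is.finite(s) || s < 1e-12) next
    flagged <- flagged | abs(pc$x[, j]) > sd_mult * s
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  ids[flagged]
}

#' Scale metabolite intensities by run-day medians
#'
#' Each value is divided by the median of its metabolite within its
#' run-day, so per-run-day medians become 1. Run-days where a metabolite is
#' entirely missing are left missing.
#'
#' @param x samples x metabolites numeric matrix of positive intensities.
#' @param runday per-sample batch labels (length `nrow(x)`).
#' @return scaled matrix.
#' @export
runday_median_scale <- function(x, runday) {
  if (length(runday) != nrow(x)) {
    stop("runday_median_scale: runday labels must match sample count")
  }
  out <- x
  for (lev in unique(runday)) {
    rows <- which(runday == lev)
    med <- apply(x[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- NA_real_
    out[rows, ] <- sweep(x[rows, , drop = FALSE], 2, med, "/")
  }
  out
}

#' Natural log transform
#'
#' @param x numeric vector or matrix of strictly positive values (or `NA`).
#' @return `log(x)` with missing values preserved.
#' @export
log_transform <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) && min(v) <= 0) stop("log_transform: values must be positive")
  out <- x
  out[!is.na(x)] <- log(x[!is.na(x)])
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps the value with (average) rank r of n to `qnorm((r - 0.5) / n)`.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return transformed vector, monotone in the input; `NA` preserved.
#' @export
inverse_normal_transform <- function(x) {
  idx <- which(!is.na(x))
  if (length(unique(x[idx])) < 2) {
    stop("inverse_normal_transform: need >= 2 distinct non-missing values")
  }
  r <- rank(x[idx], ties.method = "average")
  out <- x
  out[idx] <- stats::qnorm((r - 0.5) / length(idx))
  out
}

#' Mask values more than `sd_mult` SDs from the mean
#'
#' Single-pass rule used for adiposity phenotypes and for temporal
#' stability profiles before standardization.
#'
#' @param x numeric vector.
#' @param sd_mult threshold in SD units (default 3).
#' @return `x` with extreme values set to `NA`.
#' @export
sd_outlier_mask <- function(x, sd_mult = 3) {
  v <- x[!is.na(x)]
  if (length(v) < 2) return(x)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(x)
  out <- x
  out[!is.na(x) & abs(x - mean(v)) > sd_mult * s] <- NA_real_
  out
}

# Column-wise application preserving dimnames; columns that cannot be
# transformed (too few values, constant) become all-NA with one warning.
apply_columns <- function(x, f, what) {
  out <- x
  dropped <- character(0)
  for (j in seq_len(ncol(x))) {
    res <- tryCatch(f(x[, j]), error = function(e) NULL)
    if (is.null(res)) {
      out[, j] <- NA_real_
      dropped <- c(dropped, colnames(x)[j] %||% as.character(j))
    } else {
      out[, j] <- res
    }
  }
  if (length(dropped)) {
    warning(sprintf("%s: %d column(s) could not be transformed and were set to NA (%s)",
                    what, length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess a microbial feature table
#'
#' Pipeline: zeros -> missing, arcsine square-root, per-feature iterative
#' Grubbs filtering, per-feature standardization.
#'
#' @param x samples x features relative-abundance matrix.
#' @param grubbs_alpha Grubbs significance level (default 0.05).
#' @return transformed matrix (same shape).
#' @export
preprocess_features <- function(x, grubbs_alpha = 0.05) {
  x <- zeros_to_missing(x)
  x <- arcsine_sqrt(x)
  x <- apply_columns(x, function(v) suppressWarnings(grubbs_filter(v, grubbs_alpha)),
                     "grubbs_filter")
  apply_columns(x, standardize, "standardize")
}

#' Preprocess a metabolite table
#'
#' Pipeline: below-detection (zero) -> missing, run-day median scaling,
#' natural log, and optionally per-metabolite standardization (applied to
#' faecal but not blood metabolites).
#'
#' @param x samples x metabolites positive-intensity matrix.
#' @param runday per-sample batch labels, or `NULL` to skip batch scaling.
#' @param scale standardize each metabolite after the log transform?
#' @return transformed matrix (same shape).
#' @export
preprocess_metabolites <- function(x, runday = NULL, scale = TRUE) {
  x <- zeros_to_missing(x)
  if (!is.null(runday)) x <- runday_median_scale(x, runday)
  x <- log_transform(x)
  if (scale) x <- apply_columns(x, standardize, "standardize")
  x
}
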