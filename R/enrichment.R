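#' @title Parametric analysis of set enrichment (PAGE)
#' @name enrichment
#' @description
#' PAGE enrichment of per-metabolite association statistics over
#' metabolite super-pathways. The Z score compares a set's mean statistic
#' to the background mean, scaled by the background SD and the square
#' root of the set size; significance comes from label permutations with
#' an add-one empirical P, adjusted across sets by Benjamini-Hochberg.
NULL

#' PAGE Z score
#'
#' `z = (S_m - mu) * sqrt(m) / delta`, with `S_m` the set mean, `mu` and
#' `delta` the background mean and SD, `m` the set size.
#'
#' @param set_values statistics of the metabolites in the set.
#' @param background statistics of all metabolites.
#' @return the Z score.
#' @export
page_z <- function(set_values, background) {
  delta <- stats::sd(background)
  if (!is.finite(delta) || delta == 0) stop("page_z: background SD is zero")
  (mean(set_values) - mean(background)) * sqrt(length(set_values)) / delta
}

#' Signed-count statistic per metabolite
#'
#' For each metabolite, the number of significant positive associations
#' minus the number of significant negative ones. This is the statistic
#' fed to PAGE: positive values mean the metabolite predominantly
#' increases with the feature class under test.
#'
#' @param assoc association data.frame (feature_id, metabolite_id, beta, q).
#' @param metabolite_ids metabolites to report (default: all in `assoc`).
#' @param fdr significance threshold on q.
#' @return named numeric vector of signed counts.
#' @export
metabolite_direction_stat <- function(assoc, metabolite_ids = NULL,
                                      fdr = 0.05) {
  if (is.null(metabolite_ids)) metabolite_ids <- unique(assoc$metabolite_id)
  stat <- stats::setNames(numeric(length(metabolite_ids)), metabolite_ids)
  sig <- assoc[assoc$q <= fdr, , drop = FALSE]
  if (nrow(sig)) {
    s <- tapply(sign(sig$beta), sig$metabolite_id, sum)
    keep <- intersect(names(s), metabolite_ids)
    stat[keep] <- s[keep]
  }
  stat
}

#' PAGE enrichment test over metabolite super-pathways
#'
#' Computes the PAGE Z score of each annotated set on the supplied
#' per-metabolite statistics, a two-sided permutation P value from
#' `n_perm` label shuffles (add-one convention), and Benjamini-Hochberg
#' adjusted P values across the sets.
#'
#' @param stats_vec named per-metabolite statistic vector (names are
#'   metabolite ids).
#' @param annotation data.frame with `metabolite_id` and `super_pathway`.
#' @param n_perm number of permutations (default 10000).
#' @return data.frame with set_id, m, z, direction, p_perm, p_adj.
#' @export
page_test <- function(stats_vec, annotation, n_perm = 10000) {
  ann <- annotation[annotation$metabolite_id %in% names(stats_vec), , drop = FALSE]
  if (nrow(ann) == 0) stop("page_test: no annotated metabolites")
  background <- stats_vec[ann$metabolite_id]
  delta <- stats::sd(background)
  sets <- split(ann$metabolite_id, ann$super_pathway)
  sets <- sets[lengths(sets) > 0]
  mu <- mean(background)
  z_of <- function(values, members) {
    vapply(sets, function(ids) {
      (mean(values[members %in% ids]) - mu) * sqrt(sum(members %in% ids)) / delta
    }, numeric(1))
  }
  if (!is.finite(delta) || delta == 0) {
    res <- data.frame(set_id = names(sets), m = lengths(sets), z = 0,
                      direction = 0, p_perm = 1, p_adj = 1,
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    return(res)
  }
  # precompute membership index per set for speed
  member_idx <- lapply(sets, function(ids) which(ann$metabolite_id %in% ids))
  z_fast <- function(values) {
    vapply(member_idx, function(ix) {
      (mean(values[ix]) - mu) * sqrt(length(ix)) / delta
    }, numeric(1))
  }
  z_obs <- z_fast(as.numeric(background))
  exceed <- numeric(length(sets))
  v <- as.numeric(background)
  for (k in seq_len(n_perm)) {
    zp <- z_fast(sample(v))
    exceed <- exceed + (abs(zp) >= abs(z_obs))
  }
  p_perm <- (1 + exceed) / (1 + n_perm)
  res <- data.frame(set_id = names(sets), m = lengths(sets), z = z_obs,
                    direction = sign(z_obs), p_perm = p_perm,
                    p_adj = stats::p.adjust(p_perm, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
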