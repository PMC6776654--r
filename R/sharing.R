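#' @title Presence/absence sharing and cohort-structure statistics
#' @name sharing
#' @description
#' Descriptive statistics of the cohort's microbial structure: the
#' fraction of features shared between unrelated individuals (species vs
#' pathways), prevalence binning, the prevalence-redundancy correlation,
#' per-species contribution fractions, and the temporal stability of
#' metabolic profiles against a random-pairing permutation null.
NULL

#' Presence/absence matrix from a feature table
#'
#' @param x samples x features abundance matrix.
#' @return binary matrix: 1 where abundance is positive and non-missing.
#' @export
presence_matrix <- function(x) {
  (!is.na(x) & x > 0) * 1L
}

#' Sharing fraction between two presence vectors
#'
#' Jaccard-type fraction: features present in both members over features
#' present in at least one.
#'
#' @param a,b binary presence vectors of equal length.
#' @return fraction in \[0, 1\]; `NA` when the union is empty.
#' @export
sharing_fraction <- function(a, b) {
  if (length(a) != length(b)) stop("sharing_fraction: length mismatch")
  u <- sum(a == 1 | b == 1)
  if (u == 0) return(NA_real_)
  sum(a == 1 & b == 1) / u
}

# index pairs (i < j) of samples from different families
unrelated_pairs <- function(family_ids) {
  n <- length(family_ids)
  if (length(unique(family_ids)) < 2) {
    stop("unrelated_pairs: need at least 2 families")
  }
  idx <- which(outer(family_ids, family_ids, "!="), arr.ind = TRUE)
  idx[idx[, 1] < idx[, 2], , drop = FALSE]
}

# pairwise sharing fractions for a set of index pairs, vectorized through
# the cross-product of the presence matrix
pairwise_sharing <- function(pres, pairs) {
  inter <- tcrossprod(pres)
  counts <- rowSums(pres)
  i <- pairs[, 1]; j <- pairs[, 2]
  un <- counts[i] + counts[j] - inter[cbind(i, j)]
  out <- unname(inter[cbind(i, j)] / un)
  out[un == 0] <- NA_real_
  out
}

#' Compare species vs pathway sharing between unrelated individuals
#'
#' Enumerates all cross-family sample pairs, computes the sharing fraction
#' of species and of pathways for each pair, and compares the paired
#' distributions with a two-sided Wilcoxon signed-rank test.
#'
#' @param species,pathways presence matrices over the same samples.
#' @param pedigree pedigree data.frame (defines family membership).
#' @return list with `mean_species`, `mean_pathways`, `wilcoxon_p`,
#'   `n_pairs`, and the per-pair fractions.
#' @export
compare_sharing <- function(species, pathways, pedigree) {
  stopifnot(nrow(species) == nrow(pathways))
  fam <- pedigree$family_id[match(rownames(species), pedigree$individual_id)]
  if (anyNA(fam)) stop("compare_sharing: samples missing from pedigree")
  pairs <- unrelated_pairs(fam)
  sp <- pairwise_sharing(species, pairs)
  pw <- pairwise_sharing(pathways, pairs)
  keep <- !is.na(sp) & !is.na(pw)
  d <- pw[keep] - sp[keep]
  wp <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(pw[keep], sp[keep],
                                        paired = TRUE)$p.value)
  list(mean_species = mean(sp, na.rm = TRUE),
       mean_pathways = mean(pw, na.rm = TRUE),
       wilcoxon_p = wp,
       n_pairs = nrow(pairs),
       species_fractions = sp,
       pathway_fractions = pw)
}

#' Prevalence bin fractions
#'
#' Fraction of features whose prevalence (column mean of the presence
#' matrix) falls in \[0, 1%), \[1, 25%), \[25, 50%), \[50, 75%) and
#' \[75, 100%\].
#'
#' @param pres presence matrix.
#' @param edges inner bin edges as proportions.
#' @return named vector of bin fractions (sums to 1).
#' @export
prevalence_bins <- function(pres, edges = c(0.01, 0.25, 0.50, 0.75)) {
  if (ncol(pres) == 0) stop("prevalence_bins: empty matrix")
  prev <- colMeans(pres)
  br <- c(0, edges, 1 + 1e-9)
  labs <- c(sprintf("<%g%%", edges[1] * 100),
            sprintf("[%g%%,%g%%)", edges[-length(edges)] * 100,
                    edges[-1] * 100),
            sprintf(">=%g%%", edges[length(edges)] * 100))
  counts <- table(cut(prev, breaks = br, right = FALSE, labels = labs))
  as.numeric(counts) / length(prev) -> frac
  names(frac) <- labs
  frac
}

#' Correlation of pathway prevalence with contributor redundancy
#'
#' Spearman correlation between per-pathway prevalence and the number of
#' contributing species.
#'
#' @param pathways pathway presence matrix.
#' @param contribution_map pathway -> named species weight vectors.
#' @return list with `rho` and `p` (asymptotic).
#' @export
prevalence_redundancy_correlation <- function(pathways, contribution_map) {
  ids <- colnames(pathways)
  if (length(ids) < 3) stop("prevalence_redundancy_correlation: need >= 3 pathways")
  counts <- vapply(contribution_map[ids], length, integer(1))
  if (length(unique(counts)) < 2) {
    stop("prevalence_redundancy_correlation: contributor count is constant")
  }
  prev <- colMeans(pathways)
  ct <- suppressWarnings(stats::cor.test(prev, counts, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Mean contribution fraction of a species to a pathway
#'
#' Mean, over samples where the pathway is present, of the species' share
#' of the pathway's abundance (weight x species abundance over the raw
#' pathway abundance including its unclassified residual).
#'
#' @param pathway_id,species_id identifiers.
#' @param species species abundance matrix.
#' @param contribution_map pathway -> named species weight vectors.
#' @return fraction in \[0, 1\].
#' @export
contribution_fraction <- function(pathway_id, species_id, species,
                                  contribution_map) {
  w <- contribution_map[[pathway_id]]
  if (is.null(w)) stop(sprintf("contribution_fraction: unknown pathway %s", pathway_id))
  csum <- sum(w)
  contrib <- species[, names(w), drop = FALSE] %*% w
  present <- contrib > 0
  if (!any(present)) stop("contribution_fraction: pathway never present")
  wi <- if (species_id %in% names(w)) w[[species_id]] else 0
  if (wi == 0) return(0)
  raw <- contrib[present] / csum  # includes the proportional residual
  mean(wi * species[present, species_id] / raw)
}

#' Temporal stability of metabolic profiles
#'
#' Per-individual Pearson correlation of two metabolomic profiles taken at
#' different time points (after a 3-SD outlier mask and standardization of
#' each metabolite), compared with a permutation null of randomly paired
#' profiles. The empirical P uses the add-one convention
#' `(1 + b) / (1 + n_perm)` and is never 0.
#'
#' @param t1,t2 samples x metabolites matrices with matched rows (row i of
#'   `t2` is the same individual as row i of `t1`).
#' @param n_perm number of random-pairing permutations (>= 100).
#' @param sd_mult outlier mask threshold (default 3).
#' @return list with `mean_r`, `empirical_p`, the per-pair correlations
#'   and the null means.
#' @export
temporal_stability <- function(t1, t2, n_perm = 10000, sd_mult = 3) {
  if (nrow(t1) != nrow(t2)) stop("temporal_stability: row mismatch")
  if (nrow(t1) < 10) stop("temporal_stability: need >= 10 matched pairs")
  if (n_perm < 100) stop("temporal_stability: n_perm must be >= 100")
  clean <- function(x) {
    apply_columns(x, function(v) standardize(sd_outlier_mask(v, sd_mult)),
                  "temporal_stability")
  }
  a <- clean(t1)
  b <- clean(t2)
  pair_r <- function(perm) {
    vapply(seq_len(nrow(a)), function(i) {
      suppressWarnings(stats::cor(a[i, ], b[perm[i], ],
                                  use = "pairwise.complete.obs"))
    }, numeric(1))
  }
  obs <- mean(pair_r(seq_len(nrow(a))), na.rm = TRUE)
  null_means <- vapply(seq_len(n_perm), function(k) {
    perm <- sample.int(nrow(a))
    mean(pair_r(perm), na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(null_means >= obs)) / (1 + n_perm)
  list(mean_r = obs, empirical_p = p,
       pair_correlations = pair_r(seq_len(nrow(a))),
       null_means = null_means)
}
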