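#' @title Gut-host metabolic dialogue detection
#' @name dialogue
#' @description
#' Identifies faecal-blood metabolite pairs co-associated with the same
#' microbial feature, tests mediation plausibility with a
#' missingness-based correlation simulation (co-associated pairs should
#' correlate more strongly where the feature is present), and quantifies
#' each trio with the P-gain statistic -- the ratio of the smaller
#' single-metabolite P value to the metabolite-ratio P value -- against a
#' null threshold calibrated on correlation- and sample-size-matched
#' metabolite pairs associated with two different features.
NULL

#' Find co-association trios
#'
#' For every feature significant (q <= fdr) in both compartments, forms
#' the cartesian product of its significant faecal and blood metabolites
#' and drops trios with fewer than `min_complete` complete observations
#' (feature present plus both metabolites measured).
#'
#' @param faecal_assoc,blood_assoc association data.frames from
#'   [run_screen()].
#' @param faecal,blood preprocessed metabolite matrices (log scale).
#' @param features preprocessed feature matrix (`NA` = not detected).
#' @param min_complete minimum complete observations (default 100).
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame with feature_id, faecal_met_id, blood_met_id,
#'   n_complete and r_observed (pairwise-complete Pearson correlation of
#'   the metabolite pair).
#' @export
find_co_associations <- function(faecal_assoc, blood_assoc, faecal, blood,
                                 features, min_complete = 100, fdr = 0.05) {
  sf <- faecal_assoc[faecal_assoc$q <= fdr, , drop = FALSE]
  sb <- blood_assoc[blood_assoc$q <= fdr, , drop = FALSE]
  common <- intersect(unique(sf$feature_id), unique(sb$feature_id))
  out <- list()
  for (fid in common) {
    fmets <- sf$metabolite_id[sf$feature_id == fid]
    bmets <- sb$metabolite_id[sb$feature_id == fid]
    grid <- expand.grid(faecal_met_id = fmets, blood_met_id = bmets,
                        stringsAsFactors = FALSE)
    grid$feature_id <- fid
    out[[fid]] <- grid
  }
  if (length(out) == 0) {
    return(data.frame(feature_id = character(0), faecal_met_id = character(0),
                      blood_met_id = character(0), n_complete = integer(0),
                      r_observed = numeric(0)))
  }
  trios <- do.call(rbind, out)
  rownames(trios) <- NULL
  trios$n_complete <- vapply(seq_len(nrow(trios)), function(i) {
    sum(!is.na(features[, trios$feature_id[i]]) &
          !is.na(faecal[, trios$faecal_met_id[i]]) &
          !is.na(blood[, trios$blood_met_id[i]]))
  }, numeric(1))
  trios$r_observed <- vapply(seq_len(nrow(trios)), function(i) {
    suppressWarnings(stats::cor(faecal[, trios$faecal_met_id[i]],
                                blood[, trios$blood_met_id[i]],
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  trios <- trios[trios$n_complete >= min_complete, , drop = FALSE]
  rownames(trios) <- NULL
  trios[, c("feature_id", "faecal_met_id", "blood_met_id", "n_complete",
            "r_observed")]
}

#' Log-ratio of two metabolites
#'
#' @param m1,m2 log-intensity vectors (the preprocessing contract puts
#'   metabolites on the natural-log scale).
#' @return elementwise `m1 - m2`; missing where either is missing.
#' @export
log_ratio <- function(m1, m2) {
  m1 - m2
}

#' Family-random-effect LMM association P value
#'
#' Random-intercept-per-family Gaussian mixed model fitted by ML via the
#' variance-component machinery (relatedness 1 within families), with a
#' likelihood-ratio P for the feature's fixed effect. When the family
#' variance collapses to zero the fit equals ordinary least squares.
#'
#' @param y response vector.
#' @param feature predictor vector.
#' @param covariates numeric covariate matrix/data.frame or `NULL`.
#' @param family_ids per-sample family labels.
#' @param min_n minimum complete observations (default 100).
#' @return list with `p`, `beta`, `se`, `n`; or `NULL` if skipped.
#' @export
lmm_family_p <- function(y, feature, covariates = NULL, family_ids,
                         min_n = 100) {
  K <- family_matrix(family_ids)
  lrt_association(y, feature, covariates, K, min_n = min_n)
}

#' P-gain statistic
#'
#' `min(p_faecal, p_blood) / p_ratio`. Large values indicate the
#' metabolite ratio is more informative than either metabolite alone.
#'
#' @param p_faecal,p_blood,p_ratio P values in (0, 1\].
#' @return the P-gain (positive; `p_ratio` is floored at 1e-300).
#' @export
pgain <- function(p_faecal, p_blood, p_ratio) {
  ps <- c(p_faecal, p_blood, p_ratio)
  if (anyNA(ps) || any(ps <= 0) || any(ps > 1)) {
    stop("pgain: P values must lie in (0, 1]")
  }
  min(p_faecal, p_blood) / max(p_ratio, 1e-300)
}

# Fit the three LMMs of one trio on its shared complete-case set and
# return the P-gain record. `rot_cache` memoizes rotations by missingness
# pattern across calls.
trio_pgain <- function(feature_id, faecal_met_id, blood_met_id, faecal,
                       blood, features, covariates, family_ids,
                       min_n = 100, rot_cache = NULL) {
  y1 <- faecal[, faecal_met_id]
  y2 <- blood[, blood_met_id]
  f <- features[, feature_id]
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  idx <- !is.na(y1) & !is.na(y2) & !is.na(f)
  if (!is.null(cov_m)) idx <- idx & rowSums(is.na(cov_m)) == 0
  n <- sum(idx)
  if (n < min_n) return(NULL)
  key <- paste0("k", paste(which(!idx), collapse = ","))
  ent <- if (!is.null(rot_cache)) rot_cache[[key]] else NULL
  if (is.null(ent)) {
    rot <- kinship_rotation(family_matrix(family_ids[idx]))
    # family blocks can exceed size 2 in general; family_matrix on the
    # subset stays tiny relative to the fits, so no structure fast-path
    Xn <- cbind(`(Intercept)` = rep(1, n),
                if (is.null(cov_m)) NULL else cov_m[idx, , drop = FALSE])
    ent <- list(rot = rot, tXn = rot$rotate(Xn))
    if (!is.null(rot_cache)) rot_cache[[key]] <- ent
  }
  tXf <- cbind(ent$tXn, feature = ent$rot$rotate(f[idx]))
  one_p <- function(y) {
    ty <- ent$rot$rotate(y[idx])
    f0 <- vc_fit_rotated(ty, ent$tXn, ent$rot$values)
    f1 <- vc_fit_rotated(ty, tXf, ent$rot$values)
    stat <- max(2 * (f1$loglik - f0$loglik), 0)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  p_f <- one_p(y1)
  p_b <- one_p(y2)
  p_r <- one_p(log_ratio(y1, y2))
  list(n = n, p_faecal = p_f, p_blood = p_b, p_ratio = p_r,
       pgain = pgain(max(p_f, 1e-300), max(p_b, 1e-300), p_r))
}

#' Compute P-gain records for co-association trios
#'
#' For each trio, fits the family LMM of the faecal metabolite, the blood
#' metabolite and their log-ratio against the feature on the trio's
#' shared complete-case set, and evaluates the P-gain.
#'
#' @param trios data.frame from [find_co_associations()].
#' @param faecal,blood preprocessed metabolite matrices (log scale).
#' @param features preprocessed feature matrix.
#' @param covariates numeric covariate matrix or `NULL`.
#' @param family_ids per-sample family labels.
#' @param min_n minimum complete observations (default 100).
#' @return the trios data.frame augmented with p_faecal, p_blood, p_ratio
#'   and pgain (NA where skipped).
#' @export
compute_pgain_records <- function(trios, faecal, blood, features,
                                  covariates = NULL, family_ids,
                                  min_n = 100) {
  cache <- new.env(parent = emptyenv())
  cols <- c("p_faecal", "p_blood", "p_ratio", "pgain")
  for (cl in cols) trios[[cl]] <- NA_real_
  for (i in seq_len(nrow(trios))) {
    rec <- trio_pgain(trios$feature_id[i], trios$faecal_met_id[i],
                      trios$blood_met_id[i], faecal, blood, features,
                      covariates, family_ids, min_n, cache)
    if (!is.null(rec)) {
      trios$p_faecal[i] <- rec$p_faecal
      trios$p_blood[i] <- rec$p_blood
      trios$p_ratio[i] <- rec$p_ratio
      trios$pgain[i] <- rec$pgain
    }
  }
  trios
}

#' Build the no-interplay null pool
#'
#' Pairs of metabolites significantly associated (q <= fdr) with two
#' *different* features, excluding the target co-associated pairs: the
#' conservative assumption is that such pairs have no microbiome-mediated
#' interplay. Each pool pair carries the faecal member's feature (whose
#' missingness pattern the null P-gain is computed under).
#'
#' @param faecal_assoc,blood_assoc association data.frames.
#' @param trios target trios whose metabolite pairs are excluded.
#' @param faecal,blood preprocessed metabolite matrices.
#' @param features preprocessed feature matrix.
#' @param fdr significance threshold (default 0.05).
#' @param max_pool cap on the pool size (deterministic head).
#' @return data.frame with feature_id, faecal_met_id, blood_met_id,
#'   n_complete, r (pairwise-complete correlation).
#' @export
build_null_pool <- function(faecal_assoc, blood_assoc, trios, faecal, blood,
                            features, fdr = 0.05, max_pool = 20000) {
  sf <- faecal_assoc[faecal_assoc$q <= fdr, c("feature_id", "metabolite_id")]
  sb <- blood_assoc[blood_assoc$q <= fdr, c("feature_id", "metabolite_id")]
  if (nrow(sf) == 0 || nrow(sb) == 0) {
    stop("build_null_pool: no significant associations to build the pool from")
  }
  grid <- merge(sf, sb, by = NULL, suffixes = c("_f", "_b"))
  names(grid) <- c("feature_id", "faecal_met_id", "blood_feature_id",
                   "blood_met_id")
  grid <- grid[grid$feature_id != grid$blood_feature_id, , drop = FALSE]
  tkey <- paste(trios$faecal_met_id, trios$blood_met_id)
  grid <- grid[!(paste(grid$faecal_met_id, grid$blood_met_id) %in% tkey), ,
               drop = FALSE]
  grid <- unique(grid[, c("feature_id", "faecal_met_id", "blood_met_id")])
  if (nrow(grid) == 0) stop("build_null_pool: empty pool")
  if (nrow(grid) > max_pool) grid <- grid[seq_len(max_pool), , drop = FALSE]
  rownames(grid) <- NULL
  grid$n_complete <- vapply(seq_len(nrow(grid)), function(i) {
    sum(!is.na(features[, grid$feature_id[i]]) &
          !is.na(faecal[, grid$faecal_met_id[i]]) &
          !is.na(blood[, grid$blood_met_id[i]]))
  }, numeric(1))
  grid$r <- vapply(seq_len(nrow(grid)), function(i) {
    suppressWarnings(stats::cor(faecal[, grid$faecal_met_id[i]],
                                blood[, grid$blood_met_id[i]],
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  grid[is.finite(grid$r), , drop = FALSE]
}

#' Match null pairs to targets by correlation and sample size
#'
#' For each draw, picks a pool pair whose absolute correlation is within
#' `tol_r` of the target's and whose sample size is within relative
#' `tol_n`, sampling with replacement across draws. If a target's
#' tolerance neighbourhood is empty the tolerances are doubled once (with
#' a warning); a still-empty neighbourhood is an error.
#'
#' @param targets data.frame with `r_observed` and `n_complete`.
#' @param pool data.frame from [build_null_pool()] (`r`, `n_complete`).
#' @param n_draws number of matched draws.
#' @param tol_r absolute tolerance on |r| (default 0.05).
#' @param tol_n relative tolerance on n (default 0.10).
#' @return data.frame: one row per draw with `target` (row index) and the
#'   matched pool columns; the tolerances used are attached as attributes.
#' @export
match_null_pairs <- function(targets, pool, n_draws, tol_r = 0.05,
                             tol_n = 0.10) {
  if (nrow(pool) == 0) stop("match_null_pairs: empty pool")
  if (nrow(targets) == 0) stop("match_null_pairs: no targets")
  neighbourhood <- function(i, tr, tn) {
    which(abs(abs(pool$r) - abs(targets$r_observed[i])) <= tr &
            abs(pool$n_complete - targets$n_complete[i]) <=
              tn * targets$n_complete[i])
  }
  nb <- lapply(seq_len(nrow(targets)), neighbourhood, tr = tol_r, tn = tol_n)
  if (any(lengths(nb) == 0)) {
    warning("match_null_pairs: empty tolerance neighbourhood for some targets; doubling tolerances once")
    tol_r <- 2 * tol_r; tol_n <- 2 * tol_n
    nb <- lapply(seq_len(nrow(targets)), neighbourhood, tr = tol_r, tn = tol_n)
    if (any(lengths(nb) == 0)) {
      bad <- which(lengths(nb) == 0)
      stop(sprintf("match_null_pairs: no matchable candidates for target(s) %s",
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  tgt <- rep_len(seq_len(nrow(targets)), n_draws)
  picks <- vapply(tgt, function(i) {
    cand <- nb[[i]]
    if (length(cand) == 1) cand else sample(cand, 1)
  }, integer(1))
  out <- pool[picks, , drop = FALSE]
  out$target <- tgt
  rownames(out) <- NULL
  attr(out, "tol_r") <- tol_r
  attr(out, "tol_n") <- tol_n
  out
}

#' Null P-gain distribution from matched pairs
#'
#' Computes the P-gain of each matched null pair against its pool
#' feature, memoizing distinct (pair, feature) combinations.
#'
#' @param matched data.frame from [match_null_pairs()].
#' @param faecal,blood,features,covariates,family_ids as in
#'   [compute_pgain_records()].
#' @param min_n minimum complete observations (default 100).
#' @return numeric vector of null P-gains, one per draw (NA where the
#'   complete-case rule skipped the pair).
#' @export
null_pgain_distribution <- function(matched, faecal, blood, features,
                                    covariates = NULL, family_ids,
                                    min_n = 100) {
  key <- paste(matched$feature_id, matched$faecal_met_id,
               matched$blood_met_id)
  uniq <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  vals <- stats::setNames(rep(NA_real_, sum(uniq)), key[uniq])
  for (k in which(uniq)) {
    rec <- trio_pgain(matched$feature_id[k], matched$faecal_met_id[k],
                      matched$blood_met_id[k], faecal, blood, features,
                      covariates, family_ids, min_n, cache)
    if (!is.null(rec)) vals[key[k]] <- rec$pgain
  }
  unname(vals[key])
}

#' Empirical P-gain threshold
#'
#' The q-quantile of the null P-gain distribution by the higher
#' order-statistic convention (no interpolation): the smallest null value
#' with at least `q` of the nulls at or below it.
#'
#' @param null_pgains vector of null P-gains (>= 100 non-missing values).
#' @param q quantile (default 0.95, i.e. the top 5% critical value).
#' @return the threshold.
#' @export
empirical_pgain_threshold <- function(null_pgains, q = 0.95) {
  v <- sort(null_pgains[!is.na(null_pgains)])
  if (length(v) < 100) {
    stop("empirical_pgain_threshold: need >= 100 null values")
  }
  v[ceiling(q * length(v))]
}

#' Missingness-based presence-correlation test
#'
#' Tests whether co-associated metabolite pairs correlate more strongly
#' where their feature is detected. The observed statistic is the mean,
#' over trios whose feature is missing in at least `min_missing` samples,
#' of the Pearson correlation of the metabolite pair computed on
#' feature-present samples. The null repeats the computation on
#' `n_datasets` random datasets of `n_pairs` metabolite pairs matched by
#' correlation and sample size and imposed on the same feature presence
#' patterns; empirical P uses the add-one convention.
#'
#' @param trios data.frame from [find_co_associations()].
#' @param pool candidate metabolite pairs (data.frame with faecal_met_id,
#'   blood_met_id, r, n_complete), e.g. all cross-compartment pairs; see
#'   [all_metabolite_pairs()].
#' @param faecal,blood preprocessed metabolite matrices.
#' @param features preprocessed feature matrix (`NA` = not detected).
#' @param n_datasets number of null datasets (default 1000).
#' @param n_pairs pairs per null dataset (default 1000).
#' @param min_missing minimum missing observations of the feature
#'   (default 30).
#' @param tol_r,tol_n matching tolerances as in [match_null_pairs()].
#' @return list with `observed`, `null_means`, `empirical_p`,
#'   `n_trios_used`.
#' @export
presence_correlation_test <- function(trios, pool, faecal, blood, features,
                                      n_datasets = 1000, n_pairs = 1000,
                                      min_missing = 30, tol_r = 0.05,
                                      tol_n = 0.10) {
  n_missing <- vapply(trios$feature_id,
                      function(f) sum(is.na(features[, f])), numeric(1))
  use <- trios[n_missing >= min_missing, , drop = FALSE]
  if (nrow(use) == 0) {
    stop("presence_correlation_test: no trios with enough missing observations")
  }
  present <- lapply(use$feature_id, function(f) !is.na(features[, f]))
  r_present <- function(fm, bm, pr) {
    suppressWarnings(stats::cor(faecal[pr, fm], blood[pr, bm],
                                use = "pairwise.complete.obs"))
  }
  obs <- mean(vapply(seq_len(nrow(use)), function(i) {
    r_present(use$faecal_met_id[i], use$blood_met_id[i], present[[i]])
  }, numeric(1)), na.rm = TRUE)

  tkey <- paste(use$faecal_met_id, use$blood_met_id)
  pool <- pool[!(paste(pool$faecal_met_id, pool$blood_met_id) %in% tkey), ,
               drop = FALSE]
  # match on the metabolite pair's own correlation and pairwise-complete
  # sample size (the pool pairs are later combined with the target
  # features' presence patterns, which equalizes the effective n)
  use$n_complete <- vapply(seq_len(nrow(use)), function(i) {
    sum(!is.na(faecal[, use$faecal_met_id[i]]) &
          !is.na(blood[, use$blood_met_id[i]]))
  }, numeric(1))
  matched <- match_null_pairs(
    data.frame(r_observed = use$r_observed, n_complete = use$n_complete),
    pool, n_draws = 1, tol_r = tol_r, tol_n = tol_n)  # validates coverage
  nb <- attr(matched, "tol_r")  # tolerances actually used after widening
  tn <- attr(matched, "tol_n")
  neighbourhoods <- lapply(seq_len(nrow(use)), function(i) {
    which(abs(abs(pool$r) - abs(use$r_observed[i])) <= nb &
            abs(pool$n_complete - use$n_complete[i]) <=
              tn * use$n_complete[i])
  })
  cache <- new.env(parent = emptyenv())
  null_r <- function(t_idx, p_idx) {
    key <- paste(t_idx, p_idx)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- r_present(pool$faecal_met_id[p_idx], pool$blood_met_id[p_idx],
                     present[[t_idx]])
      cache[[key]] <- v
    }
    v
  }
  null_means <- vapply(seq_len(n_datasets), function(k) {
    tgt <- rep_len(seq_len(nrow(use)), n_pairs)
    mean(vapply(tgt, function(t_idx) {
      cand <- neighbourhoods[[t_idx]]
      p_idx <- if (length(cand) == 1) cand else sample(cand, 1)
      null_r(t_idx, p_idx)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(null_means >= obs)) / (1 + n_datasets)
  list(observed = obs, null_means = null_means, empirical_p = p,
       n_trios_used = nrow(use))
}

#' All cross-compartment metabolite pairs with correlation and size
#'
#' Convenience pool builder for [presence_correlation_test()].
#'
#' @param faecal,blood preprocessed metabolite matrices.
#' @return data.frame with faecal_met_id, blood_met_id, r, n_complete.
#' @export
all_metabolite_pairs <- function(faecal, blood) {
  r <- suppressWarnings(stats::cor(faecal, blood,
                                   use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(faecal), !is.na(blood))
  out <- data.frame(
    faecal_met_id = rep(colnames(faecal), times = ncol(blood)),
    blood_met_id = rep(colnames(blood), each = ncol(faecal)),
    r = as.vector(r), n_complete = as.vector(n),
    stringsAsFactors = FALSE)
  out[is.finite(out$r), , drop = FALSE]
}

#' Summarise the detected dialogue
#'
#' Fractions of distinct faecal metabolites, blood metabolites and
#' features appearing in at least one P-gain record passing the
#' threshold.
#'
#' @param records data.frame from [compute_pgain_records()].
#' @param threshold empirical P-gain threshold.
#' @param n_faecal_total,n_blood_total,n_features_total denominators
#'   (panel/feature-class sizes).
#' @return list with pass counts and coverage fractions.
#' @export
dialogue_summary <- function(records, threshold, n_faecal_total,
                             n_blood_total, n_features_total) {
  passing <- records[!is.na(records$pgain) & records$pgain >= threshold, ,
                     drop = FALSE]
  list(threshold = threshold,
       n_records = nrow(records),
       n_passing = nrow(passing),
       frac_faecal = length(unique(passing$faecal_met_id)) / n_faecal_total,
       frac_blood = length(unique(passing$blood_met_id)) / n_blood_total,
       frac_features = length(unique(passing$feature_id)) / n_features_total)
}
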