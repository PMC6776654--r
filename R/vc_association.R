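#' @title Variance-component association screen
#' @name vc_association
#' @description
#' Metagenome-wide association of metabolite levels with transformed
#' microbial feature abundances under the Gaussian variance-component
#' model `y ~ N(X beta, sigma_g^2 K + sigma_e^2 I)`, where `K` is the
#' pedigree-expected relatedness matrix. Fixed effects are tested by a
#' likelihood-ratio test (ML fits, chi-square with 1 df), and the screen
#' is FDR-controlled with Storey q-values.
NULL

# Profile-likelihood evaluator on the rotated scale. ty, tX live in the
# eigenbasis of K with eigenvalues d; the model is a weighted regression
# with weights w(h) = h d + (1 - h), profiled over total variance. Twin
# cohorts have very few distinct eigenvalues, so sufficient statistics
# are grouped by eigenvalue and each evaluation costs O(G p^2).
vc_profile <- function(ty, tX, d) {
  n <- length(ty)
  p <- ncol(tX)
  du <- as.character(round(d, 10))
  groups <- split(seq_len(n), du)
  dg <- as.numeric(names(groups))
  if (length(groups) <= 64) {
    G <- length(groups)
    Gx_flat <- vapply(groups, function(ix) {
      as.vector(crossprod(tX[ix, , drop = FALSE]))
    }, numeric(p * p))
    dim(Gx_flat) <- c(p * p, G)
    Gxy <- vapply(groups, function(ix) {
      as.vector(crossprod(tX[ix, , drop = FALSE], ty[ix]))
    }, numeric(p))
    dim(Gxy) <- c(p, G)
    Gyy <- vapply(groups, function(ix) sum(ty[ix]^2), numeric(1))
    ng <- lengths(groups)
    w_rows <- function(w) {
      out <- numeric(n)
      for (g in seq_along(groups)) out[groups[[g]]] <- w[g]
      out
    }
    function(h) {
      w <- h * dg + (1 - h)
      w[w < 1e-12] <- 1e-12
      iw <- 1 / w
      A <- matrix(Gx_flat %*% iw, p, p)
      b <- drop(Gxy %*% iw)
      beta <- tryCatch(drop(solve(A, b)), error = function(e) rep(NA_real_, p))
      if (anyNA(beta)) {
        # rank-deficient design on this subset: pivoted least squares
        sw <- 1 / sqrt(w_rows(w))
        fit <- stats::lm.fit(tX * sw, ty * sw)
        beta <- fit$coefficients
        rss <- sum(fit$residuals^2)
      } else {
        rss <- max(sum(Gyy * iw) - sum(b * beta), 0)
      }
      sigma2 <- max(rss / n, 1e-300)
      ll <- -0.5 * (n * log(2 * pi * sigma2) + n + sum(ng * log(w)))
      list(ll = ll, beta = beta, sigma2 = sigma2, A = A)
    }
  } else {
    function(h) {
      w <- h * d + (1 - h)
      w[w < 1e-12] <- 1e-12
      sw <- 1 / sqrt(w)
      Xw <- tX * sw
      fit <- stats::lm.fit(Xw, ty * sw)
      rss <- sum(fit$residuals^2)
      sigma2 <- max(rss / n, 1e-300)
      ll <- -0.5 * (n * log(2 * pi * sigma2) + n + sum(log(w)))
      list(ll = ll, beta = fit$coefficients, sigma2 = sigma2,
           A = crossprod(Xw))
    }
  }
}

# With singular MZ blocks the ML likelihood can diverge as h -> 1
# whenever a fixed effect can interpolate a twin-difference contrast, so
# the heritability ratio is bounded away from the singular boundary.
VC_H_MAX <- 0.99

vc_fit_rotated <- function(ty, tX, d, tol = 1e-8) {
  n <- length(ty)
  p <- ncol(tX)
  profile <- vc_profile(ty, tX, d)
  opt <- stats::optimize(function(h) -profile(h)$ll, c(0, VC_H_MAX), tol = tol)
  h_hat <- opt$minimum
  cand <- profile(h_hat)
  at0 <- profile(0)
  # prefer the h = 0 boundary when it is as good (within numerical noise):
  # with K = I the profile is flat in h and the model is plain OLS
  if (at0$ll >= cand$ll - 1e-9) { h_hat <- 0; cand <- at0 }
  covb <- tryCatch(solve(cand$A) * cand$sigma2, error = function(e) {
    matrix(NA_real_, p, p)
  })
  list(beta = cand$beta,
       se = sqrt(pmax(diag(covb), 0)),
       sigma_g2 = h_hat * cand$sigma2,
       sigma_e2 = (1 - h_hat) * cand$sigma2,
       h2 = h_hat,
       loglik = cand$ll,
       n = n,
       boundary = cand$sigma2 < 1e-12 || h_hat > VC_H_MAX - 1e-5)
}

# Grid-assisted refit used when the LRT statistic comes out negative
# beyond numerical noise: evaluate the profile on a coarse h grid and
# polish around the best point.
vc_fit_rotated_grid <- function(ty, tX, d, tol = 1e-10) {
  profile <- vc_profile(ty, tX, d)
  grid <- seq(0, VC_H_MAX, by = 0.01)
  vals <- vapply(grid, function(h) -profile(h)$ll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- min(grid[min(length(grid), i + 1)], VC_H_MAX)
  opt <- stats::optimize(function(h) -profile(h)$ll, c(lo, hi), tol = tol)
  h <- if (-vals[1] >= -opt$objective) 0 else opt$minimum
  fit <- vc_fit_rotated(ty, tX, d, tol = tol)
  cand <- profile(h)
  if (cand$ll > fit$loglik) {
    fit$loglik <- cand$ll
    fit$beta <- cand$beta
    fit$h2 <- h
    fit$sigma_g2 <- h * cand$sigma2
    fit$sigma_e2 <- (1 - h) * cand$sigma2
  }
  fit
}

#' Fit the variance-component model
#'
#' Maximum-likelihood estimates of `(beta, sigma_g^2, sigma_e^2)` for
#' `y ~ N(X beta, sigma_g^2 K + sigma_e^2 I)`, obtained by a 1-D search
#' over the heritability ratio `h = sigma_g^2 / (sigma_g^2 + sigma_e^2)`
#' after rotating into the eigenbasis of `K`. Singular (e.g. MZ-block) `K`
#' is handled without inversion.
#'
#' @param y response vector (no missing values; subset beforehand).
#' @param X fixed-effect design matrix, full column rank.
#' @param K relatedness matrix aligned with `y`.
#' @param tol convergence tolerance of the 1-D search.
#' @return list with `beta`, `se`, `sigma_g2`, `sigma_e2`, `h2`, `loglik`,
#'   `n` and a `boundary` flag.
#' @export
fit_vc <- function(y, X, K, tol = 1e-8) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X)) stop("fit_vc: complete cases only; drop missing rows first")
  n <- length(y)
  if (nrow(X) != n || nrow(K) != n) stop("fit_vc: dimension mismatch")
  if (n <= ncol(X)) stop("fit_vc: need more observations than fixed effects")
  if (qr(X)$rank < ncol(X)) stop("fit_vc: design matrix is rank-deficient")
  rot <- kinship_rotation(K)
  fit <- vc_fit_rotated(rot$rotate(y), rot$rotate(X), rot$values, tol = tol)
  if (fit$boundary) warning("fit_vc: boundary fit (residual variance ~ 0 or h ~ 1)")
  fit
}

#' Likelihood-ratio association test for one feature-metabolite pair
#'
#' Fits a null model (covariates only) and a full model (covariates plus
#' feature) by ML on the same complete-case set, and refers twice the
#' log-likelihood difference to chi-square with 1 df. Pairs with fewer
#' than `min_n` complete observations are skipped.
#'
#' @param metabolite response vector (preprocessed metabolite level).
#' @param feature predictor vector (transformed feature abundance).
#' @param covariates numeric matrix/data.frame of covariates or `NULL`.
#' @param K relatedness matrix aligned with the vectors.
#' @param min_n minimum complete observations (default 50).
#' @return list with `n`, `beta`, `se`, `p`, log-likelihoods; or `NULL`
#'   when skipped for insufficient observations.
#' @export
lrt_association <- function(metabolite, feature, covariates = NULL, K,
                            min_n = 50) {
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  idx <- !is.na(metabolite) & !is.na(feature)
  if (!is.null(cov_m)) idx <- idx & rowSums(is.na(cov_m)) == 0
  n <- sum(idx)
  p_fixed <- 2L + if (is.null(cov_m)) 0L else ncol(cov_m)
  if (n < max(min_n, p_fixed + 1)) return(NULL)
  Xn <- cbind(`(Intercept)` = rep(1, n), cov_m[idx, , drop = FALSE])
  Xf <- cbind(Xn, feature = feature[idx])
  rot <- kinship_rotation(K[idx, idx, drop = FALSE])
  ty <- rot$rotate(metabolite[idx])
  f0 <- vc_fit_rotated(ty, rot$rotate(Xn), rot$values)
  f1 <- vc_fit_rotated(ty, rot$rotate(Xf), rot$values)
  stat <- 2 * (f1$loglik - f0$loglik)
  if (stat < -1e-6) {
    f0 <- vc_fit_rotated_grid(ty, rot$rotate(Xn), rot$values)
    f1 <- vc_fit_rotated_grid(ty, rot$rotate(Xf), rot$values)
    stat <- 2 * (f1$loglik - f0$loglik)
  }
  stat <- max(stat, 0)
  k <- ncol(Xf)
  list(n = n,
       beta = unname(f1$beta[k]),
       se = unname(f1$se[k]),
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       loglik_full = f1$loglik,
       loglik_null = f0$loglik,
       h2 = f1$h2)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the lambda grid 0.05..0.90
#' (step 0.05) with a cubic smoothing spline evaluated at the largest
#' lambda (capped at 1), then computes adaptive FDR q-values. With fewer
#' than 100 P values the smoother is unstable and `pi0` falls back to 1
#' (making the result identical to Benjamini-Hochberg).
#'
#' @param p vector of P values in \[0, 1\].
#' @param pi0 optional fixed null proportion overriding estimation
#'   (`pi0 = 1` reproduces Benjamini-Hochberg exactly).
#' @param lambda tuning grid for the pi0 estimate.
#' @return q-values in the order of `p`; the `pi0` used is attached as an
#'   attribute.
#' @export
storey_qvalues <- function(p, pi0 = NULL,
                           lambda = seq(0.05, 0.90, by = 0.05)) {
  if (length(p) == 0) stop("storey_qvalues: empty P value vector")
  if (anyNA(p) || min(p) < 0 || max(p) > 1) {
    stop("storey_qvalues: P values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      warning("storey_qvalues: fewer than 100 P values; using pi0 = 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        warning("storey_qvalues: pi0 estimate <= 0; using 1/m")
        pi0 <- 1 / m
      }
    }
  }
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  # op order matches p.adjust's n/i * p so pi0 = 1 reproduces BH bit-exactly
  q <- numeric(m)
  q[o] <- cummin(pi0 * (m / r[o] * p[o]))
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Run a full association screen
#'
#' Tests every (feature, metabolite) pair with `lrt_association()` and
#' computes Storey q-values over the whole batch. Screens for different
#' feature classes and metabolite compartments should be run (and
#' FDR-adjusted) separately.
#'
#' @param metabolites samples x metabolites matrix (preprocessed).
#' @param features samples x features matrix (preprocessed; `NA` = absent).
#' @param covariates numeric matrix/data.frame of covariates or `NULL`.
#' @param K relatedness matrix aligned with the rows.
#' @param min_n minimum complete observations per pair (default 50).
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame with columns feature_id, metabolite_id, n, beta, se,
#'   p, q, significant; `pi0` attached as an attribute.
#' @export
run_screen <- function(metabolites, features, covariates = NULL, K,
                       min_n = 50, fdr = 0.05) {
  stopifnot(nrow(metabolites) == nrow(features), nrow(K) == nrow(features))
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cov_ok <- if (is.null(cov_m)) rep(TRUE, nrow(features)) else rowSums(is.na(cov_m)) == 0
  fids <- colnames(features) %||% paste0("F", seq_len(ncol(features)))
  mids <- colnames(metabolites) %||% paste0("M", seq_len(ncol(metabolites)))
  st <- kinship_structure(K)
  rot_cache <- new.env(parent = emptyenv())
  null_cache <- new.env(parent = emptyenv())
  out <- vector("list", ncol(features) * ncol(metabolites))
  nrec <- 0L
  p_fixed <- 2L + if (is.null(cov_m)) 0L else ncol(cov_m)
  for (fi in seq_len(ncol(features))) {
    feat <- features[, fi]
    f_ok <- !is.na(feat) & cov_ok
    for (mi in seq_len(ncol(metabolites))) {
      met <- metabolites[, mi]
      idx <- f_ok & !is.na(met)
      n <- sum(idx)
      if (n < max(min_n, p_fixed + 1)) next
      key <- paste0("k", paste(which(!idx), collapse = ","))
      ent <- rot_cache[[key]]
      if (is.null(ent)) {
        rot <- if (!is.null(st)) rotation_from_structure(st, which(idx))
               else kinship_rotation(K[idx, idx, drop = FALSE])
        Xn <- cbind(`(Intercept)` = rep(1, n),
                    if (is.null(cov_m)) NULL else cov_m[idx, , drop = FALSE])
        ent <- list(rot = rot, tXn = rot$rotate(Xn))
        rot_cache[[key]] <- ent
      }
      nkey <- paste(key, mi, sep = "|")
      nent <- null_cache[[nkey]]
      ty <- if (is.null(nent)) ent$rot$rotate(met[idx]) else nent$ty
      if (is.null(nent)) {
        f0 <- vc_fit_rotated(ty, ent$tXn, ent$rot$values)
        nent <- list(ty = ty, f0 = f0)
        null_cache[[nkey]] <- nent
      }
      tXf <- cbind(ent$tXn, feature = ent$rot$rotate(feat[idx]))
      f1 <- vc_fit_rotated(ty, tXf, ent$rot$values)
      stat <- 2 * (f1$loglik - nent$f0$loglik)
      if (stat < -1e-6) {
        f0g <- vc_fit_rotated_grid(ty, ent$tXn, ent$rot$values)
        f1 <- vc_fit_rotated_grid(ty, tXf, ent$rot$values)
        stat <- 2 * (f1$loglik - f0g$loglik)
      }
      stat <- max(stat, 0)
      k <- ncol(tXf)
      nrec <- nrec + 1L
      out[[nrec]] <- data.frame(
        feature_id = fids[fi], metabolite_id = mids[mi], n = n,
        beta = unname(f1$beta[k]), se = unname(f1$se[k]),
        p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (nrec == 0L) stop("run_screen: no testable pairs (min_n too high?)")
  res <- do.call(rbind, out[seq_len(nrec)])
  q <- suppressWarnings(storey_qvalues(res$p))
  res$q <- as.numeric(q)
  res$significant <- res$q <= fdr
  attr(res, "pi0") <- attr(q, "pi0")
  res
}

#' Compare two association screens run with different covariate sets
#'
#' Reports how many pairs are significant in both screens with concordant
#' effect direction, significant in only one, or sign-discordant.
#'
#' @param screen_a,screen_b association data.frames over the same pairs.
#' @param fdr significance threshold on q (default 0.05).
#' @return list with counts and the concordance fraction among pairs
#'   significant in both screens.
#' @export
covariate_sensitivity <- function(screen_a, screen_b, fdr = 0.05) {
  key_a <- paste(screen_a$feature_id, screen_a$metabolite_id)
  key_b <- paste(screen_b$feature_id, screen_b$metabolite_id)
  if (!setequal(key_a, key_b) || length(key_a) != length(key_b)) {
    stop("covariate_sensitivity: the two screens cover different pairs")
  }
  b <- screen_b[match(key_a, key_b), ]
  sig_a <- screen_a$q <= fdr
  sig_b <- b$q <= fdr
  both <- sig_a & sig_b
  concordant <- both & sign(screen_a$beta) == sign(b$beta)
  list(n_pairs = length(key_a),
       n_both = sum(both),
       n_concordant = sum(concordant),
       n_discordant = sum(both & !concordant),
       n_only_a = sum(sig_a & !sig_b),
       n_only_b = sum(sig_b & !sig_a),
       concordance = if (sum(both) == 0) NA_real_ else sum(concordant) / sum(both))
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("bonferroni_threshold: m must be >= 1")
  alpha / m
}
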