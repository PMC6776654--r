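# Small preprocessed world shared by the dialogue tests.
dialogue_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_mz_pairs = 50, n_dz_pairs = 50,
                          n_singletons = 60, n_species = 60,
                          n_pathways = 20, n_faecal_mets = 40,
                          n_blood_mets = 40, n_planted_effects = 8,
                          effect_size = 0.6, n_planted_trios = 4,
                          n_corr_pairs = 12, seed = 21)
      co <- simulate_cohort(spec)
      w <- list(
        co = co,
        sp_t = preprocess_features(co$species),
        fa_t = preprocess_metabolites(co$faecal, co$covariates$runday,
                                      scale = TRUE),
        bl_t = preprocess_metabolites(co$blood, co$covariates$runday,
                                      scale = FALSE),
        cov_m = cbind(sex = co$covariates$sex, age = co$covariates$age),
        fam = co$pedigree$family_id)
      w$K <- kinship_matrix(co$pedigree)
      w$sf <- run_screen(w$fa_t, w$sp_t, w$cov_m, w$K, 50)
      w$sb <- run_screen(w$bl_t, w$sp_t, w$cov_m, w$K, 50)
      cache <<- w
    }
    cache
  }
})

test_that("find_co_associations forms the cartesian trio set", {
  fa <- data.frame(feature_id = rep("f1", 2),
                   metabolite_id = c("fm1", "fm2"), q = 0.01)
  fb <- data.frame(feature_id = rep("f1", 3),
                   metabolite_id = c("bm1", "bm2", "bm3"), q = 0.01)
  n <- 150
  set.seed(1)
  fmat <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("fm1", "fm2")))
  bmat <- matrix(runif(n * 3), n, 3,
                 dimnames = list(NULL, c("bm1", "bm2", "bm3")))
  feat <- matrix(runif(n), n, 1, dimnames = list(NULL, "f1"))
  trios <- find_co_associations(fa, fb, fmat, bmat, feat, min_complete = 100)
  expect_equal(nrow(trios), 6)  # 2 x 3 cartesian
  # combinatorial identity: sum over features of (sig faecal x sig blood)
  expect_equal(nrow(trios), sum(table(fa$feature_id) * table(fb$feature_id)))
  # no overlap in significant features -> empty
  fb2 <- fb; fb2$feature_id <- "f2"
  expect_equal(nrow(find_co_associations(fa, fb2, fmat, bmat, feat, 100)), 0)
})

test_that("log_ratio and pgain arithmetic", {
  expect_equal(log_ratio(c(1, 2), c(1, 1)), c(0, 1))
  expect_equal(log_ratio(log(4), log(2)), log(2))
  expect_equal(log_ratio(c(1, NA), c(1, 1)), c(0, NA))
  expect_equal(pgain(0.01, 0.05, 0.001), 10)
  expect_equal(pgain(0.05, 0.01, 0.01), 1)
  expect_equal(pgain(1, 1, 1), 1)
  # scale-free in the three P values
  expect_equal(pgain(0.02, 0.04, 0.002), pgain(0.01, 0.02, 0.001))
  expect_error(pgain(0, 0.5, 0.5), "\\(0, 1\\]")
})

test_that("lmm_family_p equals OLS with singleton families and is calibrated", {
  set.seed(2)
  n <- 200
  x <- rnorm(n); y <- rnorm(n)
  fam <- as.character(seq_len(n))  # all singletons
  rec <- lmm_family_p(y, x, NULL, fam, min_n = 100)
  m0 <- lm(y ~ 1); m1 <- lm(y ~ x)
  p_ols <- pchisq(2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))),
                  1, lower.tail = FALSE)
  expect_lt(abs(rec$p - p_ols), 1e-6)
  # power at planted slope 0.5, n = 400
  set.seed(3)
  ok <- vapply(1:20, function(i) {
    xx <- rnorm(400)
    yy <- 0.5 * xx + rnorm(400)
    fam4 <- rep(as.character(1:200), each = 2)
    lmm_family_p(yy, xx, NULL, fam4, min_n = 100)$p < 0.001
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # calibration with family structure
  set.seed(4)
  fam2 <- rep(as.character(1:150), each = 2)
  ps <- replicate(300, {
    u <- rep(rnorm(150), each = 2)
    yy <- sqrt(0.4) * u + sqrt(0.6) * rnorm(300)
    lmm_family_p(yy, rnorm(300), NULL, fam2, min_n = 100)$p
  })
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("empirical_pgain_threshold uses the higher order statistic", {
  expect_equal(empirical_pgain_threshold(1:100), 95)
  expect_equal(empirical_pgain_threshold(rep(7, 150)), 7)
  expect_error(empirical_pgain_threshold(1:50), ">= 100")
})

test_that("match_null_pairs matches, widens once, then errors", {
  targets <- data.frame(r_observed = c(0.3, 0.5), n_complete = c(100, 200))
  pool <- data.frame(feature_id = "f", faecal_met_id = letters[1:4],
                     blood_met_id = LETTERS[1:4],
                     r = c(0.31, -0.49, 0.52, 0.1),
                     n_complete = c(105, 195, 205, 100))
  set.seed(5)
  m <- match_null_pairs(targets, pool, n_draws = 50)
  expect_equal(nrow(m), 50)
  # every draw satisfies the tolerances (|r| matching)
  dr <- abs(abs(m$r) - abs(targets$r_observed[m$target]))
  dn <- abs(m$n_complete - targets$n_complete[m$target]) /
    targets$n_complete[m$target]
  expect_true(all(dr <= 0.05 + 1e-12))
  expect_true(all(dn <= 0.10 + 1e-12))
  # exact copies match with zero discrepancy
  pool2 <- data.frame(feature_id = "f", faecal_met_id = c("x", "y"),
                      blood_met_id = c("X", "Y"),
                      r = targets$r_observed, n_complete = targets$n_complete)
  m2 <- match_null_pairs(targets, pool2, n_draws = 10)
  expect_true(all(abs(abs(m2$r) - abs(targets$r_observed[m2$target])) == 0))
  # unmatched target: widen once (warning) then error
  far <- data.frame(feature_id = "f", faecal_met_id = "z",
                    blood_met_id = "Z", r = 0.9, n_complete = 1000)
  expect_warning(expect_error(
    match_null_pairs(targets, far, n_draws = 5), "no matchable"),
    "doubling")
  expect_error(match_null_pairs(targets, far[0, ], 5), "empty pool")
})

test_that("planted dialogue is recovered end to end", {
  w <- dialogue_world()
  trios <- find_co_associations(w$sf, w$sb, w$fa_t, w$bl_t, w$sp_t,
                                min_complete = 100)
  truth <- w$co$truth$planted_trios
  tr_key <- paste(truth$feature_id, truth$faecal_met_id, truth$blood_met_id)
  k <- paste(trios$feature_id, trios$faecal_met_id, trios$blood_met_id)
  expect_gte(sum(k %in% tr_key), 3)  # >= 3 of 4 planted trios surface
  recs <- compute_pgain_records(trios, w$fa_t, w$bl_t, w$sp_t, w$cov_m,
                                w$fam, min_n = 100)
  pool <- build_null_pool(w$sf, w$sb, trios, w$fa_t, w$bl_t, w$sp_t)
  expect_true(all(pool$feature_id != "" & pool$faecal_met_id != ""))
  set.seed(6)
  suppressWarnings({
    matched <- match_null_pairs(recs, pool, n_draws = 500)
    np <- null_pgain_distribution(matched, w$fa_t, w$bl_t, w$sp_t, w$cov_m,
                                  w$fam, min_n = 100)
  })
  thr <- empirical_pgain_threshold(np)
  planted <- k %in% tr_key
  pass <- !is.na(recs$pgain) & recs$pgain >= thr
  expect_gte(sum(pass & planted) / sum(planted), 0.75)
  summ <- dialogue_summary(recs[pass | !pass, ], thr, ncol(w$fa_t),
                           ncol(w$bl_t), ncol(w$sp_t))
  expect_equal(summ$n_passing, sum(pass))
  expect_true(summ$frac_faecal >= 0 && summ$frac_faecal <= 1)
  # no record passes an infinite threshold
  summ0 <- dialogue_summary(recs, Inf, ncol(w$fa_t), ncol(w$bl_t),
                            ncol(w$sp_t))
  expect_equal(summ0$n_passing, 0)
  expect_equal(summ0$frac_faecal, 0)
})

test_that("presence_correlation_test flags the planted mediation", {
  w <- dialogue_world()
  trios <- find_co_associations(w$sf, w$sb, w$fa_t, w$bl_t, w$sp_t,
                                min_complete = 100)
  set.seed(7)
  suppressWarnings(
    pct <- presence_correlation_test(trios,
                                     all_metabolite_pairs(w$fa_t, w$bl_t),
                                     w$fa_t, w$bl_t, w$sp_t,
                                     n_datasets = 200, n_pairs = 100,
                                     min_missing = 30))
  expect_equal(pct$empirical_p, 1 / 201)
  expect_true(pct$observed > 0)
  expect_true(all(pct$null_means > -1 & pct$null_means < 1))
})

test_that("presence_correlation_test is exchangeability-valid under the null", {
  # a trio whose pair has the same homogeneous correlation structure as
  # every pool pair: its empirical P must be stochastically >= uniform,
  # never systematically extreme
  set.seed(8)
  one_run <- function() {
    n <- 300
    k <- 25
    fa <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("fm", 1:k)))
    bl <- sapply(1:k, function(j) 0.5 * fa[, j] + sqrt(0.75) * rnorm(n))
    colnames(bl) <- paste0("bm", 1:k)
    feat <- matrix(ifelse(runif(n) < 0.7, runif(n), NA), n, 1,
                   dimnames = list(NULL, "f1"))
    trio <- data.frame(feature_id = "f1", faecal_met_id = "fm1",
                       blood_met_id = "bm1",
                       n_complete = sum(!is.na(feat)),
                       r_observed = cor(fa[, 1], bl[, 1]))
    suppressWarnings(
      presence_correlation_test(trio, all_metabolite_pairs(fa, bl),
                                fa, bl, feat, n_datasets = 100,
                                n_pairs = 1, min_missing = 30))$empirical_p
  }
  ps <- replicate(50, one_run())
  expect_true(all(ps > 0 & ps <= 1))
  expect_lt(mean(ps <= 0.05), 0.2)   # ~0.05 expected; bug floors all of them
  expect_gt(mean(ps), 0.3)           # uniform-ish mean, not near 0
})
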