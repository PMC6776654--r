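test_that("generate_pedigree produces the requested family structure", {
  p <- generate_pedigree(cohort_spec(n_mz_pairs = 1, n_dz_pairs = 1,
                                     n_singletons = 1))
  expect_equal(nrow(p), 5)
  expect_equal(length(unique(p$family_id)), 3)
  expect_false(anyDuplicated(p$individual_id) > 0)
  # the cohort the generator emulates: 161 MZ + 201 DZ pairs + 280 singletons
  p2 <- generate_pedigree(cohort_spec(n_mz_pairs = 161, n_dz_pairs = 201,
                                      n_singletons = 280))
  expect_equal(nrow(p2), 1004)
  expect_equal(sum(p2$zygosity == "MZ", na.rm = TRUE), 322)
  expect_equal(sum(p2$zygosity == "DZ", na.rm = TRUE), 402)
  expect_equal(sum(is.na(p2$zygosity)), 280)
  expect_error(generate_pedigree(cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0,
                                             n_singletons = 0)),
               "empty cohort")
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_species = -1), ">= 0")
  expect_error(cohort_spec(heritability = 1.2), "\\[0, 1\\]")
  expect_error(cohort_spec(prevalence_range = c(0, 0.5)), "prevalence_range")
  expect_error(cohort_spec(prevalence_range = c(0.9, 0.1)), "prevalence_range")
})

test_that("species table is compositional, zero-inflated and honours prevalence", {
  spec <- small_spec()
  ped <- generate_pedigree(spec)
  x <- generate_species_table(spec, ped)
  expect_true(all(abs(rowSums(x) - 1) < 1e-9))
  expect_true(any(x == 0))
  expect_true(all(x >= 0))
  # prevalence_range (1, 1): no absent entries
  full <- generate_species_table(cohort_spec(prevalence_range = c(1, 1),
                                             n_mz_pairs = 5, n_dz_pairs = 5,
                                             n_singletons = 5, n_species = 10),
                                 generate_pedigree(small_spec()))
  expect_true(all(full > 0))
  # detection fraction within 3 binomial SEs at p = 0.5
  spec5 <- cohort_spec(n_mz_pairs = 50, n_dz_pairs = 50, n_singletons = 0,
                       n_species = 50, prevalence_range = c(0.5, 0.5), seed = 2)
  x5 <- generate_species_table(spec5, generate_pedigree(spec5))
  frac <- mean(x5 > 0)
  se <- sqrt(0.25 / length(x5))
  expect_lt(abs(frac - 0.5), 3 * se + 0.01)  # +0.01 for forced detections
  expect_error(generate_species_table(cohort_spec(n_species = 0), ped),
               "n_species")
})

test_that("pathway table: identity case, union property, redundancy correlation", {
  spec <- small_spec()
  ped <- generate_pedigree(spec)
  sp <- generate_species_table(spec, ped)
  # single pathway fed by one species, weight 1, no residual
  truth1 <- list(contribution_map = list(pwy_a = c(sp_001 = 1)))
  pw1 <- derive_pathway_table(sp, truth1)
  expect_equal(unname(pw1[, 1] > 0), unname(sp[, "sp_001"] > 0))
  # generated map: pathway prevalence >= each contributor's prevalence
  truth <- gutdialogue:::make_ground_truth(spec)
  pw <- derive_pathway_table(sp, truth)
  prev_sp <- colMeans(sp > 0)
  prev_pw <- colMeans(pw > 0)
  for (j in seq_along(truth$contribution_map)) {
    members <- names(truth$contribution_map[[j]])
    expect_gte(prev_pw[j], max(prev_sp[members]) - 1e-12)
  }
  # recomputed prevalence correlates positively with contributor count
  counts <- lengths(truth$contribution_map)
  expect_gt(suppressWarnings(cor(prev_pw, counts, method = "spearman")), 0)
  # empty contributor set with zero residual errors
  expect_error(derive_pathway_table(sp, list(contribution_map =
    list(bad = numeric(0)))), "no contributors")
})

test_that("metabolite tables carry the planted family and effect structure", {
  # MZ intraclass correlation of a null metabolite ~ heritability
  spec <- cohort_spec(n_mz_pairs = 200, n_dz_pairs = 0, n_singletons = 0,
                      n_species = 20, n_pathways = 5, n_faecal_mets = 6,
                      n_blood_mets = 6, n_planted_effects = 0,
                      n_planted_trios = 0, n_corr_pairs = 0,
                      heritability = 0.6, runday_sd = 0, missing_rate = 0,
                      seed = 3)
  co <- simulate_cohort(spec)
  l <- log(co$faecal[, 1])
  a <- l[seq(1, 400, 2)]; b <- l[seq(2, 400, 2)]
  icc <- cor(c(a, b), c(b, a))
  expect_lt(abs(icc - 0.6), 3 * (1 - 0.6^2) / sqrt(200))
  # heritability 0: co-twins uncorrelated
  spec0 <- cohort_spec(n_mz_pairs = 200, n_dz_pairs = 0, n_singletons = 0,
                       n_species = 20, n_pathways = 5, n_faecal_mets = 6,
                       n_blood_mets = 6, n_planted_effects = 0,
                       n_planted_trios = 0, n_corr_pairs = 0,
                       heritability = 0, runday_sd = 0, missing_rate = 0,
                       seed = 4)
  co0 <- simulate_cohort(spec0)
  l0 <- log(co0$faecal[, 1])
  icc0 <- cor(l0[seq(1, 400, 2)], l0[seq(2, 400, 2)])
  expect_lt(abs(icc0), 3 / sqrt(200))
  # planted slope recovered by OLS within 3 SEs
  spec_e <- cohort_spec(n_mz_pairs = 100, n_dz_pairs = 100, n_singletons = 0,
                        n_species = 40, n_pathways = 5, n_faecal_mets = 12,
                        n_blood_mets = 12, n_planted_effects = 4,
                        effect_size = 0.5, n_planted_trios = 0,
                        n_corr_pairs = 0, missing_rate = 0, seed = 5)
  co_e <- simulate_cohort(spec_e)
  eff <- co_e$truth$planted_effects[1, ]
  tf <- gutdialogue:::transformed_feature(co_e$species[, eff$feature_id])
  fit <- summary(lm(log(co_e$faecal[, eff$metabolite_id]) ~ tf))
  expect_lt(abs(fit$coefficients[2, 1] - eff$slope),
            3 * fit$coefficients[2, 2])
})

test_that("generate_metabolites errors when the variance budget is exceeded", {
  spec <- small_spec(heritability = 0.9, effect_size = 0.5)
  ped <- generate_pedigree(spec)
  sp <- generate_species_table(spec, ped)
  truth <- gutdialogue:::make_ground_truth(spec)
  pw <- derive_pathway_table(sp, truth)
  expect_error(generate_metabolites(spec, sp, pw, ped, truth),
               "residual variance")
})

test_that("plant_dialogue imposes present-subset correlation and leaves the rest", {
  set.seed(6)
  n <- 600
  fa <- matrix(exp(rnorm(n)), n, 2, dimnames = list(NULL, c("f1", "f2")))
  bl <- matrix(exp(rnorm(n)), n, 2, dimnames = list(NULL, c("b1", "b2")))
  mediator <- ifelse(runif(n) < 0.5, runif(n, 0.01, 0.2), 0)
  out <- plant_dialogue(fa, bl, "f1", "b1", mediator, 0.8)
  pres <- mediator > 0
  r_pres <- cor(log(fa[pres, "f1"]), log(out[pres, "b1"]))
  r_abs <- cor(log(fa[!pres, "f1"]), log(out[!pres, "b1"]))
  se <- 1 / sqrt(sum(pres))
  expect_lt(abs(r_pres - 0.8), 3 * se * (1 - 0.8^2) + 0.02)
  expect_lt(abs(r_abs), 3 / sqrt(sum(!pres)))
  expect_equal(out[!pres, "b1"], bl[!pres, "b1"])  # absent rows untouched
  expect_equal(out[, "b2"], bl[, "b2"])            # other columns untouched
  # strength 0 is the identity
  expect_identical(plant_dialogue(fa, bl, "f1", "b1", mediator, 0), bl)
  # mediator never present errors
  expect_error(plant_dialogue(fa, bl, "f1", "b1", rep(0, n), 0.5),
               "fewer than 10")
  expect_error(plant_dialogue(fa, bl, "f1", "b1", mediator, 1.5), "strength")
})

test_that("the generator is bit-deterministic given the spec", {
  co1 <- simulate_cohort(small_spec(seed = 9))
  co2 <- simulate_cohort(small_spec(seed = 9))
  expect_identical(co1$species, co2$species)
  expect_identical(co1$pathways, co2$pathways)
  expect_identical(co1$faecal, co2$faecal)
  expect_identical(co1$blood, co2$blood)
  expect_identical(co1$truth, co2$truth)
  co3 <- simulate_cohort(small_spec(seed = 10))
  expect_false(identical(co1$faecal, co3$faecal))
})

test_that("write_cohort emits the full TSV/JSON bundle that reads back", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_spec(seed = 2))
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  sp <- read_table(paths[["species"]], "features")
  expect_equal(sp, co$species, ignore_attr = TRUE, tolerance = 1e-12)
  ped <- read_table(paths[["pedigree"]], "pedigree")
  expect_equal(ped$individual_id, co$pedigree$individual_id)
})
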