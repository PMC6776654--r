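# Shared fixtures: small cohort specs and hand-built toy tables.

small_spec <- function(seed = 1, ...) {
  args <- list(n_mz_pairs = 30, n_dz_pairs = 30, n_singletons = 40,
               n_species = 40, n_pathways = 20, n_faecal_mets = 24,
               n_blood_mets = 24, n_planted_effects = 4,
               n_planted_trios = 2, n_corr_pairs = 8, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# deterministic twin pedigree + kinship for model tests
twin_kinship <- function(n_mz, n_dz, n_single = 0, seed = 1) {
  ped <- generate_pedigree(cohort_spec(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                                       n_singletons = n_single, seed = seed))
  list(pedigree = ped, K = kinship_matrix(ped))
}

# y with a family variance component matching the pedigree (uses the
# current RNG state, unlike the generator operations which re-seed)
simulate_family_y <- function(pedigree, h2, beta = 0, x = NULL) {
  n <- nrow(pedigree)
  fam <- numeric(n)
  for (f in unique(pedigree$family_id)) {
    rows <- which(pedigree$family_id == f)
    zy <- pedigree$zygosity[rows[1]]
    if (!is.na(zy) && zy == "DZ") {
      s <- stats::rnorm(1)
      fam[rows] <- sqrt(h2) * (sqrt(0.5) * s + sqrt(0.5) * stats::rnorm(2))
    } else {
      fam[rows] <- sqrt(h2) * stats::rnorm(1)
    }
  }
  y <- fam + sqrt(1 - h2) * stats::rnorm(n)
  if (!is.null(x)) y <- y + beta * x
  y
}
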