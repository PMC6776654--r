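#' @title Synthetic twin-cohort generator
#' @name synthetic_cohort
#' @description
#' Generates pedigrees, zero-inflated compositional feature tables,
#' log-scale metabolite panels and ground-truth labels with the
#' statistical structure the downstream analysis assumes: MZ/DZ/singleton
#' family structure, pathway abundances that are weighted sums of
#' contributing species, planted feature-to-metabolite effects, a family
#' (genetic) variance component, run-day batch shifts, and planted
#' mediated faecal-blood metabolite trios.
NULL

METABOLON_SUPER_PATHWAYS <- c(
  "amino acid", "carbohydrate", "cofactors and vitamins", "energy",
  "lipid", "nucleotide", "peptide", "xenobiotics")

#' Cohort specification
#'
#' Parameters of the synthetic twin cohort. Defaults mirror the structure
#' of the study cohort the generator emulates: 161 MZ pairs, 201 DZ pairs
#' and 280 singletons (n = 1004), predominantly female (96%) with mean
#' age 65; metabolite variance is budgeted on the standardized log scale
#' (family fraction `heritability`, planted fraction `effect_size^2`,
#' remainder residual).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons family-structure counts.
#' @param n_species,n_pathways microbial feature counts.
#' @param contribution_density probability a species contributes to a
#'   pathway.
#' @param prevalence_range interval of per-feature detection probability.
#' @param n_faecal_mets,n_blood_mets metabolite panel sizes.
#' @param n_planted_effects number of generic planted feature-metabolite
#'   effects per compartment (distinct features and metabolites).
#' @param effect_size standardized slope of planted effects.
#' @param heritability fraction of metabolite variance from the family
#'   component.
#' @param n_planted_trios number of mediated faecal-blood metabolite trios.
#' @param mediation_strength residual correlation induced between trio
#'   metabolites where the mediator species is present.
#' @param n_corr_pairs number of cross-compartment metabolite pairs with a
#'   homogeneous planted residual correlation, each member associated with
#'   a different feature. These pairs populate the "no interplay" null
#'   pool that correlation-matched P-gain calibration requires.
#' @param corr_range interval from which the correlation of those pairs is
#'   drawn.
#' @param n_rundays,runday_sd number of run-day batches and the SD of the
#'   per-(run-day, metabolite) log-scale shift.
#' @param missing_rate extra random missingness applied to the metabolite
#'   tables.
#' @param seed integer seed; identical specs give bit-identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 161, n_dz_pairs = 201, n_singletons = 280,
                        n_species = 100, n_pathways = 50,
                        contribution_density = 0.2,
                        prevalence_range = c(0.1, 0.95),
                        n_faecal_mets = 60, n_blood_mets = 60,
                        n_planted_effects = 15, effect_size = 0.5,
                        heritability = 0.4,
                        n_planted_trios = 5, mediation_strength = 0.8,
                        n_corr_pairs = 20, corr_range = c(0.2, 0.9),
                        n_rundays = 5, runday_sd = 0.3,
                        missing_rate = 0.05, seed = 1) {
  spec <- list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
               n_singletons = n_singletons, n_species = n_species,
               n_pathways = n_pathways,
               contribution_density = contribution_density,
               prevalence_range = prevalence_range,
               n_faecal_mets = n_faecal_mets, n_blood_mets = n_blood_mets,
               n_planted_effects = n_planted_effects,
               effect_size = effect_size, heritability = heritability,
               n_planted_trios = n_planted_trios,
               mediation_strength = mediation_strength,
               n_corr_pairs = n_corr_pairs, corr_range = corr_range,
               n_rundays = n_rundays, runday_sd = runday_sd,
               missing_rate = missing_rate, seed = as.integer(seed))
  counts <- c("n_mz_pairs", "n_dz_pairs", "n_singletons", "n_species",
              "n_pathways", "n_faecal_mets", "n_blood_mets",
              "n_planted_effects", "n_planted_trios", "n_corr_pairs",
              "n_rundays")
  for (f in counts) {
    if (spec[[f]] < 0) stop(sprintf("cohort_spec: %s must be >= 0", f))
  }
  probs <- c(contribution_density, heritability, mediation_strength,
             missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_spec: probabilities and heritability must lie in [0, 1]")
  }
  if (length(prevalence_range) != 2 || prevalence_range[1] > prevalence_range[2] ||
      prevalence_range[1] <= 0 || prevalence_range[2] > 1) {
    stop("cohort_spec: prevalence_range must be an interval within (0, 1]")
  }
  structure(spec, class = "cohort_spec")
}

#' Generate a twin-cohort pedigree
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `family_id`, `individual_id`, `zygosity`
#'   (`"MZ"`, `"DZ"`, or `NA` for singletons).
#' @export
generate_pedigree <- function(spec) {
  n_fam <- spec$n_mz_pairs + spec$n_dz_pairs + spec$n_singletons
  if (n_fam == 0) stop("generate_pedigree: empty cohort (all counts zero)")
  set.seed(spec$seed + 1L)
  fam <- character(0); ind <- character(0); zyg <- character(0)
  fam_i <- 0L; ind_i <- 0L
  add <- function(k, size, z) {
    for (i in seq_len(k)) {
      fam_i <<- fam_i + 1L
      fid <- sprintf("FAM%04d", fam_i)
      for (s in seq_len(size)) {
        ind_i <<- ind_i + 1L
        fam <<- c(fam, fid)
        ind <<- c(ind, sprintf("S%04d", ind_i))
        zyg <<- c(zyg, z)
      }
    }
  }
  add(spec$n_mz_pairs, 2, "MZ")
  add(spec$n_dz_pairs, 2, "DZ")
  add(spec$n_singletons, 1, NA_character_)
  data.frame(family_id = fam, individual_id = ind, zygosity = zyg,
             stringsAsFactors = FALSE)
}

#' Generate a zero-inflated compositional species table
#'
#' Per-entry log-normal intensities (mean 0, SD 1 on the log scale) are
#' masked by per-species Bernoulli detection with detection probabilities
#' drawn uniformly from `prevalence_range`, then closed so each sample's
#' detected abundances sum to 1. Every sample is guaranteed at least one
#' detected species (the most prevalent one is forced if needed).
#'
#' @param spec a [cohort_spec()].
#' @param pedigree pedigree data.frame (defines sample ids).
#' @param detect_prob optional per-species detection probabilities
#'   overriding the uniform draw.
#' @return samples x species relative-abundance matrix; undetected entries
#'   are exactly 0.
#' @export
generate_species_table <- function(spec, pedigree, detect_prob = NULL) {
  if (spec$n_species == 0) stop("generate_species_table: n_species must be > 0")
  if (nrow(pedigree) == 0) stop("generate_species_table: empty pedigree")
  set.seed(spec$seed + 2L)
  n <- nrow(pedigree)
  p <- spec$n_species
  if (is.null(detect_prob)) {
    detect_prob <- stats::runif(p, spec$prevalence_range[1], spec$prevalence_range[2])
  }
  intensity <- matrix(exp(stats::rnorm(n * p)), n, p)
  mask <- matrix(stats::rbinom(n * p, 1, rep(detect_prob, each = n)), n, p)
  x <- intensity * mask
  empty <- rowSums(x) == 0
  if (any(empty)) {
    j <- which.max(detect_prob)
    x[empty, j] <- exp(stats::rnorm(sum(empty)))
  }
  x <- x / rowSums(x)
  dimnames(x) <- list(pedigree$individual_id, sprintf("sp_%03d", seq_len(p)))
  attr(x, "detect_prob") <- detect_prob
  x
}

#' Derive a pathway table from species contributions
#'
#' Pathway abundance per sample is the weighted sum of contributing
#' species abundances plus a proportional "unclassified" residual term
#' (weights sum to `1 - residual`); a pathway is present iff any
#' contributing term is positive. Rows are renormalized to sum to 1 over
#' present pathways.
#'
#' @param species samples x species relative-abundance matrix.
#' @param truth ground-truth list holding `contribution_map` (pathway ->
#'   named non-negative species weights summing to <= 1).
#' @return samples x pathways relative-abundance matrix.
#' @export
derive_pathway_table <- function(species, truth) {
  cmap <- truth$contribution_map
  n <- nrow(species)
  raw <- matrix(0, n, length(cmap),
                dimnames = list(rownames(species), names(cmap)))
  for (j in seq_along(cmap)) {
    w <- cmap[[j]]
    csum <- sum(w)
    if (length(w) == 0 || csum == 0) {
      # the unclassified residual scales with the classified contribution,
      # so a pathway with no contributors has no abundance source at all
      stop(sprintf("derive_pathway_table: pathway %s has no contributors",
                   names(cmap)[j]))
    }
    missing_sp <- setdiff(names(w), colnames(species))
    if (length(missing_sp)) {
      stop(sprintf("derive_pathway_table: unknown species %s in contribution map",
                   missing_sp[1]))
    }
    contrib <- species[, names(w), drop = FALSE] %*% w
    # unclassified residual scales with the classified contribution, so
    # presence equals the union of contributor presence
    raw[, j] <- contrib / csum
  }
  rs <- rowSums(raw)
  ok <- rs > 0
  raw[ok, ] <- raw[ok, , drop = FALSE] / rs[ok]
  raw
}

# Choose planted features/metabolites, contribution map and annotations.
make_ground_truth <- function(spec) {
  set.seed(spec$seed + 3L)
  sp_ids <- sprintf("sp_%03d", seq_len(spec$n_species))
  pw_ids <- sprintf("pwy_%03d", seq_len(spec$n_pathways))
  f_ids <- sprintf("fmet_%03d", seq_len(spec$n_faecal_mets))
  b_ids <- sprintf("bmet_%03d", seq_len(spec$n_blood_mets))

  need_sp <- 2 * spec$n_planted_effects + spec$n_planted_trios +
    2 * spec$n_corr_pairs
  if (need_sp > spec$n_species) {
    stop("make_ground_truth: not enough species for the requested plantings")
  }
  need_f <- spec$n_planted_effects + spec$n_planted_trios + spec$n_corr_pairs
  need_b <- need_f
  if (need_f > spec$n_faecal_mets || need_b > spec$n_blood_mets) {
    stop("make_ground_truth: not enough metabolites for the requested plantings")
  }
  sp_pool <- sample(sp_ids, need_sp)
  take <- function(k) {
    out <- sp_pool[seq_len(k)]
    sp_pool <<- sp_pool[-seq_len(k)]
    out
  }
  pe_f_sp <- take(spec$n_planted_effects)
  pe_b_sp <- take(spec$n_planted_effects)
  trio_sp <- take(spec$n_planted_trios)
  cp_f_sp <- take(spec$n_corr_pairs)
  cp_b_sp <- take(spec$n_corr_pairs)

  idx_f <- seq_len(need_f)
  pe_f_met <- f_ids[seq_len(spec$n_planted_effects)]
  trio_f_met <- f_ids[spec$n_planted_effects + seq_len(spec$n_planted_trios)]
  cp_f_met <- f_ids[spec$n_planted_effects + spec$n_planted_trios +
                      seq_len(spec$n_corr_pairs)]
  pe_b_met <- b_ids[seq_len(spec$n_planted_effects)]
  trio_b_met <- b_ids[spec$n_planted_effects + seq_len(spec$n_planted_trios)]
  cp_b_met <- b_ids[spec$n_planted_effects + spec$n_planted_trios +
                      seq_len(spec$n_corr_pairs)]

  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  block <- function(features, mets, comp, slopes) {
    if (length(features) == 0) return(NULL)
    data.frame(feature_id = features, metabolite_id = mets,
               compartment = rep(comp, length(features)), slope = slopes,
               stringsAsFactors = FALSE)
  }
  # trio: production into faeces and opposite-signed effect in blood
  # (microbes modulating absorption show opposite effect directions in
  # the two compartments), so the metabolite ratio keeps a feature
  # signal while the mediated residual correlation cancels
  eff <- rbind(
    block(pe_f_sp, pe_f_met, "faecal",
          spec$effect_size * sgn(spec$n_planted_effects)),
    block(pe_b_sp, pe_b_met, "blood",
          spec$effect_size * sgn(spec$n_planted_effects)),
    block(trio_sp, trio_f_met, "faecal",
          rep(spec$effect_size, spec$n_planted_trios)),
    block(trio_sp, trio_b_met, "blood",
          rep(-spec$effect_size, spec$n_planted_trios)),
    block(cp_f_sp, cp_f_met, "faecal",
          spec$effect_size * sgn(spec$n_corr_pairs)),
    block(cp_b_sp, cp_b_met, "blood",
          spec$effect_size * sgn(spec$n_corr_pairs)))
  if (is.null(eff)) {
    eff <- data.frame(feature_id = character(0), metabolite_id = character(0),
                      compartment = character(0), slope = numeric(0),
                      stringsAsFactors = FALSE)
  }
  eff <- eff[eff$slope != 0, , drop = FALSE]

  trios <- data.frame(feature_id = trio_sp, faecal_met_id = trio_f_met,
                      blood_met_id = trio_b_met,
                      strength = rep(spec$mediation_strength,
                                     spec$n_planted_trios),
                      stringsAsFactors = FALSE)
  corr_pairs <- data.frame(
    faecal_met_id = cp_f_met, blood_met_id = cp_b_met,
    faecal_feature_id = cp_f_sp, blood_feature_id = cp_b_sp,
    rho = if (spec$n_corr_pairs)
      stats::runif(spec$n_corr_pairs, spec$corr_range[1], spec$corr_range[2])
    else numeric(0),
    stringsAsFactors = FALSE)

  cmap <- vector("list", spec$n_pathways)
  names(cmap) <- pw_ids
  for (j in seq_len(spec$n_pathways)) {
    members <- sp_ids[stats::runif(spec$n_species) < spec$contribution_density]
    if (length(members) == 0) members <- sample(sp_ids, 1)
    w <- stats::runif(length(members))
    resid <- stats::runif(1, 0, 0.3)
    w <- w / sum(w) * (1 - resid)
    names(w) <- members
    cmap[[j]] <- w
  }

  ann <- data.frame(
    metabolite_id = c(f_ids, b_ids),
    compartment = rep(c("faecal", "blood"), c(length(f_ids), length(b_ids))),
    compound_key = sprintf("CK%04d", c(seq_along(f_ids),
                                       length(f_ids) + seq_along(b_ids))),
    super_pathway = sample(METABOLON_SUPER_PATHWAYS,
                           length(f_ids) + length(b_ids), replace = TRUE),
    stringsAsFactors = FALSE)
  linked <- ann$compound_key[stats::runif(nrow(ann)) < 0.3]
  cp_map <- if (length(linked)) {
    do.call(rbind, lapply(linked, function(ck) {
      data.frame(compound_key = ck,
                 pathway_id = sample(pw_ids, sample(1:3, 1)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(compound_key = character(0), pathway_id = character(0))
  }

  list(planted_effects = eff, planted_trios = trios,
       corr_pairs = corr_pairs, contribution_map = cmap,
       annotation = ann, compound_pathway_map = cp_map,
       trio_features = trio_sp)
}

# Transformed (arcsine-sqrt, standardized) feature with zeros kept as 0,
# the scale planted slopes act on.
transformed_feature <- function(x) {
  t <- asin(sqrt(x))
  s <- stats::sd(t)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (t - mean(t)) / s
}

#' Generate faecal and blood metabolite tables
#'
#' Log-metabolite levels follow a linear model: intercept + planted
#' feature effects (on the standardized arcsine-sqrt abundance scale) +
#' sex and age effects + a family random effect with variance
#' `heritability` + a per-(run-day, metabolite) batch shift + residual.
#' Intensities are the exponential of that; `missing_rate` of entries are
#' then set missing at random.
#'
#' @param spec a [cohort_spec()].
#' @param species,pathways feature tables sharing sample ids with the
#'   pedigree.
#' @param pedigree pedigree data.frame.
#' @param truth ground truth from the generator.
#' @return list with `faecal`, `blood` (intensity matrices) and
#'   `covariates` (data.frame: sample_id, sex, age, runday).
#' @export
generate_metabolites <- function(spec, species, pathways, pedigree, truth) {
  set.seed(spec$seed + 4L)
  n <- nrow(pedigree)
  stopifnot(identical(rownames(species), pedigree$individual_id))
  h <- spec$heritability

  sex <- stats::rbinom(n, 1, 0.04)            # ~96% female cohort
  age <- pmin(pmax(stats::rnorm(n, 65, 8), 18), 90)
  runday <- sample(seq_len(max(spec$n_rundays, 1)), n, replace = TRUE)
  age_std <- if (stats::sd(age) > 0) (age - mean(age)) / stats::sd(age) else age * 0

  # family effect, drawn independently for every metabolite: MZ co-twins
  # share the family draw, DZ co-twins mix it half-and-half with an
  # individual draw (within-pair correlation 0.5), singletons get their
  # own. Coefficients per sample; the per-metabolite draws happen in
  # family_effect_matrix() below.
  fams <- unique(pedigree$family_id)
  fam_index <- match(pedigree$family_id, fams)
  dz <- !is.na(pedigree$zygosity) & pedigree$zygosity == "DZ"
  c_shared <- ifelse(dz, sqrt(0.5), 1)
  c_indiv <- ifelse(dz, sqrt(0.5), 0)
  family_effect_matrix <- function(p) {
    shared <- matrix(stats::rnorm(length(fams) * p), length(fams), p)
    indiv <- matrix(stats::rnorm(n * p), n, p)
    sqrt(h) * (c_shared * shared[fam_index, , drop = FALSE] +
                 c_indiv * indiv)
  }

  tfeat <- apply(species, 2, transformed_feature)
  rownames(tfeat) <- rownames(species)

  build <- function(met_ids, compartment) {
    p <- length(met_ids)
    eff <- truth$planted_effects
    eff <- eff[eff$compartment == compartment, , drop = FALSE]
    planted_var <- numeric(p)
    names(planted_var) <- met_ids
    if (nrow(eff)) {
      pv <- tapply(eff$slope^2, eff$metabolite_id, sum)
      planted_var[names(pv)] <- pv
    }
    if (any(h + planted_var >= 1)) {
      stop("generate_metabolites: heritability + planted variance >= 1 ",
           "(non-positive residual variance)")
    }
    resid_sd <- sqrt(1 - h - planted_var)
    mu <- stats::rnorm(p, 3, 0.5)
    shift <- matrix(stats::rnorm(max(spec$n_rundays, 1) * p, 0, spec$runday_sd),
                    max(spec$n_rundays, 1), p)
    resid <- matrix(stats::rnorm(n * p), n, p)
    resid <- sweep(resid, 2, resid_sd, "*")
    list(met_ids = met_ids, mu = mu, shift = shift, resid = resid,
         resid_sd = resid_sd, eff = eff, fam_eff = family_effect_matrix(p))
  }

  fa <- build(sprintf("fmet_%03d", seq_len(spec$n_faecal_mets)), "faecal")
  bl <- build(sprintf("bmet_%03d", seq_len(spec$n_blood_mets)), "blood")

  # homogeneous cross-compartment residual correlation for the null pool
  cp <- truth$corr_pairs
  if (nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      fj <- match(cp$faecal_met_id[i], fa$met_ids)
      bj <- match(cp$blood_met_id[i], bl$met_ids)
      zf <- fa$resid[, fj] / fa$resid_sd[fj]
      bl$resid[, bj] <- bl$resid_sd[bj] *
        (cp$rho[i] * zf + sqrt(1 - cp$rho[i]^2) * stats::rnorm(n))
    }
  }

  assemble <- function(comp) {
    p <- length(comp$met_ids)
    logm <- matrix(rep(comp$mu, each = n), n, p) +
      comp$shift[runday, , drop = FALSE] +
      comp$resid + comp$fam_eff +
      0.2 * sex + 0.1 * age_std
    if (nrow(comp$eff)) {
      for (i in seq_len(nrow(comp$eff))) {
        j <- match(comp$eff$metabolite_id[i], comp$met_ids)
        logm[, j] <- logm[, j] +
          comp$eff$slope[i] * tfeat[, comp$eff$feature_id[i]]
      }
    }
    x <- exp(logm)
    if (spec$missing_rate > 0) {
      x[stats::runif(n * p) < spec$missing_rate] <- NA_real_
    }
    dimnames(x) <- list(pedigree$individual_id, comp$met_ids)
    x
  }

  faecal <- assemble(fa)
  blood <- assemble(bl)
  covariates <- data.frame(sample_id = pedigree$individual_id,
                           sex = sex, age = age, runday = runday,
                           stringsAsFactors = FALSE)
  list(faecal = faecal, blood = blood, covariates = covariates)
}

#' Plant a mediated faecal-blood metabolite correlation
#'
#' Among samples where the mediator feature is detected, the blood
#' metabolite's residual (after removing each metabolite's linear
#' dependence on the mediator's transformed abundance) is redrawn so its
#' partial correlation with the faecal metabolite equals `strength`.
#' Samples where the mediator is absent are left untouched, so
#' absent-subset independence is exact by construction. Uses the current
#' RNG state.
#'
#' @param faecal,blood metabolite intensity matrices (positive values).
#' @param faecal_met,blood_met column names of the trio metabolites.
#' @param mediator the mediator feature's abundance vector (presence is
#'   `> 0` and non-missing).
#' @param strength target partial correlation in \[0, 1\]; 0 returns
#'   `blood` unchanged.
#' @return modified blood matrix.
#' @export
plant_dialogue <- function(faecal, blood, faecal_met, blood_met, mediator,
                           strength) {
  if (strength < 0 || strength > 1) stop("plant_dialogue: strength must be in [0, 1]")
  if (strength == 0) return(blood)
  present <- !is.na(mediator) & mediator > 0
  if (sum(present) < 10) {
    stop("plant_dialogue: mediator present in fewer than 10 samples")
  }
  lf <- log(faecal[, faecal_met])
  lb <- log(blood[, blood_met])
  idx <- which(present & !is.na(lf) & !is.na(lb))
  t <- transformed_feature(ifelse(is.na(mediator), 0, mediator))
  fit_b <- stats::lm.fit(cbind(1, t[idx]), lb[idx])
  fit_f <- stats::lm.fit(cbind(1, t[idx]), lf[idx])
  sd_b <- stats::sd(fit_b$residuals)
  sd_f <- stats::sd(fit_f$residuals)
  if (sd_b == 0 || sd_f == 0) stop("plant_dialogue: degenerate metabolite column")
  zf <- fit_f$residuals / sd_f
  new_resid <- sd_b * (strength * zf +
                         sqrt(1 - strength^2) * stats::rnorm(length(idx)))
  lb[idx] <- fit_b$fitted.values + new_resid
  blood[, blood_met] <- ifelse(is.na(blood[, blood_met]),
                               NA_real_, exp(lb))
  blood
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: pedigree, ground truth, species and pathway
#' tables, metabolite panels, and planted mediated trios.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `gut_cohort` with elements `pedigree`, `species`,
#'   `pathways`, `faecal`, `blood`, `covariates`, `truth` and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pedigree <- generate_pedigree(spec)
  truth <- make_ground_truth(spec)
  # trio mediators need both enough present (>= 100 for the P-gain stage)
  # and enough absent (>= 30 for the missingness simulation) samples
  set.seed(spec$seed + 2L)
  dp <- stats::runif(spec$n_species, spec$prevalence_range[1],
                     spec$prevalence_range[2])
  names(dp) <- sprintf("sp_%03d", seq_len(spec$n_species))
  if (length(truth$trio_features)) {
    dp[truth$trio_features] <- stats::runif(length(truth$trio_features),
                                            0.6, 0.8)
  }
  species <- generate_species_table(spec, pedigree, detect_prob = dp)
  pathways <- derive_pathway_table(species, truth)
  mets <- generate_metabolites(spec, species, pathways, pedigree, truth)
  faecal <- mets$faecal
  blood <- mets$blood
  if (nrow(truth$planted_trios)) {
    for (i in seq_len(nrow(truth$planted_trios))) {
      tr <- truth$planted_trios[i, ]
      set.seed(spec$seed + 100L + i)
      blood <- plant_dialogue(faecal, blood, tr$faecal_met_id,
                              tr$blood_met_id, species[, tr$feature_id],
                              tr$strength)
    }
  }
  structure(list(pedigree = pedigree, species = species, pathways = pathways,
                 faecal = faecal, blood = blood,
                 covariates = mets$covariates, truth = truth, spec = spec),
            class = "gut_cohort")
}

#' Write a simulated cohort to TSV files
#'
#' Writes species.tsv, pathways.tsv, faecal_mets.tsv, blood_mets.tsv,
#' pedigree.tsv, covariates.tsv, annotation.tsv,
#' compound_pathway_map.tsv and truth.json into `dir`.
#'
#' @param cohort a `gut_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    species = file.path(dir, "species.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    faecal = file.path(dir, "faecal_mets.tsv"),
    blood = file.path(dir, "blood_mets.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    cmap = file.path(dir, "compound_pathway_map.tsv"),
    truth = file.path(dir, "truth.json"))
  write_matrix_tsv(cohort$species, paths["species"])
  write_matrix_tsv(cohort$pathways, paths["pathways"])
  write_matrix_tsv(cohort$faecal, paths["faecal"])
  write_matrix_tsv(cohort$blood, paths["blood"])
  utils::write.table(cohort$pedigree, paths["pedigree"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$covariates, paths["covariates"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$truth$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$truth$compound_pathway_map, paths["cmap"],
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  truth_json <- list(
    planted_effects = cohort$truth$planted_effects,
    planted_trios = cohort$truth$planted_trios,
    corr_pairs = cohort$truth$corr_pairs,
    contribution_map = lapply(cohort$truth$contribution_map, as.list))
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
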