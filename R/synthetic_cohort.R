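# Synthetic case-control cohorts with the statistical structure the
# analysis assumes: HWE genotypes, a weighted score with a known per-SD
# effect on CAD, beta-distributed calcification linked to the score, and
# questionnaire-style missingness for the autopsy flavor.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate a clinical angiography cohort: 11 independent scored
#' SNPs under Hardy-Weinberg equilibrium, a standardized score with per-SD
#' odds ratio 1.4 on CAD, and a 70/30 case/control imbalance. The generative
#' CAD model is exactly the model-2 covariate structure (score + risk
#' factors), so `per_sd_or_cad` is the estimand of the fitted model-2 score
#' term; the second (metaGRS-like) score has a null effect by default
#' (`per_sd_or_meta = 1`) and is plumbing for joint-score analyses.
#' Continuous covariate effects are log-odds per SD of the covariate; binary
#' effects are log-odds for the 0/1 indicator.
#'
#' @param n_samples Cohort size.
#' @param flavor `"clinical"` (lipids/BP available) or `"autopsy"` (age,
#'   sex, BMI plus questionnaire smoking/hypertension and morphometric
#'   calcification/stenosis).
#' @param n_score_snps Number of scored SNPs (default 11).
#' @param n_meta_snps Number of SNPs in the metaGRS-like stand-in score
#'   (default 1000, a computational stand-in for a genome-wide score).
#' @param maf_range Allele-frequency range for simulated SNPs.
#' @param per_sd_or_cad True per-SD odds ratio of the score on CAD.
#' @param per_sd_or_meta True per-SD odds ratio of the second score.
#' @param covariate_effects Named log-OR map for covariates; `NULL` picks
#'   flavor defaults.
#' @param target_case_fraction Desired case fraction; the intercept is
#'   calibrated by bisection to reach it (tolerance 1e-4 on the mean
#'   probability).
#' @param calc_link `c(intercept, score_coef, age_coef)` on the logit-mean
#'   scale for calcified-area proportions (autopsy flavor).
#' @param calc_phi Beta-regression precision of simulated calcification.
#' @param missing_rate_lifestyle Fraction of samples whose questionnaire
#'   covariates (smoking, hypertension treatment) are masked jointly;
#'   default 0.655 for the autopsy flavor, 0 otherwise.
#' @param missing_rate_core Fraction of samples whose coronary measurements
#'   (CAD label, stenosis, calcification) are masked jointly (autopsy
#'   flavor; deaths without coronary morphometry).
#' @param dosage_noise_sd SD of Gaussian noise added to hard-call dosages
#'   (clipped to \[0, 2\]) to mimic imputation uncertainty.
#' @param tau SD of the raw SNP weights before rescaling; `tau = 0` yields
#'   an all-zero (degenerate) score.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples, flavor = c("clinical", "autopsy"),
                       n_score_snps = 11, n_meta_snps = 1000,
                       maf_range = c(0.05, 0.5), per_sd_or_cad = 1.4,
                       per_sd_or_meta = 1, covariate_effects = NULL,
                       target_case_fraction = 0.70,
                       calc_link = c(-1.8, log(1.78), 0.5), calc_phi = 5,
                       missing_rate_lifestyle = NULL, missing_rate_core = 0,
                       dosage_noise_sd = 0, tau = 1, seed = 1) {
  flavor <- match.arg(flavor)
  if (is.null(missing_rate_lifestyle)) {
    missing_rate_lifestyle <- if (flavor == "autopsy") 0.655 else 0
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- if (flavor == "clinical") {
      c(age = 0.5, sex_male = 1.0, smoking = 0.6, hdl_chol = -0.25,
        total_chol = -0.05, sbp = 0.1, htn_med = 0.28)
    } else {
      c(age = 0.55, sex_male = 0.3, smoking = 0.6, htn_med = 0.25)
    }
  }
  stopifnot(n_samples >= 2, n_score_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            per_sd_or_cad > 0, per_sd_or_meta > 0, calc_phi > 0,
            target_case_fraction > 0, target_case_fraction < 1,
            missing_rate_lifestyle >= 0, missing_rate_lifestyle <= 1,
            missing_rate_core >= 0, missing_rate_core <= 1,
            dosage_noise_sd >= 0)
  structure(list(
    n_samples = n_samples, flavor = flavor, n_score_snps = n_score_snps,
    n_meta_snps = n_meta_snps, maf_range = maf_range,
    per_sd_or_cad = per_sd_or_cad, per_sd_or_meta = per_sd_or_meta,
    covariate_effects = covariate_effects,
    target_case_fraction = target_case_fraction, calc_link = calc_link,
    calc_phi = calc_phi, missing_rate_lifestyle = missing_rate_lifestyle,
    missing_rate_core = missing_rate_core,
    dosage_noise_sd = dosage_noise_sd, tau = tau, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Preset configurations mirroring the three cohort designs
#'
#' `"luric"`: clinical angiography cohort, n = 2742, 70\% cases.
#' `"tvs"`: small clinical cohort, n = 133, 74\% cases.
#' `"tsds"`: autopsy cohort, n = 660 of which 622 have coronary
#' morphometry, balanced-ish cases (52.6\%), questionnaire covariates
#' available for 34.5\% of samples.
#'
#' @param preset `"luric"`, `"tvs"` or `"tsds"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_config <- function(preset = c("luric", "tvs", "tsds"), seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    luric = list(n_samples = 2742, flavor = "clinical",
                 target_case_fraction = 1912 / 2742),
    tvs = list(n_samples = 133, flavor = "clinical",
               target_case_fraction = 98 / 133),
    tsds = list(n_samples = 660, flavor = "autopsy",
                target_case_fraction = 327 / 622,
                missing_rate_lifestyle = 432 / 660,
                missing_rate_core = 38 / 660)
  )
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  cfg <- do.call(sim_config, args)
  attr(cfg, "preset") <- preset
  cfg
}

non_palindromic_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T")
)

#' Generate a synthetic variant-weights table
#'
#' Variant IDs, non-palindromic allele pairs, allele frequencies uniform on
#' `maf_range` and Gaussian weights rescaled so that the raw score has unit
#' SD in expectation under Hardy-Weinberg (`sum(w^2 * 2 f (1 - f)) = 1`).
#' Uses the current RNG state.
#'
#' @param n_snps Number of variants.
#' @param maf_range Frequency range.
#' @param tau Weight SD before rescaling; 0 gives all-zero weights.
#' @param id_prefix Prefix for generated variant IDs.
#' @return A `grs_weights` data frame with a `freq` attribute (the true
#'   effect-allele frequencies).
#' @export
gen_weights <- function(n_snps, maf_range = c(0.05, 0.5), tau = 1,
                        id_prefix = "rs") {
  pair <- non_palindromic_pairs[
    sample.int(nrow(non_palindromic_pairs), n_snps, replace = TRUE), ,
    drop = FALSE]
  freq <- stats::runif(n_snps, maf_range[1], maf_range[2])
  w <- stats::rnorm(n_snps, 0, tau)
  if (tau > 0) {
    v <- sum(w^2 * 2 * freq * (1 - freq))
    w <- w / sqrt(v)
  }
  out <- data.frame(
    variant_id = paste0(id_prefix, sample.int(1e7, n_snps)),
    chromosome = as.character(sample.int(22, n_snps, replace = TRUE)),
    position = sample.int(2e8, n_snps),
    effect_allele = pair[, 1], other_allele = pair[, 2],
    effect_weight = w, imputation_r2 = round(stats::runif(n_snps, 0.31, 1), 3),
    stringsAsFactors = FALSE
  )
  class(out) <- c("grs_weights", "data.frame")
  attr(out, "freq") <- freq
  out
}

#' Generate Hardy-Weinberg genotype dosages
#'
#' Hard dosages are Binomial(2, f) per sample and variant (independent SNPs,
#' no LD); optional Gaussian noise clipped to \[0, 2\] mimics imputation
#' uncertainty. Uses the current RNG state.
#'
#' @param weights A `grs_weights` with a `freq` attribute (or a numeric
#'   frequency vector with a `variant_id` names attribute).
#' @param n_samples Number of samples.
#' @param dosage_noise_sd Noise SD (default 0: hard calls only).
#' @param sample_ids Optional sample IDs.
#' @return A `dosage_matrix` coded to the effect alleles (file ALT = effect
#'   allele).
#' @export
gen_genotypes <- function(weights, n_samples, dosage_noise_sd = 0,
                          sample_ids = NULL) {
  freq <- attr(weights, "freq")
  n_var <- nrow(weights)
  d <- matrix(stats::rbinom(n_samples * n_var, 2, rep(freq, each = n_samples)),
              nrow = n_samples)
  if (dosage_noise_sd > 0) {
    d <- d + stats::rnorm(length(d), 0, dosage_noise_sd)
    d <- pmin(pmax(d, 0), 2)
  }
  new_dosage_matrix(
    d, sample_ids = sample_ids %||% sprintf("S%05d", seq_len(n_samples)),
    variant_ids = weights$variant_id,
    ref = weights$other_allele, alt = weights$effect_allele
  )
}

#' Generate covariates for a synthetic cohort
#'
#' Clinical flavor: age ~ N(62, 10) clipped to \[18, 95\], male ~
#' Bernoulli(0.72), BMI ~ N(27.5, 4), SBP ~ N(140, 20), total cholesterol ~
#' N(208, 40), HDL ~ N(38, 12), smoking ~ Bernoulli(0.6), hypertension
#' treatment ~ Bernoulli(0.58), statin ~ Bernoulli(0.48). Autopsy flavor
#' omits SBP/cholesterol/statin and masks smoking and hypertension jointly
#' for an exact count `round(missing_rate * n)` of samples (questionnaire
#' non-response). The unmasked values are kept in a `complete` attribute so
#' outcome generation can condition on them.
#'
#' @param n_samples Number of samples.
#' @param flavor `"clinical"` or `"autopsy"`.
#' @param missing_rate_lifestyle Masked fraction (autopsy default 0.655).
#' @return A `cohort_table` (covariate columns only).
#' @export
gen_covariates <- function(n_samples, flavor = c("clinical", "autopsy"),
                           missing_rate_lifestyle = NULL) {
  flavor <- match.arg(flavor)
  if (is.null(missing_rate_lifestyle)) {
    missing_rate_lifestyle <- if (flavor == "autopsy") 0.655 else 0
  }
  out <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n_samples)),
    cad_case = NA_real_, stenosis_lad_pct = NA_real_,
    stenosis_rca_pct = NA_real_, calc_lad_pct = NA_real_,
    calc_rca_pct = NA_real_,
    age = pmin(pmax(stats::rnorm(n_samples, 62, 10), 18), 95),
    sex = ifelse(stats::rbinom(n_samples, 1, 0.72) == 1, "male", "female"),
    bmi = stats::rnorm(n_samples, 27.5, 4),
    sbp = NA_real_, total_chol = NA_real_, hdl_chol = NA_real_,
    smoking = stats::rbinom(n_samples, 1, 0.6),
    htn_med = stats::rbinom(n_samples, 1, 0.58),
    statin = NA_real_, stringsAsFactors = FALSE
  )
  if (flavor == "clinical") {
    out$sbp <- stats::rnorm(n_samples, 140, 20)
    out$total_chol <- stats::rnorm(n_samples, 208, 40)
    out$hdl_chol <- stats::rnorm(n_samples, 38, 12)
    out$statin <- stats::rbinom(n_samples, 1, 0.48)
  }
  complete <- out[, c("smoking", "htn_med")]
  n_mask <- round(missing_rate_lifestyle * n_samples)
  if (n_mask > 0) {
    mask <- sample.int(n_samples, n_mask)
    out$smoking[mask] <- NA_real_
    out$htn_med[mask] <- NA_real_
  }
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "complete") <- complete
  out
}

# Bisection on the intercept so mean(plogis(alpha + lp)) hits the target.
calibrate_intercept <- function(lp, target, tol = 1e-4) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target case fraction unreachable given the covariate effects")
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate outcomes for a synthetic cohort
#'
#' CAD: `eta = alpha + log(per_sd_or_cad) z + log(per_sd_or_meta) z_meta +`
#' covariate effects, with `alpha` calibrated by bisection so the population
#' mean probability equals `target_case_fraction`; `cad_case ~
#' Bernoulli(plogis(eta))`. Autopsy flavor additionally simulates
#' calcified-area percentages `100 y`, `y ~ Beta(mu phi, (1 - mu) phi)`,
#' `logit(mu) = calc_link . (1, z, z_age)`, independently for LAD and RCA,
#' and stenosis percentages as a noisy monotone transform of calcification
#' (plumbing to exercise case definitions, no biological fidelity claimed).
#' Uses the current RNG state.
#'
#' @param cohort Covariate table from [gen_covariates()].
#' @param scores Standardized `grs_score` for the primary score.
#' @param config A `sim_config`.
#' @param scores_meta Optional standardized second score.
#' @return The cohort with outcomes filled, plus a `truth` attribute
#'   (intercept, per-sample linear predictors and probabilities).
#' @export
gen_outcomes <- function(cohort, scores, config, scores_meta = NULL) {
  n <- nrow(cohort)
  z <- scores$standardized
  complete <- attr(cohort, "complete")
  eff <- config$covariate_effects
  lp <- log(config$per_sd_or_cad) * z
  if (!is.null(scores_meta) && config$per_sd_or_meta != 1) {
    lp <- lp + log(config$per_sd_or_meta) * scores_meta$standardized
  }
  for (nm in names(eff)) {
    x <- switch(nm,
      sex_male = as.numeric(cohort$sex == "male"),
      smoking = complete$smoking %||% cohort$smoking,
      htn_med = complete$htn_med %||% cohort$htn_med,
      cohort[[nm]]
    )
    if (nm %in% c("age", "bmi", "sbp", "total_chol", "hdl_chol")) {
      x <- as.numeric(scale(x))
    }
    lp <- lp + eff[nm] * x
  }
  alpha <- calibrate_intercept(lp, config$target_case_fraction)
  p <- stats::plogis(alpha + lp)
  cohort$cad_case <- stats::rbinom(n, 1, p)
  if (config$flavor == "autopsy") {
    z_age <- as.numeric(scale(cohort$age))
    mu <- stats::plogis(config$calc_link[1] + config$calc_link[2] * z +
                          config$calc_link[3] * z_age)
    for (col in c("calc_lad_pct", "calc_rca_pct")) {
      y <- stats::rbeta(n, mu * config$calc_phi, (1 - mu) * config$calc_phi)
      cohort[[col]] <- 100 * y
    }
    for (art in c("lad", "rca")) {
      calc <- cohort[[paste0("calc_", art, "_pct")]]
      sten <- 1.2 * calc + 20 * cohort$cad_case + stats::rnorm(n, 0, 12)
      cohort[[paste0("stenosis_", art, "_pct")]] <- pmin(pmax(sten, 0), 100)
    }
  }
  attr(cohort, "truth") <- list(
    alpha = alpha, linear_predictor = lp + alpha, probability = p,
    true_log_or_cad = log(config$per_sd_or_cad)
  )
  cohort
}

#' Generate a complete synthetic cohort bundle
#'
#' Runs the full generative chain under `config$seed`: two weight tables
#' (the 11-SNP score and a metaGRS-like stand-in), HWE genotype dosages for
#' both, raw and standardized scores, covariates, outcomes and missingness
#' masks; optionally writes the bundle to disk in the exact external
#' formats the readers accept (weights TSV x2, dosage TSV x2 or VCF,
#' phenotype CSV, truth JSON).
#'
#' @param config A `sim_config` (see also [preset_config()]).
#' @param out_dir Optional output directory.
#' @param genotype_format `"tsv"` (default) or `"vcf"` for the scored-SNP
#'   genotypes (the large metaGRS stand-in is always TSV).
#' @return A list of class `sim_cohort`: `weights`, `weights_meta`,
#'   `dosages`, `dosages_meta`, `cohort`, `scores`, `scores_meta`, `truth`,
#'   `config`, and `files` (paths, when written).
#' @export
gen_cohort <- function(config, out_dir = NULL,
                       genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  set.seed(config$seed)
  weights <- gen_weights(config$n_score_snps, config$maf_range, config$tau)
  weights_meta <- gen_weights(config$n_meta_snps, config$maf_range,
                              config$tau, id_prefix = "rsM")
  dm <- gen_genotypes(weights, config$n_samples, config$dosage_noise_sd)
  dm_meta <- gen_genotypes(weights_meta, config$n_samples,
                           config$dosage_noise_sd,
                           sample_ids = dm$sample_ids)
  scores <- standardize_grs(compute_grs(weights, dm))
  scores_meta <- standardize_grs(compute_grs(weights_meta, dm_meta))
  cohort <- gen_covariates(config$n_samples, config$flavor,
                           config$missing_rate_lifestyle)
  cohort <- gen_outcomes(cohort, scores, config, scores_meta)
  truth <- attr(cohort, "truth")
  n_core_mask <- round(config$missing_rate_core * config$n_samples)
  if (n_core_mask > 0) {
    mask <- sample.int(config$n_samples, n_core_mask)
    core <- c("cad_case", "stenosis_lad_pct", "stenosis_rca_pct",
              "calc_lad_pct", "calc_rca_pct")
    cohort[mask, core] <- NA_real_
  }
  truth$config <- unclass(config)
  out <- structure(
    list(weights = weights, weights_meta = weights_meta, dosages = dm,
         dosages_meta = dm_meta, cohort = cohort, scores = scores,
         scores_meta = scores_meta, truth = truth, config = config),
    class = "sim_cohort"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      weights = file.path(out_dir, "cac_weights.tsv"),
      weights_meta = file.path(out_dir, "meta_weights.tsv"),
      dosages = file.path(out_dir,
                          if (genotype_format == "vcf") "genotypes.vcf"
                          else "dosages.tsv"),
      dosages_meta = file.path(out_dir, "dosages_meta.tsv"),
      phenotypes = file.path(out_dir, "phenotypes.csv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_score_file(weights, files$weights)
    write_score_file(weights_meta, files$weights_meta)
    if (genotype_format == "vcf") {
      write_vcf_dosages(dm, weights, files$dosages)
    } else {
      write_dosages(dm, files$dosages)
    }
    write_dosages(dm_meta, files$dosages_meta)
    write_phenotypes(cohort, files$phenotypes)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}

#' Write a dosage matrix as a VCF with a DS FORMAT field
#'
#' Emits a minimal VCF v4.2 whose REF/ALT follow the matrix's recorded
#' alleles and whose genotypes carry the dosage in `DS` (with a hard-call
#' `GT` derived by rounding).
#'
#' @param dm A `dosage_matrix`.
#' @param weights A `grs_weights` supplying chromosome/position per variant.
#' @param path Output path.
#' @export
write_vcf_dosages <- function(dm, weights, path) {
  i <- match(dm$variant_ids, weights$variant_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dm$sample_ids), collapse = "\t")
  ), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (v in seq_along(dm$variant_ids)) {
    d <- dm$dosages[, v]
    cells <- ifelse(is.na(d), "./.:.",
                    paste0(gt_of[pmin(pmax(round(d), 0), 2) + 1], ":",
                           format(d, digits = 10, trim = TRUE)))
    writeLines(paste(c(weights$chromosome[i[v]], weights$position[i[v]],
                       dm$variant_ids[v], dm$ref[v], dm$alt[v], ".", "PASS",
                       ".", "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}
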