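test_that("generated weight files round-trip through the scoring-file reader", {
  set.seed(131)
  w <- gen_weights(11)
  path <- tempfile(fileext = ".tsv")
  write_score_file(w, path)
  w2 <- read_score_file(path)
  expect_equal(nrow(w2), 11)
  expect_equal(w2$variant_id, w$variant_id)
  expect_equal(w2$effect_weight, w$effect_weight, tolerance = 0)
  expect_false(any(cacgrs:::is_palindromic(w$effect_allele, w$other_allele)))
  # raw-score variance calibration: sum w^2 2f(1-f) = 1
  f <- attr(w, "freq")
  expect_equal(sum(w$effect_weight^2 * 2 * f * (1 - f)), 1, tolerance = 1e-12)
})

test_that("zero-tau weights produce a degenerate score caught downstream", {
  set.seed(137)
  w <- gen_weights(11, tau = 0)
  expect_true(all(w$effect_weight == 0))
  dm <- gen_genotypes(w, 50)
  expect_error(standardize_grs(compute_grs(w, dm)), "degenerate")
})

test_that("the generator is deterministic under a fixed configuration", {
  cfg <- sim_config(n_samples = 60, seed = 139, n_meta_snps = 10)
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- gen_cohort(cfg, out_dir = d1)
  b2 <- gen_cohort(cfg, out_dir = d2)
  expect_identical(b1$scores$raw, b2$scores$raw)
  expect_identical(b1$cohort$cad_case, b2$cohort$cad_case)
  for (f in names(b1$files)) {
    expect_identical(readLines(b1$files[[f]]), readLines(b2$files[[f]]))
  }
})

test_that("genotypes follow Hardy-Weinberg expectations", {
  set.seed(149)
  w1 <- simple_weights("v", "A", "G", 1)
  attr(w1, "freq") <- 0.5
  g <- gen_genotypes(w1, 1e4)
  expect_lt(abs(mean(g$dosages) - 1), 0.02)
  expect_true(all(g$dosages %in% c(0, 1, 2)))

  noisy <- gen_genotypes(w1, 100, dosage_noise_sd = 0.3)
  expect_true(all(noisy$dosages >= 0 & noisy$dosages <= 2))
  expect_false(all(noisy$dosages %in% c(0, 1, 2)))

  # chi-square HWE conformance at alpha = 0.01 in >= 95/100 simulations
  pass <- 0
  for (i in 1:100) {
    f <- runif(1, 0.1, 0.5)
    wf <- simple_weights("v", "A", "G", 1)
    attr(wf, "freq") <- f
    d <- gen_genotypes(wf, 2000)$dosages
    obs <- tabulate(d + 1, 3)
    exp_p <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    p <- suppressWarnings(chisq.test(obs, p = exp_p)$p.value)
    pass <- pass + (p > 0.01)
  }
  expect_gte(pass, 95)
})

test_that("covariate generation respects flavor and masks an exact count", {
  set.seed(151)
  clin <- gen_covariates(2000, "clinical")
  for (col in c("age", "bmi", "sbp", "total_chol", "hdl_chol", "smoking",
                "htn_med", "statin")) {
    expect_false(anyNA(clin[[col]]), info = col)
  }
  expect_true(all(clin$age >= 18 & clin$age <= 95))

  aut <- gen_covariates(660, "autopsy", missing_rate_lifestyle = 432 / 660)
  expect_equal(sum(!is.na(aut$smoking)), 228)
  expect_equal(sum(!is.na(aut$htn_med)), 228)
  expect_true(all(is.na(aut$sbp)))
  # observed questionnaire fraction = 34.5%
  expect_equal(100 * mean(!is.na(aut$smoking)), 34.5, tolerance = 0.05)
})

test_that("outcome generation hits the target case fraction and is self-consistent", {
  # null score, no covariate effects: case fraction = target up to binomial noise
  set.seed(157)
  cfg0 <- sim_config(n_samples = 20000, per_sd_or_cad = 1, seed = 157,
                     n_meta_snps = 2,
                     covariate_effects = c(age = 0),
                     target_case_fraction = 0.7)
  b0 <- gen_cohort(cfg0)
  expect_lt(abs(mean(b0$cohort$cad_case) - 0.7), 0.01)
  # independence of score and outcome under the null
  r0 <- fit_logistic(data.frame(y = b0$cohort$cad_case,
                                z = b0$scores$standardized), "y", "z")
  expect_lt(abs(r0$estimate), 3 * r0$std_error + 1e-9)

  # large-n: refit on the score alone recovers log(1.4)
  cfg <- sim_config(n_samples = 1e5, per_sd_or_cad = 1.4, seed = 163,
                    n_meta_snps = 2,
                    covariate_effects = c(age = 0))
  b <- gen_cohort(cfg)
  r <- fit_logistic(data.frame(y = b$cohort$cad_case,
                               z = b$scores$standardized), "y", "z")
  expect_lt(abs(r$estimate - log(1.4)), 0.03)

  # unreachable target fails in calibration: half the cohort has an
  # effectively -Inf linear predictor, capping the mean probability at 0.5
  expect_error(
    cacgrs:::calibrate_intercept(c(rep(-1e6, 5), rep(0, 5)), 0.9),
    "unreachable")
})

test_that("presets reproduce the three cohort shapes and run end to end", {
  luric <- preset_config("luric", seed = 1, n_meta_snps = 5)
  expect_equal(luric$n_samples, 2742)
  expect_equal(luric$flavor, "clinical")
  tvs <- gen_cohort(preset_config("tvs", seed = 2, n_meta_snps = 5))
  expect_equal(nrow(tvs$cohort), 133)
  r <- run_model(tvs$cohort, tvs$scores, model_spec("model1"))
  expect_s3_class(r, "association_result")

  tsds <- gen_cohort(preset_config("tsds", seed = 3, n_meta_snps = 5))
  expect_equal(nrow(tsds$cohort), 660)
  expect_equal(sum(!is.na(tsds$cohort$cad_case)), 622)
  expect_equal(sum(!is.na(tsds$cohort$smoking)), 228)
  expect_true(all(is.na(tsds$cohort$sbp)))
  # autopsy model 2 runs without lipid/BP columns
  r2 <- run_model(tsds$cohort, tsds$scores,
                  model_spec("model2", flavor = "autopsy", pc_count = 0))
  expect_s3_class(r2, "association_result")
  # stenosis exercises the case definition
  relab <- define_cad_cases(tsds$cohort)
  expect_true(all(relab$cad_case[!is.na(relab$cad_case)] %in% c(0, 1)))
  expect_gt(cor(relab$cad_case, tsds$cohort$cad_case,
                use = "complete.obs"), 0.2)
})
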