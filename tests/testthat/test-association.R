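test_that("logistic OR equals the 2x2 closed form", {
  d <- expand_2x2(30, 10, 10, 30)
  r <- fit_logistic(d, "y", "x")
  expect_equal(r$odds_ratio, 9.0, tolerance = 1e-8)
  expect_equal(attr(r, "n_used"), 80)
  expect_true(attr(r, "converged"))

  set.seed(17)
  for (rep in 1:30) {
    tab <- sample(5:60, 4, replace = TRUE)
    d <- expand_2x2(tab[1], tab[2], tab[3], tab[4])
    r <- fit_logistic(d, "y", "x")
    expect_equal(r$odds_ratio, tab[1] * tab[4] / (tab[2] * tab[3]),
                 tolerance = 1e-6)
  }
})

test_that("logistic fit rejects degenerate designs and separation", {
  d <- expand_2x2(20, 10, 10, 20)
  d$const <- 1
  expect_error(fit_logistic(d, "y", c("x", "const")), "rank-deficient")

  d1 <- d[d$y == 1, ]
  expect_error(fit_logistic(d1, "y", "x"), "single class")

  sep <- data.frame(y = rep(c(0, 1), each = 20),
                    x = c(rnorm(20, -3), rnorm(20, 3)))
  expect_error(fit_logistic(sep, "y", "x"), "separation")
})

test_that("null predictor gives calibrated Wald tests and near-zero log-OR", {
  set.seed(23)
  est <- p <- numeric(100)
  for (i in 1:100) {
    d <- data.frame(y = rbinom(400, 1, 0.5), x = rnorm(400))
    r <- fit_logistic(d, "y", "x")
    est[i] <- r$estimate
    p[i] <- r$p_value
  }
  expect_lt(abs(mean(est)), 0.03)
  # rejection rate ~ 5%: 99% binomial band for 100 draws
  expect_lte(sum(p < 0.05), qbinom(0.995, 100, 0.05))
})

test_that("PCs separate simulated subpopulations and match an eigen oracle", {
  set.seed(29)
  n_var <- 40
  f1 <- runif(n_var, 0.1, 0.4)
  f2 <- pmin(f1 + 0.35, 0.95)
  g1 <- sapply(f1, function(f) rbinom(60, 2, f))
  g2 <- sapply(f2, function(f) rbinom(60, 2, f))
  d <- rbind(g1, g2)
  rownames(d) <- paste0("s", 1:120)
  pcs <- compute_pcs(d, 5)
  grp <- rep(1:2, each = 60)
  expect_true(max(pcs[grp == 1, 1]) < min(pcs[grp == 2, 1]) ||
                min(pcs[grp == 1, 1]) > max(pcs[grp == 2, 1]))
  ev <- attr(pcs, "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))

  # left singular vectors agree with eigenvectors of the scaled Gram matrix
  f <- colMeans(d) / 2
  Z <- sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  for (j in 1:5) {
    v <- eig$vectors[, j]
    expect_equal(abs(sum(v * pcs[, j])), 1, tolerance = 1e-8)
  }
})

test_that("compute_pcs handles k = 0 and rejects k beyond the rank", {
  set.seed(3)
  w <- gen_weights(6)
  dm <- gen_genotypes(w, 20)
  p0 <- compute_pcs(dm, 0)
  expect_equal(ncol(p0), 0)
  expect_error(compute_pcs(dm, 10), "rank")
})

test_that("run_model reports the score per SD and catches collinear second scores", {
  set.seed(41)
  cfg <- sim_config(n_samples = 800, seed = 41, n_meta_snps = 5)
  b <- gen_cohort(cfg)
  spec <- model_spec("model2", pc_count = 0)
  r <- run_model(b$cohort, b$scores, spec)
  expect_s3_class(r, "association_result")
  expect_true("score" %in% r$term)
  expect_true(all(r$ci_low < r$odds_ratio & r$odds_ratio < r$ci_high))
  expect_true(all(r$p_value > 0 & r$p_value <= 1))

  spec3 <- model_spec("model3", pc_count = 0)
  expect_error(run_model(b$cohort, b$scores, spec3, scores2 = b$scores),
               "rank-deficient")
})

test_that("model-2 covariate sets follow the cohort flavor", {
  clin <- model_spec("model2", flavor = "clinical", pc_count = 2)
  expect_true(all(c("sbp", "total_chol", "hdl_chol", "PC1", "PC2") %in%
                    clin$terms))
  expect_false("bmi" %in% clin$terms)
  aut <- model_spec("model2", flavor = "autopsy", pc_count = 2)
  expect_true("bmi" %in% aut$terms)
  expect_false(any(c("sbp", "total_chol", "hdl_chol") %in% aut$terms))
  stat <- model_spec("model2", include_statin = TRUE)
  expect_true("statin" %in% stat$terms)
})

test_that("a pure-noise covariate leaves the score log-OR essentially unshifted", {
  set.seed(47)
  shift <- numeric(500)
  for (i in 1:500) {
    z <- rnorm(500)
    y <- rbinom(500, 1, plogis(0.3 + log(1.4) * z))
    d <- data.frame(y = y, z = z, noise = rnorm(500))
    b1 <- fit_logistic(d, "y", "z")$estimate
    b2 <- fit_logistic(d, "y", c("z", "noise"))$estimate[1]
    shift[i] <- b2 - b1
  }
  expect_lt(abs(mean(shift)), 0.02)
})

test_that("quantile association is null-calibrated and score-agnostic", {
  set.seed(53)
  logs <- matrix(0, 30, 3)
  for (i in 1:30) {
    cfg <- sim_config(n_samples = 1000, per_sd_or_cad = 1, seed = i,
                      n_meta_snps = 5,
                      covariate_effects = c(age = 0.3))
    b <- gen_cohort(cfg)
    bins <- quantile_bins(b$scores)
    r <- quantile_association(b$cohort, b$scores, bins, model_spec("model1"))
    logs[i, ] <- r$estimate[match(c("binQ2", "binQ3", "binQ4"), r$term)]
  }
  expect_true(all(abs(colMeans(logs)) < 0.12))

  # the machinery is agnostic to which score produced the bins
  cfg <- sim_config(n_samples = 600, seed = 99, n_meta_snps = 20)
  b <- gen_cohort(cfg)
  bins_meta <- quantile_bins(b$scores_meta)
  r2 <- quantile_association(b$cohort, b$scores_meta, bins_meta,
                             model_spec("model1"))
  expect_s3_class(r2, "association_result")
  expect_true(all(c("binQ2", "binQ3", "binQ4") %in% r2$term))
})

test_that("stratified reruns agree under a shared effect and survive bad strata", {
  set.seed(59)
  cfg <- sim_config(n_samples = 4000, seed = 59, n_meta_snps = 5,
                    covariate_effects = c(age = 0.4, sex_male = 0.8))
  b <- gen_cohort(cfg)
  out <- stratified_association(b$cohort, b$scores, model_spec("model1"))
  expect_named(out, c("female", "male"))
  e_f <- out$female[out$female$term == "score", ]
  e_m <- out$male[out$male$term == "score", ]
  expect_lt(abs(e_f$estimate - e_m$estimate),
            3 * sqrt(e_f$std_error^2 + e_m$std_error^2))

  # a stratum with a single outcome class is recorded, not fatal
  co <- b$cohort
  co$cad_case[co$sex == "female"] <- 1
  out2 <- stratified_association(co, b$scores, model_spec("model1"))
  expect_s3_class(out2$female, "stratum_error")
  expect_s3_class(out2$male, "association_result")

  # the under-40 stratum is small: flagged low-power (or a recorded error),
  # never a run-stopping failure
  out3 <- stratified_association(b$cohort, b$scores, model_spec("model1"),
                                 strata = "age40")
  expect_lt(sum(b$cohort$age < 40), 100)
  lt40 <- out3$age_lt40
  expect_true(inherits(lt40, "stratum_error") ||
                !is.null(attr(lt40, "low_power_warning")))
  expect_s3_class(out3$age_ge40, "association_result")
})
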