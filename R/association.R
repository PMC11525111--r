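# Nested logistic CAD models, genotype principal components,
# quantile-interval odds ratios and stratified reruns.

#' Specify a CAD association model
#'
#' Presets mirror the usual nested structure for risk-score association
#' testing: model 1 adjusts the score for age, sex and BMI; model 2 for the
#' Framingham-style risk factors (clinical flavor: age, sex, smoking, HDL
#' and total cholesterol, systolic blood pressure, hypertension treatment;
#' autopsy flavor, where lipids and blood pressure are unavailable: age,
#' sex, BMI, smoking, hypertension treatment) plus genotype principal
#' components; model 3 is model 2 plus a second polygenic score.
#'
#' @param preset One of `"model1"`, `"model2"`, `"model3"`, `"custom"`.
#' @param flavor Cohort flavor, `"clinical"` or `"autopsy"`; decides the
#'   model-2 covariate set.
#' @param pc_count Number of genotype principal components to adjust for in
#'   models 2 and 3 (default 5).
#' @param include_statin Add statin usage as a covariate in models 2/3
#'   (default `FALSE`).
#' @param terms Character vector of terms for `preset = "custom"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(preset = c("model1", "model2", "model3", "custom"),
                       flavor = c("clinical", "autopsy"), pc_count = 5,
                       include_statin = FALSE, terms = NULL) {
  preset <- match.arg(preset)
  flavor <- match.arg(flavor)
  pcs <- if (pc_count > 0 && preset %in% c("model2", "model3")) {
    paste0("PC", seq_len(pc_count))
  } else character(0)
  base2 <- if (flavor == "clinical") {
    c("age", "sex_male", "smoking", "hdl_chol", "total_chol", "sbp",
      "htn_med")
  } else {
    c("age", "sex_male", "bmi", "smoking", "htn_med")
  }
  if (include_statin && flavor == "clinical") base2 <- c(base2, "statin")
  terms <- switch(preset,
    model1 = c("score", "age", "sex_male", "bmi"),
    model2 = c("score", base2, pcs),
    model3 = c("score", base2, "score2", pcs),
    custom = {
      if (is.null(terms)) stop("custom preset requires 'terms'")
      terms
    }
  )
  structure(list(preset = preset, flavor = flavor, pc_count = pc_count,
                 include_statin = include_statin, terms = terms),
            class = "model_spec")
}

# Binomial IRLS fit on a ready design matrix; thin wrapper kept separate so
# the bootstrap loop can skip data-frame assembly.
logit_fit <- function(X, y, maxit = 100) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = maxit))
  )
  p <- fit$fitted.values
  separated <- any(abs(fit$coefficients) > 15) &&
    all(p < 1e-8 | p > 1 - 1e-8)
  loglik <- sum(y * log(pmax(p, 1e-300)) +
                  (1 - y) * log(pmax(1 - p, 1e-300)))
  list(coef = fit$coefficients, qr = fit$qr, converged = fit$converged,
       separated = separated, loglik = loglik, fitted = p)
}

#' Fit a logistic regression and report per-term odds ratios
#'
#' Maximum-likelihood logistic regression (binomial iteratively reweighted
#' least squares via `stats::glm.fit`) on the complete cases of the supplied
#' design. Reported per term: log-odds estimate, standard error, odds ratio
#' `exp(beta)`, 95\% Wald interval `exp(beta +/- 1.96 SE)` and two-sided
#' Wald p-value.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of covariate column names.
#' @return A data frame of class `association_result` with one row per model
#'   term (intercept excluded); attributes `n_used`, `converged`,
#'   `log_lik`.
#' @export
fit_logistic <- function(data, outcome, terms) {
  cols <- c(outcome, terms)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing model columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, cols, drop = FALSE]
  y <- d[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("outcome has a single class after complete-case filtering")
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, terms, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design: collinear or constant term(s) among ",
         paste(terms, collapse = ", "))
  }
  fit <- logit_fit(X, y)
  if (fit$separated) {
    stop("perfect separation detected (diverging coefficients)")
  }
  covmat <- chol2inv(fit$qr$qr[seq_len(ncol(X)), , drop = FALSE])
  se <- sqrt(diag(covmat))
  b <- fit$coef
  keep <- seq_along(b)[-1]  # drop intercept from the report
  res <- data.frame(
    term = terms,
    estimate = unname(b[keep]),
    std_error = unname(se[keep]),
    stringsAsFactors = FALSE
  )
  res$odds_ratio <- exp(res$estimate)
  res$ci_low <- exp(res$estimate - 1.96 * res$std_error)
  res$ci_high <- exp(res$estimate + 1.96 * res$std_error)
  res$p_value <- 2 * stats::pnorm(-abs(res$estimate / res$std_error))
  attr(res, "n_used") <- nrow(d)
  attr(res, "converged") <- fit$converged
  attr(res, "log_lik") <- fit$loglik
  class(res) <- c("association_result", "data.frame")
  res
}

#' Leading principal components of a genotype dosage matrix
#'
#' Each variant column is centered by twice the estimated allele frequency
#' and scaled by `sqrt(2 f (1 - f))` (the Patterson convention), missing
#' dosages are mean-imputed, and the PCs are the leading left singular
#' vectors of the scaled matrix. The sign of each component is fixed so the
#' largest-magnitude variant loading is positive.
#'
#' @param dm A `dosage_matrix` (or plain samples-by-variants matrix).
#' @param k Number of components (default 5); `k = 0` returns a zero-column
#'   matrix.
#' @return A samples-by-k matrix with columns `PC1..PCk` and an
#'   `explained_variance` attribute (proportions, non-increasing).
#' @export
compute_pcs <- function(dm, k = 5) {
  d <- if (inherits(dm, "dosage_matrix")) dm$dosages else as.matrix(dm)
  if (k == 0) {
    out <- matrix(numeric(0), nrow = nrow(d), ncol = 0,
                  dimnames = list(rownames(d), NULL))
    attr(out, "explained_variance") <- numeric(0)
    return(out)
  }
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  f <- colMeans(d) / 2
  ok <- f > 0 & f < 1
  d <- d[, ok, drop = FALSE]
  f <- f[ok]
  Z <- sweep(d, 2, 2 * f)
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  if (k > min(dim(Z)) - 1 || k > qr(Z)$rank) {
    stop("k = ", k, " exceeds the rank of the genotype matrix")
  }
  sv <- svd(Z, nu = k, nv = k)
  U <- sv$u
  for (j in seq_len(k)) {
    s <- sign(sv$v[which.max(abs(sv$v[, j])), j])
    if (s < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("PC", seq_len(k))
  rownames(U) <- rownames(d)
  attr(U, "explained_variance") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  U
}

# Assemble the analysis frame: cohort covariates + standardized score(s) +
# PCs, with sex recoded as a male indicator.
build_analysis_frame <- function(cohort, scores, pcs = NULL, scores2 = NULL) {
  d <- as.data.frame(cohort)
  d$sex_male <- as.numeric(d$sex == "male")
  i <- match(d$sample_id, scores$sample_id)
  if (anyNA(i)) stop("samples in cohort missing from scores")
  d$score <- scores$standardized[i] %||%
    stop("scores must be standardized (run standardize_grs)")
  if (!is.null(scores2)) {
    j <- match(d$sample_id, scores2$sample_id)
    d$score2 <- scores2$standardized[j]
  }
  if (!is.null(pcs) && ncol(pcs) > 0) {
    j <- match(d$sample_id, rownames(pcs))
    if (anyNA(j)) stop("samples in cohort missing from PC matrix")
    d <- cbind(d, pcs[j, , drop = FALSE])
  }
  d
}

#' Run a preset CAD association model on a cohort
#'
#' Assembles the design (sex as a male = 1 indicator, binary covariates as
#' 0/1, the standardized score so its odds ratio is per SD), restricts to
#' complete cases on the model terms, and fits [fit_logistic()].
#'
#' @param cohort A `cohort_table` with `cad_case` filled.
#' @param scores A standardized `grs_score` for the primary score.
#' @param spec A [model_spec()].
#' @param pcs Optional PC matrix from [compute_pcs()] (required when the
#'   spec includes PC terms).
#' @param scores2 Optional second standardized score (model 3).
#' @return An `association_result`.
#' @export
run_model <- function(cohort, scores, spec, pcs = NULL, scores2 = NULL) {
  d <- build_analysis_frame(cohort, scores, pcs, scores2)
  miss <- setdiff(spec$terms, names(d))
  if (length(miss)) {
    stop("model terms not available in cohort: ", paste(miss, collapse = ", "))
  }
  fit_logistic(d, "cad_case", spec$terms)
}

#' Quantile-interval association: odds ratios relative to the lowest bin
#'
#' Replaces the continuous score term of a model specification with
#' indicator terms for the non-reference quantile bins, so each reported
#' odds ratio compares a bin against Q1.
#'
#' @inheritParams run_model
#' @param bins A `quantile_bins` object for the score being tested.
#' @return An `association_result` with one `binQk` term per non-reference
#'   bin plus the covariate terms.
#' @export
quantile_association <- function(cohort, scores, bins, spec, pcs = NULL,
                                 scores2 = NULL) {
  d <- build_analysis_frame(cohort, scores, pcs, scores2)
  i <- match(d$sample_id, bins$sample_id)
  lev <- levels(bins$bin)
  if (sum(bins$bin == bins$reference_bin, na.rm = TRUE) == 0) {
    stop("reference bin is empty")
  }
  bin_terms <- character(0)
  for (q in setdiff(lev, bins$reference_bin)) {
    nm <- paste0("bin", q)
    d[[nm]] <- as.numeric(bins$bin[i] == q)
    bin_terms <- c(bin_terms, nm)
  }
  terms <- c(bin_terms, setdiff(spec$terms, "score"))
  cc <- stats::complete.cases(d[, c("cad_case", terms), drop = FALSE])
  counts <- table(bins$bin[i][cc])
  if (any(counts == 0)) {
    stop("quantile bin empty after complete-case filtering: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  fit_logistic(d, "cad_case", terms)
}

#' Sex- or age-stratified reruns of an association model
#'
#' Subsets the cohort by stratum and reruns [run_model()] per stratum.
#' Strata that fail (for example a single outcome class) are recorded as
#' errors without aborting the other strata; small strata are flagged with a
#' low-power warning rather than dropped.
#'
#' @inheritParams run_model
#' @param strata `"sex"` (male/female) or `"age40"` (age >= 40 vs < 40).
#' @param min_n Stratum size below which a low-power warning is attached
#'   (default 100).
#' @return A named list; each element is an `association_result` or, for a
#'   failed stratum, an object of class `stratum_error`.
#' @export
stratified_association <- function(cohort, scores, spec, strata = c("sex", "age40"),
                                   pcs = NULL, scores2 = NULL, min_n = 100) {
  strata <- match.arg(strata)
  if (strata == "sex") {
    # the stratifying variable is constant within stratum
    spec$terms <- setdiff(spec$terms, "sex_male")
  }
  groups <- if (strata == "sex") {
    split(seq_len(nrow(cohort)), cohort$sex)
  } else {
    split(seq_len(nrow(cohort)),
          ifelse(cohort$age >= 40, "age_ge40", "age_lt40"))
  }
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    res <- tryCatch(
      run_model(cohort[idx, , drop = FALSE], scores, spec,
                pcs = pcs, scores2 = scores2),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "stratum_error")
    )
    if (!inherits(res, "stratum_error") && length(idx) < min_n) {
      attr(res, "low_power_warning") <-
        paste0("stratum '", g, "' has only ", length(idx), " samples")
    }
    out[[g]] <- res
  }
  out
}

#' Write an association result as TSV (term, OR, CI, p)
#' @param result An `association_result`.
#' @param path Output path.
#' @export
write_association <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
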