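# Beta regression of calcified-plaque area proportions: logit mean link,
# constant precision phi, maximum likelihood with monotone Newton steps.

#' Squeeze proportions off the boundaries of (0, 1)
#'
#' Calcified-area percentages include exact 0 and 100 values, which lie
#' outside the beta support. The standard compression
#' `y' = (y (n - 1) + 0.5) / n` is applied to all observations, where `n` is
#' the sample count, so boundary values are moved strictly inside (0, 1)
#' while mid-range values are barely perturbed (0.5 is a fixed point).
#'
#' @param y Proportions in \[0, 1\].
#' @param n Sample count used in the transform (default `length(y)`).
#' @return A list of class `proportion_outcome` with `y`, `y_adjusted` and
#'   `n_boundary` (count of exact 0/1 values).
#' @export
squeeze_boundaries <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  y_adj <- (y * (n - 1) + 0.5) / n
  structure(list(y = y, y_adjusted = y_adj,
                 n_boundary = sum(y %in% c(0, 1))),
            class = "proportion_outcome")
}

betareg_loglik <- function(y, X, beta, phi) {
  mu <- stats::plogis(as.numeric(X %*% beta))
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

betareg_gradient <- function(y, X, beta, log_phi) {
  phi <- exp(log_phi)
  mu <- stats::plogis(as.numeric(X %*% beta))
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  g_beta <- phi * as.numeric(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  g_phi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                 (1 - mu) * digamma((1 - mu) * phi) +
                 mu * log(y) + (1 - mu) * log(1 - y))
  c(g_beta, g_phi * phi)  # chain rule: derivative w.r.t. log(phi)
}

# Numerical Hessian of the log-likelihood in (beta, log phi) by central
# differences of the analytic gradient.
betareg_hessian <- function(y, X, theta, eps = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + eps
    tm[j] <- tm[j] - eps
    gp <- betareg_gradient(y, X, tp[-p], tp[p])
    gm <- betareg_gradient(y, X, tm[-p], tm[p])
    H[, j] <- (gp - gm) / (2 * eps)
  }
  (H + t(H)) / 2
}

#' Maximum-likelihood beta regression with a logit mean link
#'
#' Fits `y ~ Beta(mu * phi, (1 - mu) * phi)` with `logit(mu) = X beta` and a
#' constant precision `phi`. Optimization is Newton's method in
#' `(beta, log phi)` with step-halving so the log-likelihood never
#' decreases, started from a least-squares fit on `logit(y)` for `beta` and
#' a method-of-moments estimate for `phi`; convergence when the
#' log-likelihood change falls below 1e-10. Standard errors come from the
#' inverse observed information at the optimum. The reported odds ratio per
#' term is `exp(beta)` on the logit-mean scale — a multiplicative effect on
#' the mean-proportion odds `mu / (1 - mu)`, not a case-control odds ratio.
#'
#' @param data Data frame with the (already boundary-squeezed) outcome and
#'   covariates.
#' @param outcome Name of the outcome column, values strictly inside (0, 1).
#' @param terms Covariate column names.
#' @param max_iter Maximum Newton iterations (default 200).
#' @return A data frame of class `betareg_result` with one row per term
#'   (estimate, std_error, odds_ratio, ci_low, ci_high, p_value);
#'   attributes `precision_phi`, `log_likelihood`, `loglik_trace`, `n_used`,
#'   `converged`, `degenerate`.
#' @export
fit_betareg <- function(data, outcome, terms, max_iter = 200) {
  cols <- c(outcome, terms)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing model columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, cols, drop = FALSE]
  y <- d[[outcome]]
  if (any(y <= 0 | y >= 1)) {
    stop("outcome must be strictly inside (0, 1); apply squeeze_boundaries first")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, terms, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: collinear or constant term(s)")
  }
  if (nrow(X) <= ncol(X) + 1) stop("too few observations for the model size")

  # starts: OLS on logit(y); method-of-moments phi
  beta <- stats::lm.fit(X, stats::qlogis(y))$coefficients
  mu0 <- stats::plogis(as.numeric(X %*% beta))
  v <- stats::var(y - mu0)
  phi <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 0.1)
  theta <- c(beta, log(phi))
  p <- length(theta)
  ll <- betareg_loglik(y, X, theta[-p], exp(theta[p]))
  trace <- ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- betareg_gradient(y, X, theta[-p], theta[p])
    H <- betareg_hessian(y, X, theta)
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g), 1))
    # Newton direction for a maximum is -H^{-1} g; fall back to the gradient
    # direction if the Hessian is not negative definite at this iterate.
    dir <- -step
    if (sum(dir * g) <= 0) dir <- g / max(abs(g), 1)
    lam <- 1
    new_ll <- -Inf
    for (h in 1:50) {
      cand <- theta + lam * dir
      new_ll <- betareg_loglik(y, X, cand[-p], exp(cand[p]))
      if (is.finite(new_ll) && new_ll >= ll) break
      lam <- lam / 2
    }
    if (!is.finite(new_ll) || new_ll < ll) break  # no ascent possible
    theta <- theta + lam * dir
    trace <- c(trace, new_ll)
    if (abs(new_ll - ll) < 1e-10) {
      converged <- TRUE
      ll <- new_ll
      break
    }
    ll <- new_ll
  }
  phi_hat <- exp(theta[p])
  H <- betareg_hessian(y, X, theta)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vc))[seq_len(ncol(X))]
  b <- theta[seq_len(ncol(X))]
  keep <- seq_along(b)[-1]
  res <- data.frame(term = terms, estimate = unname(b[keep]),
                    std_error = unname(se[keep]), stringsAsFactors = FALSE)
  res$odds_ratio <- exp(res$estimate)
  res$ci_low <- exp(res$estimate - 1.96 * res$std_error)
  res$ci_high <- exp(res$estimate + 1.96 * res$std_error)
  res$p_value <- 2 * stats::pnorm(-abs(res$estimate / res$std_error))
  attr(res, "precision_phi") <- unname(phi_hat)
  attr(res, "log_likelihood") <- ll
  attr(res, "loglik_trace") <- trace
  attr(res, "n_used") <- nrow(d)
  attr(res, "converged") <- converged
  attr(res, "degenerate") <- phi_hat < 1e-4 || phi_hat > 1e8
  attr(res, "intercept") <- unname(b[1])
  class(res) <- c("betareg_result", "data.frame")
  res
}

#' Beta regression of calcified-plaque area for one coronary artery
#'
#' Models the chosen artery's calcified-area percentage (divided by 100) as
#' a beta-distributed proportion, adjusted for the standardized score, age,
#' sex, BMI, smoking, hypertension treatment and the genotype principal
#' components; complete-case. When the outcome contains exact 0\% or 100\%
#' values (as morphometric area measurements do), [squeeze_boundaries()] is
#' applied to all observations first; boundary-free outcomes are modelled
#' as-is, because the compression measurably attenuates coefficients when
#' the outcome mass sits near a boundary.
#'
#' @param cohort A `cohort_table`.
#' @param artery `"lad"` or `"rca"`.
#' @param scores A standardized `grs_score`.
#' @param pcs Optional PC matrix ([compute_pcs()]).
#' @return A `betareg_result`; the `boundary_adjusted` attribute counts
#'   observations squeezed off exact 0/100.
#' @export
run_calcification_model <- function(cohort, artery = c("lad", "rca"),
                                    scores, pcs = NULL) {
  artery <- match.arg(artery)
  col <- paste0("calc_", artery, "_pct")
  d <- build_analysis_frame(cohort, scores, pcs)
  terms <- c("score", "age", "sex_male", "bmi", "smoking", "htn_med",
             if (!is.null(pcs) && ncol(pcs) > 0) colnames(pcs))
  cc <- stats::complete.cases(d[, c(col, terms), drop = FALSE])
  if (sum(cc) < 30) {
    stop("fewer than 30 samples with ", col, " and complete covariates")
  }
  d <- d[cc, , drop = FALSE]
  y <- d[[col]] / 100
  if (any(y %in% c(0, 1))) {
    sq <- squeeze_boundaries(y)
    d$.y <- sq$y_adjusted
    n_boundary <- sq$n_boundary
  } else {
    d$.y <- y
    n_boundary <- 0L
  }
  res <- fit_betareg(d, ".y", terms)
  attr(res, "boundary_adjusted") <- n_boundary
  attr(res, "artery") <- artery
  res
}
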