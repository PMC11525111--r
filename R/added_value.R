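# Added predictive value: rank-based AUC, 70/30 train-test evaluation,
# bootstrap delta-AUC with empirical p-value, undersampling balance check.

#' Rank-based (Mann-Whitney) area under the ROC curve
#'
#' `AUC = (#{case > control pairs} + 0.5 #{tied pairs}) / (n_case n_control)`,
#' computed via midranks so ties contribute half weight.
#'
#' @param scores Numeric predictions, higher = more case-like.
#' @param labels Binary outcome (0 = control, 1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both outcome classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit ref and test logistic models on train rows, return held-out AUCs.
# Returns NULL when either split lacks both classes.
split_fit_auc <- function(y, X_ref, X_test, train_idx) {
  y_tr <- y[train_idx]; y_te <- y[-train_idx]
  if (length(unique(y_tr)) < 2 || length(unique(y_te)) < 2) return(NULL)
  f_ref <- logit_fit(X_ref[train_idx, , drop = FALSE], y_tr)
  f_test <- logit_fit(X_test[train_idx, , drop = FALSE], y_tr)
  p_ref <- stats::plogis(as.numeric(X_ref[-train_idx, , drop = FALSE] %*%
                                      f_ref$coef))
  p_test <- stats::plogis(as.numeric(X_test[-train_idx, , drop = FALSE] %*%
                                       f_test$coef))
  c(auc(p_ref, y_te), auc(p_test, y_te))
}

prep_design <- function(data, outcome, ref_terms, test_terms) {
  cols <- unique(c(outcome, ref_terms, test_terms))
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, cols, drop = FALSE]
  list(
    y = d[[outcome]],
    X_ref = cbind(1, as.matrix(d[, ref_terms, drop = FALSE])),
    X_test = cbind(1, as.matrix(d[, test_terms, drop = FALSE])),
    n = nrow(d)
  )
}

#' Single train/test split AUC comparison of two nested prediction models
#'
#' Draws one random 70/30 split, fits the reference and the augmented
#' logistic model on the training rows, and evaluates both by the AUC of
#' their predicted probabilities on the held-out rows. The split is a simple
#' random split by default; `stratify_split = TRUE` splits cases and
#' controls separately so both parts keep the outcome mix.
#'
#' @param data Data frame with outcome and covariates (complete cases on the
#'   union of terms are used).
#' @param outcome Binary outcome column name.
#' @param ref_terms Covariates of the reference model.
#' @param test_terms Covariates of the augmented model.
#' @param train_fraction Fraction of rows used for training (default 0.7).
#' @param stratify_split Stratify the split by outcome (default `FALSE`).
#' @return Named numeric vector `c(auc_ref, auc_test)`.
#' @export
train_test_auc <- function(data, outcome, ref_terms, test_terms,
                           train_fraction = 0.7, stratify_split = FALSE) {
  pd <- prep_design(data, outcome, ref_terms, test_terms)
  for (attempt in 1:2) {
    idx <- draw_split(pd$y, train_fraction, stratify_split)
    res <- split_fit_auc(pd$y, pd$X_ref, pd$X_test, idx)
    if (!is.null(res)) {
      return(c(auc_ref = res[1], auc_test = res[2]))
    }
  }
  stop("train/test split left a single outcome class twice in a row")
}

draw_split <- function(y, train_fraction, stratify_split) {
  n <- length(y)
  if (stratify_split) {
    i1 <- which(y == 1); i0 <- which(y == 0)
    c(sample(i1, round(train_fraction * length(i1))),
      sample(i0, round(train_fraction * length(i0))))
  } else {
    sample.int(n, round(train_fraction * n))
  }
}

#' Bootstrap delta-AUC test of added predictive value
#'
#' Per bootstrap replicate: draw `n` rows with replacement, split 70/30, fit
#' the reference and the augmented logistic model on the training part, and
#' record both AUCs on the held-out part (a paired comparison — both models
#' see the same resample and split). The headline AUCs are the means of the
#' per-replicate test-set AUCs; the empirical p-value is the proportion of
#' replicates whose delta-AUC (test minus reference) falls below zero, with
#' exact zeros counted at half weight.
#'
#' Replicate-level RNG streams are derived deterministically from `seed`
#' (prefix-stable: increasing `B` does not reshuffle earlier replicates).
#' Replicates whose split leaves a single outcome class are dropped and
#' counted; more than 5\% failures is an error.
#'
#' @inheritParams train_test_auc
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed governing resampling and splits.
#' @param balanced Undersample the majority class once, before
#'   bootstrapping, so cases and controls are equally many (default
#'   `FALSE`).
#' @return A list of class `added_value_report`: `auc_reference`,
#'   `auc_test`, `delta_auc` (length-B vector), `p_value`, `B`,
#'   `train_fraction`, `seed`, `balanced`, `n`, `n_failed`.
#' @export
bootstrap_delta_auc <- function(data, outcome, ref_terms, test_terms,
                                B = 1000, train_fraction = 0.7, seed = 1,
                                balanced = FALSE, stratify_split = FALSE) {
  if (balanced) {
    set.seed(seed)
    data <- undersample_balance(data, outcome)
  }
  pd <- prep_design(data, outcome, ref_terms, test_terms)
  n <- pd$n
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, B)
  auc_ref <- auc_test <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    boot <- sample.int(n, n, replace = TRUE)
    idx <- draw_split(pd$y[boot], train_fraction, stratify_split)
    res <- split_fit_auc(pd$y[boot],
                         pd$X_ref[boot, , drop = FALSE],
                         pd$X_test[boot, , drop = FALSE], idx)
    if (!is.null(res)) {
      auc_ref[b] <- res[1]
      auc_test[b] <- res[2]
    }
  }
  ok <- !is.na(auc_ref)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    stop(n_failed, " of ", B, " bootstrap replicates failed (degenerate splits)")
  }
  delta <- auc_test[ok] - auc_ref[ok]
  p <- (sum(delta < 0) + 0.5 * sum(delta == 0)) / length(delta)
  structure(
    list(auc_reference = mean(auc_ref[ok]), auc_test = mean(auc_test[ok]),
         delta_auc = delta, p_value = p, B = B,
         train_fraction = train_fraction, seed = seed, balanced = balanced,
         n = n, n_failed = n_failed,
         auc_ref_draws = auc_ref[ok], auc_test_draws = auc_test[ok]),
    class = "added_value_report"
  )
}

#' @export
print.added_value_report <- function(x, ...) {
  cat("Added predictive value (bootstrap train/test delta-AUC)\n",
      sprintf("  reference AUC: %.3f\n", x$auc_reference),
      sprintf("  augmented AUC: %.3f\n", x$auc_test),
      sprintf("  mean delta-AUC: %.4f\n", mean(x$delta_auc)),
      sprintf("  empirical p (delta < 0): %.3g\n", x$p_value),
      sprintf("  B = %d (%d failed), n = %d%s\n", x$B, x$n_failed, x$n,
              if (x$balanced) ", balanced by undersampling" else ""),
      sep = "")
  invisible(x)
}

#' Density plot of the bootstrap delta-AUC distribution
#' @param x An `added_value_report`.
#' @param ... Passed to `plot()`.
#' @export
plot.added_value_report <- function(x, ...) {
  plot(stats::density(x$delta_auc), main = "Bootstrap delta-AUC",
       xlab = expression(Delta * "AUC"), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Balance classes by undersampling the majority class
#'
#' Randomly subsamples the majority outcome class, without replacement, down
#' to the minority count, so both classes are equally represented.
#'
#' @param data Data frame.
#' @param outcome Binary outcome column name.
#' @return The balanced data frame (row order: as sampled).
#' @export
undersample_balance <- function(data, outcome) {
  y <- data[[outcome]]
  if (length(unique(stats::na.omit(y))) < 2) {
    stop("undersampling needs both outcome classes")
  }
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (length(i1) == length(i0)) return(data)
  if (length(i1) > length(i0)) {
    keep <- c(sample(i1, length(i0)), i0)
  } else {
    keep <- c(i1, sample(i0, length(i1)))
  }
  data[sort(keep), , drop = FALSE]
}
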