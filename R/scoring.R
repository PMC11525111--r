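# Genetic risk score computation, standardization and quantile-interval bins.

#' Compute the raw weighted genetic risk score
#'
#' The raw score of sample \eqn{j} is \eqn{\sum_i w_i d_{ij}}: the sum of
#' effect-allele dosages weighted by the per-allele effect sizes. The dosage
#' matrix must already be harmonized to the effect alleles and its columns
#' must match the weights one-to-one. Missing dosages are imputed with the
#' per-variant mean dosage (twice the estimated allele frequency) before
#' scoring, so every sample is scoreable; `n_variants_used` records how many
#' variants contributed a non-imputed dosage per sample.
#'
#' @param weights A `grs_weights` data frame.
#' @param dm An aligned `dosage_matrix`.
#' @return A data frame of class `grs_score` with columns `sample_id`, `raw`
#'   and `n_variants_used`.
#' @export
compute_grs <- function(weights, dm) {
  if (length(dm$variant_ids) != nrow(weights) ||
      !all(dm$variant_ids == weights$variant_id)) {
    stop("dosage matrix columns do not match the weights one-to-one")
  }
  d <- dm$dosages
  n_used <- rowSums(!is.na(d))
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  raw <- as.numeric(d %*% weights$effect_weight)
  if (any(!is.finite(raw))) stop("non-finite raw score")
  out <- data.frame(sample_id = dm$sample_ids, raw = raw,
                    n_variants_used = n_used, stringsAsFactors = FALSE)
  attr(out, "n_imputed") <- sum(n_used < nrow(weights))
  class(out) <- c("grs_score", "data.frame")
  out
}

#' Standardize a genetic risk score to zero mean and unit SD
#'
#' Standardization uses the sample standard deviation (n - 1 denominator)
#' and is computed within the supplied cohort, matching per-cohort per-SD
#' odds-ratio reporting.
#'
#' @param scores A `grs_score` with a `raw` column.
#' @return The input with a `standardized` column added.
#' @export
standardize_grs <- function(scores) {
  if (nrow(scores) < 2) stop("standardization needs at least 2 samples")
  s <- stats::sd(scores$raw)
  if (!is.finite(s) || s == 0) {
    stop("degenerate score: raw values have zero variance")
  }
  scores$standardized <- (scores$raw - mean(scores$raw)) / s
  scores
}

#' Assign samples to quantile-interval bins of a score
#'
#' Bins are bounded by the empirical quantiles at k/n_bins (five edges for
#' the default four quartile intervals). Intervals are left-open,
#' right-closed, except the lowest which includes its minimum; values equal
#' to an internal edge therefore fall in the lower bin. The lowest interval
#' (Q1) is the reference group in downstream association models.
#'
#' @param scores A `grs_score`; the `standardized` column is binned when
#'   present, otherwise `raw` (bin membership is invariant to the choice,
#'   standardization being monotone).
#' @param n_bins Number of quantile intervals (default 4).
#' @return A list of class `quantile_bins` with `bin` (a factor Q1..Qk per
#'   sample), `bin_edges` and `reference_bin`.
#' @export
quantile_bins <- function(scores, n_bins = 4) {
  x <- scores$standardized %||% scores$raw
  if (length(unique(x)) < n_bins) {
    stop("fewer than ", n_bins, " distinct score values; use fewer bins")
  }
  edges <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE)
  labels <- paste0("Q", seq_len(n_bins))
  bin <- cut(x, breaks = edges, labels = labels, include.lowest = TRUE,
             right = TRUE)
  if (anyNA(bin) || any(table(bin) == 0)) {
    stop("ties in the score left a quantile bin empty; use fewer bins")
  }
  structure(list(bin = bin, bin_edges = edges, reference_bin = "Q1",
                 sample_id = scores$sample_id),
            class = "quantile_bins")
}

#' Write a score vector as TSV (sample_id, raw, standardized, bin)
#' @param scores A `grs_score`.
#' @param path Output path.
#' @param bins Optional `quantile_bins` to include.
#' @export
write_scores <- function(scores, path, bins = NULL) {
  df <- as.data.frame(scores)
  if (!is.null(bins)) df$bin <- as.character(bins$bin)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
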