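#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed as the probability that a random
#' presence score exceeds a random background score, with ties counted 0.5 —
#' the Mann-Whitney U statistic scaled to `[0, 1]`. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors for the
#'   positive (presence) and negative (background) class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity-plus-specificity-optimal threshold
#'
#' Scans every observed score (the union of both vectors) as a candidate
#' cutoff under the rule "suitable iff score >= t" and returns the candidate
#' maximizing sensitivity + specificity (Youden's J shifted by 1) — the
#' optimized specificity-sensitivity criterion for converting ranked
#' suitability into a binary map. Ties are broken toward the smallest
#' threshold.
#'
#' @inheritParams auc
#' @return A one-row tibble with `threshold`, `sensitivity_at`,
#'   `specificity_at`.
#' @export
optimal_threshold <- function(pos_scores, neg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  cand <- sort(unique(c(pos_scores, neg_scores)))
  sp <- sort(pos_scores); sn <- sort(neg_scores)
  # counts strictly below each candidate, via sorted lookup
  sens <- (length(sp) - findInterval(cand, sp, left.open = TRUE)) / length(sp)
  spec <- findInterval(cand, sn, left.open = TRUE) / length(sn)
  best <- which.max(sens + spec)  # which.max takes the first (smallest t) on ties
  tibble::tibble(threshold = cand[best],
                 sensitivity_at = sens[best],
                 specificity_at = spec[best])
}

#' Confusion statistics of a binary map against a range mask
#'
#' Cross-tabulates predicted suitability against the estimated range over
#' the evaluable cells: cells that are nodata in either raster, or
#' `no_consensus` in the prediction (unanimity ensembles), are excluded.
#' Cells inside the range mask are the positive class.
#'
#' Undefined ratios (e.g. sensitivity when the mask has no in-range cell) are
#' reported as `NA`, never 0.
#'
#' @param pred A `binary_map` (values 0/1/2 = unsuitable/suitable/no
#'   consensus) or any [raster_grid()] of 0/1 values.
#' @param truth A [buffer_range_mask()] (or any 0/1 raster) on the same
#'   geometry.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `n_excluded`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_stats <- function(pred, truth) {
  stopifnot(inherits(pred, "raster_grid"), inherits(truth, "raster_grid"))
  stopifnot_same_geometry(list(pred, truth), "pred and truth")
  p <- as.vector(pred$values)
  t <- as.vector(truth$values)
  use <- !is.na(p) & !is.na(t) & p != 2
  if (!any(use)) stop("no evaluable cells (all nodata or no-consensus)", call. = FALSE)
  p <- p[use]; t <- t[use]
  tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
  tn <- sum(p == 0 & t == 0); fn <- sum(p == 0 & t == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_excluded = sum(!use),
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp)
  )
}

#' Mean and standard deviation across cross-validation folds
#'
#' @param values Numeric vector, one value per fold.
#' @return A one-row tibble with `n`, `mean`, `sd`; `sd` uses the sample
#'   (n - 1) convention and is `NA` for fewer than two folds.
#' @export
summarize_folds <- function(values) {
  values <- as.numeric(values)
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_
  )
}
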