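# Imbalance-aware evaluation: confusion counts, recall/precision/F1,
# precision-recall curve with non-linear (Davis-Goadrich) interpolation,
# paired signed-rank comparison, and top-k ranking evaluation.

#' Confusion counts for aligned label vectors
#'
#' @param predicted logical vector (or "binding"/"nonbinding" labels) of
#'   predictions.
#' @param truth matching ground-truth vector.
#' @return List with integers TP, FP, TN, FN.
#' @export
confusion_counts <- function(predicted, truth) {
  as_l <- function(v) if (is.logical(v)) v else v == "binding"
  p <- as_l(predicted); t <- as_l(truth)
  if (length(p) != length(t))
    stop("predicted and truth have different lengths")
  if (!is.null(names(p)) && !is.null(names(t)) &&
      !identical(names(p), names(t)))
    stop("predicted and truth are not aligned on the same residues")
  list(TP = sum(p & t), FP = sum(p & !t),
       TN = sum(!p & !t), FN = sum(!p & t))
}

#' Recall, precision and F1 from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2 P R / (P + R)`; any metric with a zero denominator is 0 by
#' convention.
#'
#' @param counts list from [confusion_counts()].
#' @return List with `recall`, `precision`, `f1`.
#' @export
classification_metrics <- function(counts) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  r <- safe(counts$TP, counts$TP + counts$FN)
  p <- safe(counts$TP, counts$TP + counts$FP)
  list(recall = r, precision = p, f1 = safe(2 * p * r, p + r))
}

#' Precision-recall curve with non-linear interpolation
#'
#' Builds the PR curve over all distinct score thresholds (descending; tied
#' scores share a threshold) and computes its area by the non-linear
#' interpolation of Davis and Goadrich, as implemented by the
#' AUCCalculator program: between consecutive achievable (TP, FP) points
#' the false positives are interpolated linearly in TP, giving one
#' precision value per unit of true positives, and the area is the
#' trapezoidal integral of precision over recall starting from the
#' smallest achievable recall (one true positive), anchored below that
#' recall at the first point's precision.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth logical ground truth (or "binding"/"nonbinding").
#' @return Object of class `pr_curve`: data frame of (recall, precision)
#'   at unit-TP resolution and the interpolated `auc`.
#' @export
pr_curve <- function(scores, truth) {
  if (!is.logical(truth)) truth <- truth == "binding"
  stopifnot(length(scores) == length(truth))
  P <- sum(truth)
  if (P == 0 || all(truth))
    stop("PR curve needs at least one positive and one negative example")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  cum_tp <- cumsum(y); cum_fp <- cumsum(!y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_tie]; fp <- cum_fp[last_of_tie]
  # interpolate FP linearly in TP between achievable points
  tp_grid <- seq_len(P)
  fp_grid <- numeric(P)
  pts_tp <- c(0, tp); pts_fp <- c(0, fp)
  for (t in tp_grid) {
    k <- which(pts_tp >= t)[1]  # first achievable point reaching t TPs
    t0 <- pts_tp[k - 1]; f0 <- pts_fp[k - 1]
    t1 <- pts_tp[k]; f1 <- pts_fp[k]
    fp_grid[t] <- if (t1 == t0) f1 else f0 + (f1 - f0) * (t - t0) / (t1 - t0)
  }
  recall <- tp_grid / P
  precision <- tp_grid / (tp_grid + fp_grid)
  # trapezoids over the achievable range [1/P, 1]; below the smallest
  # achievable recall the curve is anchored at the first point's precision,
  # so a perfect ranking scores exactly 1 and random scores stay near the
  # prevalence
  auc <- if (P == 1) precision[1] else
    precision[1] / P + sum((precision[-1] + precision[-P]) / 2) / P
  out <- list(points = data.frame(recall = recall, precision = precision),
              auc = auc, n_pos = P, n_neg = sum(!truth))
  class(out) <- "pr_curve"
  out
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve over %d positives / %d negatives: AUC %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$points$recall, x$points$precision, type = "l",
                 xlab = "Recall", ylab = "Precision",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(h = x$n_pos / (x$n_pos + x$n_neg), lty = 2, col = "grey")
  invisible(x)
}

#' Area under the precision-recall curve
#'
#' @inheritParams pr_curve
#' @return The interpolated PR-AUC (scalar).
#' @export
pr_auc <- function(scores, truth) pr_curve(scores, truth)$auc

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired per-chain performance values.
#' Zero differences are dropped; the exact distribution is used for up to
#' 49 untied pairs, the normal approximation with continuity and tie
#' correction otherwise. When every pair is tied the p-value is 1, with a
#' warning.
#'
#' @param a,b paired metric vectors (e.g. per-chain PR-AUC of two methods).
#' @return List with `p.value`, `statistic` (V), and `n` (non-zero pairs).
#' @export
signed_rank_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(list(p.value = 1, statistic = NA, n = 0))
  }
  exact <- length(d) < 50 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       n = length(d))
}

#' Top-k ranking evaluation
#'
#' Predicts the k highest-ranked surface residues by a per-residue scalar
#' (ties broken by position in the chain) and scores the prediction against
#' the true binding set. When k equals the size of the true set, recall and
#' precision coincide.
#'
#' @param values named per-residue scalar (names = residue keys, in chain
#'   order).
#' @param truth_keys keys of the true binding residues.
#' @param k number of residues to call binding.
#' @return List with `recall`, `precision`, `predicted` (keys), and the
#'   confusion counts.
#' @export
top_k_eval <- function(values, truth_keys, k) {
  if (k <= 0) stop("k must be positive")
  if (k > length(values))
    stop("k exceeds the number of ranked residues")
  ord <- order(values, seq_along(values), decreasing = c(TRUE, FALSE),
               method = "radix")
  predicted <- names(values)[ord[seq_len(k)]]
  cc <- confusion_counts(names(values) %in% predicted,
                         names(values) %in% truth_keys)
  m <- classification_metrics(cc)
  list(recall = m$recall, precision = m$precision, predicted = predicted,
       counts = cc)
}
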