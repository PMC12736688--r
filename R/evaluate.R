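#' Confusion counts for binary rice classification
#'
#' Tabulates true/false positives and negatives with rice (label 1) as the
#' positive class.
#'
#' @param y_true,y_pred Vectors of labels in `{0, 1}`.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be 0 (non-rice) or 1 (rice)")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and Cohen's kappa. Kappa uses the
#' standard chance-corrected form `(Po - Pe) / (1 - Pe)` with the expected
#' agreement computed from the marginals,
#' `Pe = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / N^2`. Ratios with zero
#' denominators are reported as `NA` and listed in the `"flagged"`
#' attribute.
#'
#' @param cm A [confusion_counts()] or a list with `TP`, `TN`, `FP`, `FN`.
#' @return Named list `accuracy`, `precision`, `recall`, `f1`, `kappa`,
#'   with attribute `"flagged"` naming any undefined metric.
#' @export
classification_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  N <- TP + TN + FP + FN
  if (N <= 0) stop("empty confusion matrix")
  flagged <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); return(NA_real_) }
    num / den
  }
  acc <- (TP + TN) / N
  prec <- div(TP, TP + FP, "precision")
  rec <- div(TP, TP + FN, "recall")
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    flagged <- c(flagged, "f1"); NA_real_
  } else 2 * prec * rec / (prec + rec)
  pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / N^2
  kap <- if (pe == 1) { flagged <- c(flagged, "kappa"); NA_real_ }
  else (acc - pe) / (1 - pe)
  structure(list(accuracy = acc, precision = prec, recall = rec,
                 f1 = f1, kappa = kap),
            flagged = flagged)
}

#' McNemar paired comparison of two classifiers
#'
#' Counts the discordant predictions of classifiers A and B on the same
#' samples (`b`: A correct and B wrong, `c`: A wrong and B correct) and
#' tests the null that both are equally accurate with the chi-squared
#' statistic on one degree of freedom: `(|b - c| - 1)^2 / (b + c)` with the
#' continuity correction (default), `(b - c)^2 / (b + c)` without. With no
#' discordant pairs the statistic is 0 and p = 1.
#'
#' @param y_true True labels.
#' @param pred_a,pred_b Predictions of classifiers A and B.
#' @param continuity Apply the continuity correction (default TRUE).
#' @return A `mcnemar_result`: `b`, `c`, `chi2`, `p_value`,
#'   `continuity_corrected`.
#' @export
mcnemar_compare <- function(y_true, pred_a, pred_b, continuity = TRUE) {
  if (length(pred_a) != length(y_true) || length(pred_b) != length(y_true))
    stop("prediction vectors must align with y_true")
  ca <- pred_a == y_true
  cb <- pred_b == y_true
  mcnemar_from_counts(sum(ca & !cb), sum(!ca & cb), continuity = continuity)
}

#' @rdname mcnemar_compare
#' @param b,c Discordant-pair counts (A correct & B wrong, A wrong & B
#'   correct), e.g. from a published comparison table.
#' @export
mcnemar_from_counts <- function(b, c, continuity = TRUE) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- if (continuity) (abs(b - c) - 1)^2 / n else (b - c)^2 / n
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = c, chi2 = chi2, p_value = p,
                 continuity_corrected = continuity),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar%s: b = %d, c = %d, chi2 = %.4f, p = %.3g\n",
              if (x$continuity_corrected) " (continuity-corrected)" else "",
              x$b, x$c, x$chi2, x$p_value))
  invisible(x)
}

#' Class-conditional summary of predicted probabilities
#'
#' Histograms the predicted rice probability separately for rice and
#' non-rice samples and reports the overlap coefficient of the two binned
#' densities (0 = perfectly separated confidence, 1 = indistinguishable).
#'
#' @param prob Predicted rice probabilities in `[0, 1]`.
#' @param label True labels in `{0, 1}`.
#' @param bins Number of equal-width bins over `[0, 1]`.
#' @return List with `breaks`, per-class `density` matrices and `overlap`.
#' @export
probability_summary <- function(prob, label, bins = 20) {
  stopifnot(all(prob >= 0), all(prob <= 1), length(prob) == length(label))
  breaks <- seq(0, 1, length.out = bins + 1)
  dens <- function(p) {
    if (!length(p)) return(rep(0, bins))
    h <- graphics::hist(p, breaks = breaks, plot = FALSE)
    h$density
  }
  d0 <- dens(prob[label == 0])
  d1 <- dens(prob[label == 1])
  w <- diff(breaks)
  structure(list(breaks = breaks,
                 density = rbind(non_rice = d0, rice = d1),
                 overlap = sum(pmin(d0, d1) * w)),
            class = "probability_summary")
}

#' Area agreement ratio
#'
#' Percent agreement between two area totals (e.g. a mapped rice area and
#' an official statistic), `100 * min(a, b) / max(a, b)`; symmetric, so an
#' overestimate and an underestimate of the same relative size score
#' equally.
#'
#' @param area_a,area_b Positive areas in the same unit.
#' @return Agreement in percent.
#' @export
#' @examples
#' area_agreement(4.031e4, 4.394e4)  # 91.74
area_agreement <- function(area_a, area_b) {
  stopifnot(area_a > 0, area_b > 0)
  100 * min(area_a, area_b) / max(area_a, area_b)
}

#' Evaluation report for a trained classifier
#'
#' Convenience wrapper producing confusion counts, derived metrics and the
#' probability summary for one model on one test set.
#'
#' @param y_true True labels.
#' @param prob Predicted rice probabilities.
#' @param threshold Classification threshold on the rice probability.
#' @return An `eval_report` list.
#' @export
eval_report <- function(y_true, prob, threshold = 0.5) {
  y_pred <- as.integer(prob >= threshold)
  cm <- confusion_counts(y_true, y_pred)
  structure(list(confusion = cm, metrics = classification_metrics(cm),
                 probability = probability_summary(prob, y_true),
                 threshold = threshold, n = length(y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cm <- x$confusion; m <- x$metrics
  cat("eval_report on", x$n, "samples (threshold", x$threshold, ")\n")
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", cm$TP, cm$FN, cm$FP, cm$TN))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  kappa %.3f\n",
              m$accuracy, m$precision, m$recall, m$f1, m$kappa))
  cat(sprintf("  probability overlap %.3f\n", x$probability$overlap))
  invisible(x)
}
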