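# Cohort-level diagnostic performance of the WM/MZL calls: confusion
# matrix with Se/Sp/PPV/NPV, nonparametric ROC over the integer score
# thresholds, trapezoidal AUC (equal to the tie-corrected concordance
# probability) and Youden-index threshold selection. WM is the positive
# class throughout.

#' Confusion matrix and predictive values
#'
#' @param calls Character vector of `"WM"`/`"MZL"` calls.
#' @param truth Character vector of true labels, same length.
#' @return A `wm_diag_metrics`: counts `tp`, `fn`, `fp`, `tn` and
#'   proportions `sensitivity`, `specificity`, `ppv`, `npv`, `prevalence`
#'   (a proportion is `NA` and flagged when its denominator is zero).
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("calls/truth length mismatch")
  if (!length(calls)) stop("empty input")
  bad <- setdiff(unique(c(calls, truth)), c("WM", "MZL", NA))
  if (length(bad)) stop("labels must be WM/MZL; found: ", paste(bad, collapse = ", "))
  tp <- sum(calls == "WM" & truth == "WM", na.rm = TRUE)
  fn <- sum(calls == "MZL" & truth == "WM", na.rm = TRUE)
  fp <- sum(calls == "WM" & truth == "MZL", na.rm = TRUE)
  tn <- sum(calls == "MZL" & truth == "MZL", na.rm = TRUE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  flags <- character()
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    den <- switch(nm, sensitivity = tp + fn, specificity = tn + fp,
                  ppv = tp + fp, npv = tn + fn)
    if (den == 0) flags <- c(flags, paste0(nm, "_undefined"))
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 prevalence = (tp + fn) / (tp + fn + fp + tn),
                 flags = flags),
            class = "wm_diag_metrics")
}

#' @export
print.wm_diag_metrics <- function(x, ...) {
  cat("wm_diag_metrics (WM = positive class)\n")
  cat(sprintf("  tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  Se=%.1f%%  Sp=%.1f%%  PPV=%.1f%%  NPV=%.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' Nonparametric ROC curve over integer score thresholds
#'
#' One operating point per threshold `t` in `0..max_total + 1`, with the
#' call "score >= t". The AUC is the trapezoidal area under the
#' (1-specificity, sensitivity) points, which for a discrete score equals
#' the Mann-Whitney concordance probability with ties counted one half.
#'
#' @param scores Integer score totals.
#' @param truth `"WM"`/`"MZL"` labels.
#' @param max_total Highest attainable total (default: `max(scores)`);
#'   adding unattainable thresholds does not change the AUC.
#' @return A `wm_roc`: data.frame `points` (threshold, sensitivity,
#'   specificity, fpr), `auc`, `youden_threshold`, `youden_j`.
#' @export
roc_curve <- function(scores, truth, max_total = NULL) {
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  if (length(unique(truth)) < 2)
    stop("single-class input: ROC requires both WM and MZL labels")
  if (is.null(max_total)) max_total <- max(scores)
  pos <- truth == "WM"
  thresholds <- seq(0L, as.integer(max_total) + 1L)
  sens <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!pos] < t), numeric(1))
  pts <- data.frame(threshold = thresholds, sensitivity = sens,
                    specificity = spec, fpr = 1 - spec)
  # trapezoid over points ordered by decreasing threshold (fpr increasing)
  ord <- order(-pts$threshold)
  x <- pts$fpr[ord]; y <- pts$sensitivity[ord]
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[length(best)]  # ties broken toward the higher threshold
  structure(list(points = pts, auc = auc,
                 youden_threshold = thresholds[best], youden_j = j[best]),
            class = "wm_roc")
}

#' Youden-optimal threshold
#'
#' The threshold maximising J = sensitivity + specificity - 1, with ties
#' broken toward the higher threshold (higher specificity).
#'
#' @param roc A `wm_roc` from [roc_curve()].
#' @return List with `threshold` and `j`.
#' @export
youden_optimal <- function(roc) {
  list(threshold = roc$youden_threshold, j = roc$youden_j)
}

#' @export
print.wm_roc <- function(x, ...) {
  cat(sprintf("wm_roc: AUC=%.4f, Youden-optimal threshold %d (J=%.3f)\n",
              x$auc, x$youden_threshold, x$youden_j))
  invisible(x)
}

#' Evaluate a scored cohort
#'
#' Convenience wrapper: confusion matrix at the compartment's decision
#' threshold plus the full ROC with Youden selection.
#'
#' @param scores Integer totals.
#' @param truth `"WM"`/`"MZL"` labels.
#' @param compartment `"BM"` (threshold 3, max 6) or `"PB"` (4, max 7).
#' @return List with `metrics` (`wm_diag_metrics`) and `roc` (`wm_roc`).
#' @export
evaluate_cohort <- function(scores, truth, compartment = "BM") {
  compartment <- toupper(compartment)
  max_total <- if (compartment == "BM") 6L else 7L
  calls <- vapply(scores, classify, character(1), compartment = compartment)
  list(metrics = confusion(calls, truth),
       roc = roc_curve(scores, truth, max_total = max_total))
}
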