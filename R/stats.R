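# Rank-based cohort comparisons: Mann-Whitney rank-sum, Spearman rank
# correlation, and the CD38-vs-CXCR4-mutation association. These wrap the
# base-R tests (wilcox.test, cor.test, fisher.test); this module fixes the
# conventions (U statistic, exact-vs-approximate switching, tie handling)
# and the result container.

new_test_result <- function(statistic, p_value, n1, n2, method,
                            flags = character()) {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, method = method, flags = flags),
            class = "wm_test")
}

#' @export
print.wm_test <- function(x, ...) {
  cat(sprintf("wm_test: %s  statistic=%.4g  p=%.4g  (n1=%d, n2=%d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic for the first group, with the exact null distribution when
#' the smaller group has at most 8 observations and there are no ties, and
#' the tie-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `wm_test` with `statistic` (U), `p_value`, group sizes.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  if (!length(a) || !length(b)) stop("empty group in Mann-Whitney test")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = !exact))
  new_test_result(statistic = unname(wt$statistic), p_value = wt$p.value,
                  n1 = length(a), n2 = length(b),
                  method = if (exact) "Mann-Whitney (exact)"
                           else "Mann-Whitney (normal approximation)")
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank tie handling; the p-value uses the
#' t-distribution approximation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A `wm_test` with `statistic` (rho) and `p_value`; a constant
#'   input yields an `NA` statistic flagged `undefined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x/y length mismatch")
  if (length(x) < 3) stop("Spearman correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(new_test_result(NA_real_, NA_real_, length(x), length(y),
                           "Spearman (undefined: constant input)",
                           flags = "undefined"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  new_test_result(statistic = unname(ct$estimate), p_value = ct$p.value,
                  n1 = length(x), n2 = length(y), method = "Spearman")
}

#' Association between CD38 expression and CXCR4 mutation status
#'
#' Compares CD38 expression between CXCR4-mutated and unmutated patients.
#' The default compares percent-positive by Mann-Whitney; `method =
#' "fisher"` instead dichotomises CD38 at its 30% positivity threshold and
#' applies Fisher's exact test; `variable = "mfi_ratio"` uses the MFI
#' ratio rather than the percent.
#'
#' @param profiles List of `wm_profile` with `cxcr4` labels (`"mutated"` /
#'   `"unmutated"`) and a CD38 grade.
#' @param method `"ranksum"` (default) or `"fisher"`.
#' @param variable `"percent"` (default) or `"mfi_ratio"`.
#' @return A `wm_test` (mutated group first).
#' @export
cd38_cxcr4_association <- function(profiles, method = c("ranksum", "fisher"),
                                   variable = c("percent", "mfi_ratio")) {
  method <- match.arg(method); variable <- match.arg(variable)
  val <- vapply(profiles, function(p) {
    g <- p$grades[["CD38"]]
    if (is.null(g)) NA_real_
    else if (variable == "percent") g$percent_positive else g$mfi_ratio
  }, numeric(1))
  mut <- vapply(profiles, function(p) p$cxcr4 %||% NA_character_, character(1))
  keep <- !is.na(val) & mut %in% c("mutated", "unmutated")
  val <- val[keep]; mut <- mut[keep]
  if (length(unique(mut)) < 2)
    stop("single-group input: both mutated and unmutated patients required")
  if (sum(mut == "mutated") < 2 || sum(mut == "unmutated") < 2)
    stop("at least 2 patients per mutation group required")
  if (method == "ranksum") {
    res <- mann_whitney(val[mut == "mutated"], val[mut == "unmutated"])
    res$method <- paste0("CD38 ", variable, " vs CXCR4, ", res$method)
    res
  } else {
    pos <- val >= 30
    tab <- table(factor(mut, c("mutated", "unmutated")),
                 factor(pos, c(FALSE, TRUE)))
    ft <- stats::fisher.test(tab)
    new_test_result(statistic = unname(ft$estimate), p_value = ft$p.value,
                    n1 = sum(mut == "mutated"), n2 = sum(mut == "unmutated"),
                    method = "CD38 positivity vs CXCR4, Fisher exact")
  }
}
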