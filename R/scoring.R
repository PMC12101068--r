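# The WM/MZL scoring systems: 6 criteria in bone marrow, 7 in peripheral
# blood (the extra blood criterion is a clonal B-cell fraction below 10%
# of lymphocytes). One point per satisfied criterion; WM is called at a
# total of 3/6 or more (BM) or 4/7 or more (PB).
#
# Criterion table (1 point each):
#   CD19  weak (or negative) expression
#   FMC7  negative or weak expression
#   CD22  weak (or negative) expression
#   CD79b strong expression, provided CD22 is negative or weak
#   CD27  negative or weak expression
#   CD13  expressed on >= 2% of clonal B cells
#   [PB]  clonal B cells < 10% of total lymphocytes
#
# The table's CD22 row awards the point for "weak"; a fully negative CD22
# is weaker still and is scored the same way (monotone reading, matching
# the explicit "CD22-/weak" wording of the CD79b condition). Likewise for
# CD19.

BM_THRESHOLD <- 3L
PB_THRESHOLD <- 4L

grade_of <- function(profile, marker) {
  g <- profile$grades[[marker]]
  if (is.null(g)) NA_character_ else g$grade
}

criterion_points <- function(profile, compartment) {
  g <- function(mk) grade_of(profile, mk)
  low <- function(x) if (is.na(x)) NA else x %in% c("negative", "weak")
  cd22_low <- low(g("CD22"))
  cd13 <- profile$grades[["CD13"]]
  pts <- c(
    CD19 = low(g("CD19")),
    FMC7 = low(g("FMC7")),
    CD22 = cd22_low,
    CD79b = if (is.na(g("CD79b")) || is.na(cd22_low)) NA
            else (g("CD79b") == "strong" && cd22_low),
    CD27 = low(g("CD27")),
    CD13 = if (is.null(cd13)) NA else cd13$percent_positive >= 2
  )
  if (toupper(compartment) == "PB") {
    pts <- c(pts, clonal_fraction = if (is.na(profile$clonal_fraction)) NA
             else profile$clonal_fraction < 10)
  }
  pts
}

new_score_result <- function(points, compartment, threshold,
                             fmc7_grade = NA_character_) {
  available <- !is.na(points)
  total <- sum(points[available])
  n_missing <- sum(!available)
  call <- if (total >= threshold) "WM"
          else if (total + n_missing < threshold) "MZL"
          else NA_character_
  advisory <- character()
  if (identical(call, "WM") && identical(fmc7_grade, "strong"))
    advisory <- "strong FMC7 expression supports MZL despite the score"
  structure(list(compartment = compartment,
                 criterion_points = as.integer(points),
                 criteria = names(points),
                 total = as.integer(total),
                 max_total = as.integer(sum(available)),
                 full_max = length(points),
                 threshold = as.integer(threshold),
                 call = call,
                 missing_criteria = names(points)[!available],
                 advisory = advisory),
            class = "wm_score")
}

#' Bone-marrow 6-point WM/MZL score
#'
#' Applies the six BM criteria (see package overview) to a graded profile
#' and calls WM when the total reaches 3/6. Criteria whose marker grade is
#' missing are excluded: the maximum attainable total is reduced and no
#' confident call is made when the missing points could change it (the
#' call is then `NA` with the criteria listed in `missing_criteria`).
#'
#' @param profile A `wm_profile` from a bone-marrow sample.
#' @return A `wm_score` with per-criterion points, total, threshold and
#'   the WM/MZL call.
#' @export
bm_score <- function(profile) {
  if (toupper(profile$compartment) != "BM")
    stop("bm_score expects a BM profile (got ", profile$compartment, ")")
  new_score_result(criterion_points(profile, "BM"), "BM", BM_THRESHOLD,
                   fmc7_grade = grade_of(profile, "FMC7"))
}

#' Peripheral-blood 7-point WM/MZL score
#'
#' The six BM criteria plus one point when clonal B cells are below 10% of
#' total lymphocytes (small circulating clones are typical of WM, large
#' ones of MZL); WM is called at 4/7. A clonal fraction of exactly 10%
#' does not score (the rule is strictly below 10%). An unknown clonal
#' fraction makes that criterion missing, handled as in [bm_score()].
#'
#' @param profile A `wm_profile` from a peripheral-blood sample.
#' @return A `wm_score`.
#' @export
pb_score <- function(profile) {
  if (toupper(profile$compartment) != "PB")
    stop("pb_score expects a PB profile (got ", profile$compartment, ")")
  new_score_result(criterion_points(profile, "PB"), "PB", PB_THRESHOLD,
                   fmc7_grade = grade_of(profile, "FMC7"))
}

#' Score a profile in its own compartment
#' @param profile A `wm_profile`.
#' @return A `wm_score` from [bm_score()] or [pb_score()].
#' @export
score_profile <- function(profile) {
  if (toupper(profile$compartment) == "PB") pb_score(profile) else bm_score(profile)
}

#' Classify a score total
#'
#' @param total Integer score total.
#' @param compartment `"BM"` or `"PB"`.
#' @return `"WM"` if `total >= 3` (BM) or `total >= 4` (PB), else `"MZL"`.
#' @export
classify <- function(total, compartment) {
  compartment <- toupper(compartment)
  stopifnot(compartment %in% c("BM", "PB"))
  thr <- if (compartment == "BM") BM_THRESHOLD else PB_THRESHOLD
  max_total <- if (compartment == "BM") 6L else 7L
  if (total < 0 || total > max_total) stop("total out of range for ", compartment)
  if (total >= thr) "WM" else "MZL"
}

#' @export
print.wm_score <- function(x, ...) {
  cat(sprintf("wm_score (%s): %d/%d  threshold %d  call: %s\n",
              x$compartment, x$total, x$max_total, x$threshold,
              ifelse(is.na(x$call), "indeterminate", x$call)))
  for (i in seq_along(x$criteria))
    cat(sprintf("  %-16s %s\n", x$criteria[i],
                ifelse(is.na(x$criterion_points[i]), "missing",
                       x$criterion_points[i])))
  if (length(x$advisory)) cat("  advisory:", x$advisory, "\n")
  invisible(x)
}

#' Serialise a score result to a list (for JSON/CSV output)
#' @param x A `wm_score`.
#' @return A plain list with integer points.
#' @export
score_as_list <- function(x) {
  list(compartment = x$compartment,
       criterion_points = setNames(as.list(x$criterion_points), x$criteria),
       total = x$total, max_total = x$max_total, threshold = x$threshold,
       call = x$call, missing_criteria = x$missing_criteria,
       advisory = x$advisory)
}
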