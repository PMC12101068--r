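# Grading: percent-positive + MFI -> categorical expression grades
# (negative / weak / normal / strong) relative to reference B-cell MFI.
#
# The scores consume grades, not raw intensities. A marker is negative when
# its percent-positive falls below the positivity threshold (30%, or 2% for
# CD13); otherwise its grade is set by the ratio of the clonal population's
# MFI to a reference normal-B-cell MFI. The weak/strong boundaries default
# to a symmetric two-fold shift (ratio 0.5 and 2.0), the conventional
# clinical reading of "dim"/"bright"; they are configurable because no
# published numeric boundary exists for these categories.

#' Reference ranges for grading
#'
#' Per-marker reference MFI of normal mature B cells (instrument units) and
#' per-marker positivity thresholds. The preferred reference is the paired
#' residual normal B-cell population of the same sample (used automatically
#' by [grade_panel()] when it holds at least `min_residual` events); these
#' stored ranges are the fallback, e.g. for heavily infiltrated samples
#' with no residual B cells, and are configurable per laboratory.
#'
#' @param mfi Named numeric vector of reference MFIs.
#' @param boundaries Numeric `c(weak, strong)` MFI-ratio boundaries
#'   (defaults 0.5 and 2.0).
#' @param source Tag recording where the reference came from.
#' @param min_residual Minimum residual-B events to prefer the paired
#'   in-sample reference (default 50).
#' @return A `wm_reference`.
#' @export
reference_ranges <- function(mfi, boundaries = c(weak = 0.5, strong = 2.0),
                             source = "configured", min_residual = 50) {
  stopifnot(is.numeric(mfi), !is.null(names(mfi)))
  if (any(mfi[!is.na(mfi)] <= 0)) stop("reference MFIs must be positive")
  structure(list(mfi = mfi, boundaries = boundaries, source = source,
                 min_residual = min_residual,
                 pos_threshold = setNames(marker_info()$pos_threshold,
                                          marker_info()$marker)),
            class = "wm_reference")
}

#' Default healthy-control reference ranges
#'
#' Population-mean reference MFIs of normal mature B cells on the
#' package's nominal instrument scale (synthetic values, consistent with
#' the simulator's healthy-control event model; real laboratories should
#' calibrate and supply their own via [read_reference()]). Markers graded
#' on percent alone (CD13, CD5, CD23, CD43) are reference-free (`NA`).
#'
#' @return A `wm_reference`.
#' @export
default_reference <- function() {
  mfi_graded <- setdiff(PANEL_MARKERS, c(PERCENT_ONLY_MARKERS, "CD45"))
  mfi <- vapply(mfi_graded, normal_b_popmean, numeric(1))
  mfi[PERCENT_ONLY_MARKERS] <- NA_real_
  reference_ranges(mfi, source = "package default (synthetic healthy-control scale)")
}

#' Read or write reference ranges as YAML
#' @param path File path.
#' @return `read_reference` returns a `wm_reference`.
#' @export
read_reference <- function(path) {
  y <- yaml::read_yaml(path)
  reference_ranges(unlist(y$mfi), boundaries = unlist(y$boundaries),
                   source = y$source %||% path)
}

#' @rdname read_reference
#' @param reference A `wm_reference`.
#' @export
write_reference <- function(reference, path) {
  yaml::write_yaml(list(mfi = as.list(reference$mfi),
                        boundaries = as.list(reference$boundaries),
                        source = reference$source), path)
  invisible(path)
}

#' Grade a single marker
#'
#' Negative when `pct` is below the marker's positivity threshold (30%, 2%
#' for CD13). Otherwise the grade follows the MFI ratio (clonal MFI /
#' reference MFI): weak below the lower boundary (default 0.5), strong
#' above the upper (default 2.0), normal between. CD13 is graded on
#' percent alone (normal B cells do not express it, so there is no
#' meaningful reference MFI); any non-negative CD13 is reported as
#' `normal` with a missing ratio.
#'
#' @param pct Percent positive, 0-100.
#' @param clonal_mfi MFI of the clonal population (instrument scale).
#' @param reference A `wm_reference`.
#' @param marker Marker name.
#' @return A `wm_marker_grade`: list with `marker`, `grade` (one of
#'   `negative`, `weak`, `normal`, `strong`), `percent_positive`,
#'   `mfi_ratio`.
#' @export
grade_marker <- function(pct, clonal_mfi, reference = default_reference(),
                         marker) {
  thr <- if (marker %in% names(reference$pos_threshold))
    reference$pos_threshold[[marker]] else positivity_threshold(marker)
  if (is.na(pct)) stop("grading error: percent positive missing for ", marker)
  grade <- NULL; ratio <- NA_real_
  if (pct < thr) {
    grade <- "negative"
  } else if (marker %in% PERCENT_ONLY_MARKERS) {
    grade <- "normal"  # percent-only marker, reference-free
  } else {
    ref_mfi <- if (marker %in% names(reference$mfi))
      reference$mfi[[marker]] else NA_real_
    if (is.na(clonal_mfi) || is.na(ref_mfi))
      stop("grading error: reference or clonal MFI missing for non-negative marker ",
           marker)
    ratio <- clonal_mfi / ref_mfi
    grade <- if (ratio < reference$boundaries[["weak"]]) "weak"
             else if (ratio > reference$boundaries[["strong"]]) "strong"
             else "normal"
  }
  structure(list(marker = marker, grade = grade, percent_positive = pct,
                 mfi_ratio = ratio),
            class = "wm_marker_grade")
}

#' CD79b/CD22 MFI ratio
#'
#' A high ratio highlights WM B cells (strong CD79b with weak CD22);
#' typical magnitudes are around 8 for WM versus around 1.6 for MZL.
#'
#' @param mfi_cd79b,mfi_cd22 Positive MFIs.
#' @return `mfi_cd79b / mfi_cd22`.
#' @export
cd79b_cd22_ratio <- function(mfi_cd79b, mfi_cd22) {
  if (is.na(mfi_cd22) || mfi_cd22 <= 0)
    stop("CD79b/CD22 ratio undefined: non-positive CD22 MFI")
  if (is.na(mfi_cd79b) || mfi_cd79b <= 0)
    stop("CD79b/CD22 ratio undefined: non-positive CD79b MFI")
  mfi_cd79b / mfi_cd22
}

#' Construct a patient profile from known grades
#'
#' For users whose marker grades are already established (e.g. read off
#' quadrant plots) rather than derived from event data. Representative
#' percent-positive and MFI-ratio values consistent with each grade are
#' filled in unless given explicitly.
#'
#' @param grades Named character vector of grades (`negative`, `weak`,
#'   `normal`, `strong`), e.g. `c(CD19 = "weak", FMC7 = "negative", ...)`.
#' @param percents Optional named numeric vector overriding the
#'   representative percent-positive per marker (needed for CD13, whose
#'   criterion is the percent itself).
#' @param mfi_ratios Optional named numeric vector of MFI ratios.
#' @param compartment `"BM"` or `"PB"`.
#' @param clonal_fraction Clonal B cells as percent of lymphocytes
#'   (`NA` if unknown; required for the PB score's 10% criterion).
#' @param light_chain `"kappa"`, `"lambda"` or `"none"`.
#' @param patient_id,truth,cxcr4 Optional identifiers/labels.
#' @return A `wm_profile`.
#' @export
patient_profile <- function(grades, percents = NULL, mfi_ratios = NULL,
                            compartment = "BM", clonal_fraction = NA_real_,
                            light_chain = "kappa",
                            patient_id = NA_character_,
                            truth = NA_character_, cxcr4 = NA_character_) {
  stopifnot(all(grades %in% GRADE_LEVELS), !is.null(names(grades)))
  rep_ratio <- c(negative = NA_real_, weak = 0.3, normal = 1, strong = 4)
  gl <- list()
  for (mk in names(grades)) {
    g <- grades[[mk]]
    thr <- positivity_threshold(mk)
    pct <- if (!is.null(percents) && mk %in% names(percents)) percents[[mk]]
           else if (g == "negative") thr / 2 else 95
    ratio <- if (!is.null(mfi_ratios) && mk %in% names(mfi_ratios)) mfi_ratios[[mk]]
             else if (mk %in% PERCENT_ONLY_MARKERS) NA_real_
             else rep_ratio[[g]]
    gl[[mk]] <- structure(list(marker = mk, grade = g, percent_positive = pct,
                               mfi_ratio = ratio), class = "wm_marker_grade")
  }
  new_profile(patient_id = patient_id, compartment = compartment, grades = gl,
              clonal_fraction = clonal_fraction, light_chain = light_chain,
              truth = truth, cxcr4 = cxcr4)
}

new_profile <- function(patient_id, compartment, grades, clonal_fraction,
                        light_chain, truth = NA_character_,
                        cxcr4 = NA_character_, flags = character()) {
  structure(list(patient_id = patient_id,
                 compartment = toupper(compartment),
                 grades = grades,
                 clonal_fraction = clonal_fraction,
                 light_chain = light_chain,
                 truth = truth, cxcr4 = cxcr4, flags = flags),
            class = "wm_profile")
}

#' @export
print.wm_profile <- function(x, ...) {
  cat("wm_profile:", x$patient_id %||% "<unnamed>", "-", x$compartment,
      "sample, light chain", x$light_chain, "\n")
  if (!is.na(x$clonal_fraction))
    cat(sprintf("  clonal fraction of lymphocytes: %.1f%%\n", x$clonal_fraction))
  for (g in x$grades)
    cat(sprintf("  %-6s %-8s pct=%5.1f  mfi_ratio=%s\n", g$marker, g$grade,
                g$percent_positive,
                ifelse(is.na(g$mfi_ratio), "-", sprintf("%.2f", g$mfi_ratio))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Grade all panel markers of a gated sample
#'
#' Builds a `wm_profile` from a [summarize_events()] result: one grade per
#' scored marker (CD19, FMC7, CD22, CD79b, CD27, CD13) plus any other
#' panel marker present, the clonal fraction, compartment and light chain.
#' The reference MFI per marker is taken from the paired residual normal
#' B cells when that population holds at least `reference$min_residual`
#' events; otherwise from the supplied reference ranges. Markers absent
#' from the input are recorded as missing, not failed.
#'
#' @param summary A `wm_population_summary` with a clonal population.
#' @param reference Fallback `wm_reference` (default [default_reference()]).
#' @param compartment `"BM"` or `"PB"`.
#' @param patient_id Identifier carried into the profile.
#' @return A `wm_profile`.
#' @export
grade_panel <- function(summary, reference = default_reference(),
                        compartment = "BM", patient_id = NA_character_) {
  clon <- summary$populations$clonal_b
  if (is.null(clon) || clon$n_events == 0 || summary$light_chain == "none")
    stop("grading error: no clonal B-cell population to grade")
  resid <- summary$populations$residual_b
  use_resid <- !is.null(resid) && resid$n_events >= reference$min_residual
  ref <- reference
  if (use_resid) {
    rmfi <- resid$mfi[!is.na(resid$mfi) & resid$mfi > 0]
    rmfi <- rmfi[setdiff(names(rmfi), PERCENT_ONLY_MARKERS)]
    ref$mfi[names(rmfi)] <- rmfi
    ref$source <- "paired residual normal B cells"
  }
  grades <- list()
  markers <- union(SCORED_MARKERS, names(clon$pct)[!is.na(clon$pct)])
  markers <- setdiff(markers, c("CD45", "kappa", "lambda"))
  for (mk in markers) {
    if (!mk %in% names(clon$pct) || is.na(clon$pct[[mk]])) next  # missing marker
    grades[[mk]] <- grade_marker(clon$pct[[mk]], clon$mfi[[mk]], ref, mk)
  }
  flags <- summary$flags
  miss <- setdiff(SCORED_MARKERS, names(grades))
  if (length(miss)) flags <- c(flags, paste0("missing_", miss))
  new_profile(patient_id = patient_id, compartment = compartment,
              grades = grades,
              clonal_fraction = summary$clonal_fraction_of_lymphocytes,
              light_chain = summary$light_chain, flags = flags)
}
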