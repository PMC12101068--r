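# Pre-gated per-patient summary tables: one row per patient with
# percent-positive and MFI per marker, the clonal B-cell fraction and
# optional truth/mutation labels. This entry point serves labs that gate
# on their own software and only need grading + scoring.

#' Read a per-patient summary table
#'
#' Expected CSV layout: one row per patient with columns `patient_id`,
#' `compartment` (`BM` or `PB`), optional `clonal_fraction` (percent of
#' lymphocytes), optional `light_chain` (`kappa`/`lambda`/`none`), optional
#' `label` (`WM`/`MZL`) and `cxcr4` (`mutated`/`unmutated`), plus per-marker
#' columns `<marker>_pct` (percent positive, 0-100) and `<marker>_mfi`
#' (arbitrary instrument units). Marker names are matched
#' case-insensitively. Markers without columns are recorded as absent (not
#' as zero); files without light-chain information are flagged
#' clonality-unknown.
#'
#' @param path CSV file path.
#' @return List of `wm_summary_record` objects.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("cannot read summary table: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("summary table has no rows: ", path)
  cols <- names(df)
  lower <- tolower(cols)
  col <- function(nm) if (nm %in% lower) df[[cols[match(nm, lower)]]] else NULL
  pct_cols <- grep("_pct$", lower, value = FALSE)
  clonality_known <- "light_chain" %in% lower ||
    any(c("kappa_pct", "lambda_pct") %in% lower)
  records <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    markers <- list()
    for (j in pct_cols) {
      mk <- match_marker(sub("_pct$", "", lower[j]))
      if (is.na(mk)) next
      pct <- df[[j]][r]
      if (!is.na(pct) && (pct < 0 || pct > 100))
        stop("validation error in row ", r, ": ", cols[j], "=", pct,
             " outside [0,100]")
      mfi_col <- match(paste0(tolower(mk), "_mfi"), lower)
      mfi <- if (!is.na(mfi_col)) df[[mfi_col]][r] else NA_real_
      markers[[mk]] <- list(pct = pct, mfi = mfi)
    }
    cf <- col("clonal_fraction")
    cf <- if (is.null(cf)) NA_real_ else cf[r]
    if (!is.na(cf) && (cf < 0 || cf > 100))
      stop("validation error in row ", r, ": clonal_fraction=", cf,
           " outside [0,100]")
    lc <- col("light_chain"); lc <- if (is.null(lc)) NA_character_ else lc[r]
    records[[r]] <- structure(list(
      patient_id = (col("patient_id") %||% seq_len(nrow(df)))[r],
      compartment = toupper((col("compartment") %||% rep("BM", nrow(df)))[r]),
      markers = markers,
      clonal_fraction = cf,
      light_chain = lc,
      clonality_known = clonality_known || !is.na(lc) || !is.na(cf),
      label = (col("label") %||% rep(NA_character_, nrow(df)))[r],
      cxcr4 = (col("cxcr4") %||% rep(NA_character_, nrow(df)))[r]
    ), class = "wm_summary_record")
  }
  records
}

#' Build a graded patient profile from a summary record
#'
#' Grades every marker present in the record against reference MFIs (see
#' [grade_marker()]) and assembles a `wm_profile` ready for [bm_score()] /
#' [pb_score()].
#'
#' @param record A `wm_summary_record` from [read_summary_table()].
#' @param reference A `wm_reference`; defaults to [default_reference()].
#' @return A `wm_profile`.
#' @export
profile_from_summary <- function(record, reference = default_reference()) {
  grades <- list()
  for (mk in names(record$markers)) {
    entry <- record$markers[[mk]]
    grades[[mk]] <- grade_marker(entry$pct, entry$mfi, reference, mk)
  }
  new_profile(patient_id = record$patient_id,
              compartment = record$compartment,
              grades = grades,
              clonal_fraction = record$clonal_fraction,
              light_chain = if (is.na(record$light_chain)) "none" else record$light_chain,
              truth = record$label,
              cxcr4 = record$cxcr4,
              flags = if (record$clonality_known) character() else "clonality_unknown")
}
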