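# Marker vocabulary shared by all modules.

# Markers referenced by the scoring systems and the 3-tube panel.
PANEL_MARKERS <- c("CD19", "CD20", "CD22", "CD79b", "CD27", "CD13", "FMC7",
                   "CD38", "CD5", "CD23", "CD43", "CD45", "kappa", "lambda")

# Markers whose grade/percent feeds the 6- and 7-point scores.
SCORED_MARKERS <- c("CD19", "FMC7", "CD22", "CD79b", "CD27", "CD13")

GRADE_LEVELS <- c("negative", "weak", "normal", "strong")

# Markers graded on percent positive alone: normal B cells do not express
# them (CD13, CD5, CD43) or express them partially/variably (CD23, CD38),
# so a population-level MFI ratio against normal B is not meaningful; all
# of their diagnostic use here (prevalences, the CD38-CXCR4 association)
# is on percent positive.
PERCENT_ONLY_MARKERS <- c("CD13", "CD5", "CD23", "CD43", "CD38")

# Normal mature B-cell expression model shared by the grading reference
# and the simulator: per-marker positive-cell lognormal level (instrument
# units), percent positive, and the autofluorescence baseline.
NORMAL_B_LEVEL <- c(CD19 = 1200, CD20 = 1500, CD22 = 900, CD79b = 800,
                    FMC7 = 1000, CD27 = 900, CD38 = 800, CD5 = 700,
                    CD23 = 700, CD43 = 700, CD13 = 600, kappa = 800,
                    lambda = 800)
NORMAL_B_PCT <- c(CD19 = 98, CD20 = 98, CD22 = 95, CD79b = 97, FMC7 = 85,
                  CD27 = 40, CD38 = 50, CD5 = 0, CD23 = 15, CD43 = 0,
                  CD13 = 0.5, kappa = 60, lambda = 40)
BASELINE_MFI <- 25
BASELINE_SDLOG <- 0.6
POS_SDLOG <- 0.35

# Population-mean MFI of normal mature B cells per marker: the mean over
# the whole population (positives at their lognormal level, negatives at
# autofluorescence). This is the denominator scale for MFI ratios.
normal_b_popmean <- function(marker) {
  p <- NORMAL_B_PCT[[marker]] / 100
  k_pos <- exp(POS_SDLOG^2 / 2)
  base_mean <- BASELINE_MFI * exp(BASELINE_SDLOG^2 / 2)
  p * NORMAL_B_LEVEL[[marker]] * k_pos + (1 - p) * base_mean
}

#' Per-marker gating/grading metadata
#'
#' Positivity thresholds (percent of a population above the negativity
#' cutoff needed to call the marker expressed: 30 for every marker except
#' CD13, whose clinically validated threshold is 2) and the internal
#' negative reference population used to place the per-channel negativity
#' cutoff: T cells for B-lineage markers, residual normal B cells for
#' markers expressed by T cells (CD5, CD43) or myeloid cells (CD13).
#'
#' @return A data.frame with columns `marker`, `pos_threshold` (percent)
#'   and `neg_ref` (`"t_cells"` or `"residual_b"`).
#' @export
marker_info <- function() {
  data.frame(
    marker = PANEL_MARKERS,
    pos_threshold = ifelse(PANEL_MARKERS == "CD13", 2, 30),
    neg_ref = ifelse(PANEL_MARKERS %in% c("CD5", "CD43", "CD13"),
                     "residual_b", "t_cells"),
    stringsAsFactors = FALSE
  )
}

positivity_threshold <- function(marker) {
  if (marker == "CD13") 2 else 30
}

match_marker <- function(name) {
  # case-insensitive match of a channel/column name to a panel marker
  i <- match(tolower(name), tolower(PANEL_MARKERS))
  if (is.na(i)) NA_character_ else PANEL_MARKERS[i]
}
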