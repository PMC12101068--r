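# Synthetic cohort and event simulator for WM, MZL and healthy controls,
# including a CXCR4-mutated WM subgroup with its CD38-low phenotype.
#
# The defaults encode the study conditions the scores were derived under:
# kappa restriction in 79% of WM; CD5/CD23/CD43 positive in 9/18/22% of WM;
# CD13 expressed in two-thirds of WM; mean BM clonal infiltration 45%
# (range 2-92) of lymphocytes; median PB clonal fraction 7% (WM) vs 52%
# (MZL); WM B cells CD19/CD22-weak, CD79b-strong, FMC7/CD27 heterogeneous
# and often weak; MZL B cells with normal-to-strong FMC7/CD22/CD27 and
# CD38 lower than WM; CXCR4-mutated WM with low/absent CD38 and lower
# CD19/CD79b/FMC7/CD27. Quantities never published (grade-probability
# splits inside "heterogeneous", MFI-ratio dispersions, the MZL BM
# infiltration distribution, the mutated-subgroup prevalence) are modelling
# choices fixed once in this config and documented in the methods vignette.

#' Default simulation configuration
#'
#' @param seed Ignored here (draws are seeded at the simulate_* entry
#'   points); kept as a field so configs serialise the seed they were used
#'   with.
#' @return A `wm_sim_config` list; see source for the full parameter table.
#' @export
sim_config <- function(seed = NULL) {
  gp <- function(negative, weak, normal, strong) {
    v <- c(negative = negative, weak = weak, normal = normal, strong = strong)
    stopifnot(abs(sum(v) - 1) < 1e-9)
    v
  }
  groups <- list(
    WM = list(
      grade_probs = list(
        CD19 = gp(0, .70, .27, .03), CD20 = gp(0, .10, .70, .20),
        CD22 = gp(0, .70, .27, .03), CD79b = gp(0, .03, .22, .75),
        FMC7 = gp(.35, .35, .25, .05), CD27 = gp(.40, .35, .20, .05)),
      # percent-only markers: probability of positivity
      pos_prob = c(CD13 = 2 / 3, CD5 = 0.09, CD23 = 0.18, CD43 = 0.22,
                   CD38 = 0.65),
      kappa_prob = 0.79),
    MZL = list(
      grade_probs = list(
        CD19 = gp(0, .10, .75, .15), CD20 = gp(0, .05, .65, .30),
        CD22 = gp(0, .10, .60, .30), CD79b = gp(0, .10, .75, .15),
        FMC7 = gp(.05, .10, .45, .40), CD27 = gp(.10, .15, .55, .20)),
      pos_prob = c(CD13 = 0.08, CD5 = 0.22, CD23 = 0.30, CD43 = 0.10,
                   CD38 = 0.40),
      kappa_prob = 5 / 6)
  )
  # CXCR4-mutated WM: CD38 low/negative plus lower CD19/CD79b/FMC7/CD27
  groups$WM_CXCR4mut <- groups$WM
  groups$WM_CXCR4mut$pos_prob[["CD38"]] <- 0.15
  groups$WM_CXCR4mut$grade_probs$CD19 <- gp(0, .85, .14, .01)
  groups$WM_CXCR4mut$grade_probs$CD79b <- gp(0, .08, .35, .57)
  groups$WM_CXCR4mut$grade_probs$FMC7 <- gp(.50, .30, .18, .02)
  groups$WM_CXCR4mut$grade_probs$CD27 <- gp(.55, .30, .13, .02)
  structure(list(
    groups = groups,
    cxcr4_prevalence = 0.35,
    # clonal fraction of lymphocytes, percent
    clonal_fraction = list(
      WM_BM = list(dist = "beta_scaled", lo = 2, hi = 92, shape1 = 2,
                   shape2 = 2 * (1 - 43 / 90) / (43 / 90)),  # mean 45
      WM_PB = list(dist = "lognormal", median = 7, sdlog = 0.8),
      MZL_BM = list(dist = "lognormal", median = 30, sdlog = 0.8),
      MZL_PB = list(dist = "lognormal", median = 52, sdlog = 0.8)),
    # MFI-ratio bands per grade (clonal population MFI / normal-B
    # population MFI), sampled log-uniformly with a margin inside the
    # 0.5 / 2.0 grading boundaries
    ratio_bands = list(weak = c(0.18, 0.45), normal = c(0.60, 1.80),
                       strong = c(2.30, 7.00)),
    light_chain_ratio = c(3, 6),   # strong restricted-chain band
    # event-level model; the normal-B constants are shared with the
    # grading reference so measured ratios recover planted ratios
    events = list(
      positive_level = NORMAL_B_LEVEL,
      baseline_mfi = BASELINE_MFI, baseline_sdlog = BASELINE_SDLOG,
      pos_sdlog = POS_SDLOG,
      lymph_frac = 0.45, residual_b_frac = 8,  # % of lymphocytes
      cd13_pos_level = 2.5,                    # x positive level
      cd45 = list(lymph = c(3000, 0.15), other = c(1000, 0.25)),
      ssc = list(lymph = c(250, 0.30), other = c(2800, 0.30)),
      fsc = list(lymph = c(1500, 0.20), other = c(3000, 0.25)),
      residual_profile = list(  # normal mature B cells
        pct = NORMAL_B_PCT, kappa_frac = 0.6),
      t_cell_profile = list(pct = c(CD5 = 95, CD43 = 90),
                            ratio = c(CD5 = 2.0, CD43 = 1.5))),
    seed = seed
  ), class = "wm_sim_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "wm_sim_config"))
  for (g in names(config$groups)) {
    gr <- config$groups[[g]]
    for (mk in names(gr$grade_probs)) {
      p <- gr$grade_probs[[mk]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("invalid config: grade probabilities for ", g, "/", mk)
    }
    if (any(gr$pos_prob < 0) || any(gr$pos_prob > 1) ||
        gr$kappa_prob < 0 || gr$kappa_prob > 1)
      stop("invalid config: prevalence outside [0,1] in group ", g)
  }
  if (config$cxcr4_prevalence < 0 || config$cxcr4_prevalence > 1)
    stop("invalid config: cxcr4_prevalence outside [0,1]")
  invisible(TRUE)
}

runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

draw_clonal_fraction <- function(group, compartment, config) {
  key <- paste0(if (startsWith(group, "WM")) "WM" else "MZL", "_", compartment)
  d <- config$clonal_fraction[[key]]
  if (d$dist == "beta_scaled") {
    d$lo + (d$hi - d$lo) * rbeta(1, d$shape1, d$shape2)
  } else {
    min(max(exp(rnorm(1, log(d$median), d$sdlog)), 0.2), 95)
  }
}

draw_pct <- function(marker, grade, thr) {
  if (grade == "negative") {
    if (marker == "CD13") runif(1, 0, 0.6) else runif(1, 2, 0.6 * thr)
  } else if (marker == "CD13") {
    runif(1, 4, 70)
  } else if (marker %in% c("CD19", "CD20", "CD22", "CD79b")) {
    # pan-B markers: consistently expressed on the whole clone
    runif(1, 98, 99.8)
  } else if (marker %in% c("CD5", "CD23", "CD43")) {
    runif(1, 45, 90)
  } else {
    runif(1, 45, 97)  # FMC7 / CD27 / CD38: heterogeneous positives
  }
}

#' Simulate one graded patient profile
#'
#' Draws per-marker grades, percent-positive values and MFI ratios from
#' the group's distributions; `WM_CXCR4mut` applies the mutated-subgroup
#' shifts (CD38 low/negative, lower CD19/CD79b/FMC7/CD27); `control` has
#' no clone and no gradeable profile.
#'
#' @param group One of `"WM"`, `"WM_CXCR4mut"`, `"MZL"`, `"control"`.
#' @param compartment `"BM"` or `"PB"`.
#' @param config A `wm_sim_config`.
#' @param seed Optional integer seed (set once; omit when drawing many
#'   profiles inside an outer seeded context).
#' @return A `wm_profile` with `truth` and `cxcr4` labels.
#' @export
simulate_profile <- function(group = c("WM", "WM_CXCR4mut", "MZL", "control"),
                             compartment = c("BM", "PB"),
                             config = sim_config(), seed = NULL) {
  group <- match.arg(group); compartment <- match.arg(compartment)
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (group == "control") {
    return(new_profile(patient_id = "control", compartment = compartment,
                       grades = list(), clonal_fraction = 0,
                       light_chain = "none", truth = "control",
                       cxcr4 = NA_character_))
  }
  gr <- config$groups[[group]]
  info <- marker_info()
  grades <- list()
  for (mk in names(gr$grade_probs)) {
    g <- sample(GRADE_LEVELS, 1, prob = gr$grade_probs[[mk]])
    thr <- info$pos_threshold[info$marker == mk]
    pct <- draw_pct(mk, g, thr)
    ratio <- if (g == "negative") NA_real_
             else runif_log(1, config$ratio_bands[[g]][1], config$ratio_bands[[g]][2])
    grades[[mk]] <- structure(list(marker = mk, grade = g,
                                   percent_positive = pct, mfi_ratio = ratio),
                              class = "wm_marker_grade")
  }
  for (mk in names(gr$pos_prob)) {  # percent-only markers
    g <- if (runif(1) < gr$pos_prob[[mk]]) "normal" else "negative"
    thr <- info$pos_threshold[info$marker == mk]
    grades[[mk]] <- structure(list(marker = mk, grade = g,
                                   percent_positive = draw_pct(mk, g, thr),
                                   mfi_ratio = NA_real_),
                              class = "wm_marker_grade")
  }
  chain <- if (runif(1) < gr$kappa_prob) "kappa" else "lambda"
  lc_ratio <- runif_log(1, config$light_chain_ratio[1], config$light_chain_ratio[2])
  prof <- new_profile(patient_id = group, compartment = compartment,
                      grades = grades,
                      clonal_fraction = draw_clonal_fraction(group, compartment, config),
                      light_chain = chain,
                      truth = if (startsWith(group, "WM")) "WM" else "MZL",
                      cxcr4 = if (group == "WM_CXCR4mut") "mutated"
                              else if (group == "WM") "unmutated" else NA_character_)
  prof$light_chain_ratio <- lc_ratio
  prof
}

# intensity draw: positive fraction p at level (ratio x reference), rest at
# autofluorescence baseline
draw_channel <- function(n, p, level, ev) {
  pos <- runif(n) < p
  x <- rlnorm(n, log(ev$baseline_mfi), ev$baseline_sdlog)
  if (any(pos)) x[pos] <- rlnorm(sum(pos), log(level), ev$pos_sdlog)
  x
}

draw_scatter <- function(n, par) rlnorm(n, log(par[1]), par[2])

#' Simulate event-level data realising a profile
#'
#' Generates a mixture of clonal B, residual normal B, T-cell and
#' non-lymphocyte events whose per-channel lognormal components realise the
#' profile's percent-positive values and MFI ratios. All 14 panel markers
#' plus FSC/SSC are emitted as one table (a virtual single-tube
#' acquisition); use `tubes = TRUE` for three per-tube tables matching
#' [default_panel()] (independent aliquots of the same sample). The
#' ground-truth population of every event is stored in
#' `metadata$population`.
#'
#' @param profile A `wm_profile` (e.g. from [simulate_profile()]).
#' @param n_events Total events, at least 100.
#' @param config A `wm_sim_config`.
#' @param seed Optional integer seed.
#' @param tubes If `TRUE`, return a named list of three per-tube
#'   `wm_events`.
#' @return A `wm_events`, or a list of them when `tubes = TRUE`.
#' @export
simulate_events <- function(profile, n_events, config = sim_config(),
                            seed = NULL, tubes = FALSE) {
  if (n_events < 100) stop("n_events must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(tubes)) {
    pan <- default_panel()
    out <- lapply(names(pan$tubes), function(nm) {
      tab <- simulate_events(profile, n_events, config, seed = NULL, tubes = FALSE)
      keep <- c("FSC", "SSC", pan$tubes[[nm]]$markers)
      tab$values <- tab$values[, intersect(keep, colnames(tab$values)), drop = FALSE]
      tab$tube_id <- nm
      tab
    })
    names(out) <- names(pan$tubes)
    return(out)
  }
  ev <- config$events
  cf <- profile$clonal_fraction
  if (is.na(cf) || cf < 0 || cf > 100) stop("infeasible profile: clonal fraction ", cf)
  for (g in profile$grades)
    if (!is.na(g$percent_positive) &&
        (g$percent_positive < 0 || g$percent_positive > 100))
      stop("infeasible profile: ", g$marker, " percent ", g$percent_positive)
  resid_frac <- min(ev$residual_b_frac, max(95 - cf, 1))
  t_frac <- max(100 - cf - resid_frac, 2)
  lymph_split <- c(clonal_b = cf, residual_b = resid_frac, t_cells = t_frac)
  lymph_split <- lymph_split / sum(lymph_split)
  fracs <- c(ev$lymph_frac * lymph_split, other = 1 - ev$lymph_frac)
  counts <- as.vector(rmultinom(1, n_events, fracs))
  names(counts) <- names(fracs)
  ref <- ev$positive_level
  k_pos <- exp(ev$pos_sdlog^2 / 2)
  base_mean <- ev$baseline_mfi * exp(ev$baseline_sdlog^2 / 2)
  # Positive-cell level for a clonal marker: chosen so the clonal
  # population's mean MFI realises the planted ratio times the normal-B
  # population mean (MFI ratios are defined on whole-population means).
  grade_level <- function(mk) {
    g <- profile$grades[[mk]]
    if (is.null(g)) return(c(p = 0, level = ev$baseline_mfi))
    p <- g$percent_positive / 100
    if (mk %in% PERCENT_ONLY_MARKERS) {
      lev <- if (mk == "CD13") ev$cd13_pos_level * ref[[mk]] else ref[[mk]]
      return(c(p = p, level = lev))
    }
    ratio <- g$mfi_ratio
    if (is.na(ratio)) ratio <- 1
    target <- ratio * normal_b_popmean(mk)
    lev <- (target - (1 - p) * base_mean) / (p * k_pos)
    c(p = p, level = max(lev, 1.2 * ev$baseline_mfi))
  }
  rp <- ev$residual_profile
  blocks <- list()
  for (popn in names(counts)) {
    n <- counts[[popn]]
    if (n == 0) { blocks[[popn]] <- NULL; next }
    m <- matrix(0, n, length(PANEL_MARKERS) + 2,
                dimnames = list(NULL, c("FSC", "SSC", PANEL_MARKERS)))
    is_lymph <- popn != "other"
    m[, "FSC"] <- draw_scatter(n, if (is_lymph) ev$fsc$lymph else ev$fsc$other)
    m[, "SSC"] <- draw_scatter(n, if (is_lymph) ev$ssc$lymph else ev$ssc$other)
    m[, "CD45"] <- draw_scatter(n, if (is_lymph) ev$cd45$lymph else ev$cd45$other)
    for (mk in setdiff(PANEL_MARKERS, "CD45")) {
      par <- switch(popn,
        clonal_b = {
          if (mk %in% c("kappa", "lambda")) {
            restricted <- identical(profile$light_chain, mk)
            lcr <- profile$light_chain_ratio %||% 4
            c(p = if (restricted) 0.995 else 0,
              level = if (restricted) lcr * ref[[mk]] else ev$baseline_mfi)
          } else grade_level(mk)
        },
        residual_b = {
          if (mk == "kappa") c(p = rp$kappa_frac, level = ref[[mk]])
          else if (mk == "lambda") c(p = 1 - rp$kappa_frac, level = ref[[mk]])
          else c(p = (if (mk %in% names(rp$pct)) rp$pct[[mk]] else 0) / 100,
                 level = ref[[mk]])
        },
        t_cells = {
          tp <- ev$t_cell_profile
          if (mk %in% names(tp$pct))
            c(p = tp$pct[[mk]] / 100, level = tp$ratio[[mk]] * ref[[mk]])
          else c(p = 0, level = ev$baseline_mfi)
        },
        other = {
          if (mk == "CD13") c(p = 0.9, level = 2 * ref[[mk]])
          else c(p = 0, level = ev$baseline_mfi)
        })
      m[, mk] <- draw_channel(n, par[["p"]], par[["level"]], ev)
    }
    blocks[[popn]] <- m
  }
  values <- do.call(rbind, blocks)
  pop_labels <- rep(names(counts), counts[names(counts)])
  event_table(values, tube_id = "sim",
              metadata = list(population = pop_labels,
                              truth_profile_id = profile$patient_id,
                              total_leukocytes = n_events))
}

#' Simulate a labelled WM/MZL cohort
#'
#' Independent profile draws with exact group sizes; each WM patient is
#' CXCR4-mutated with probability `config$cxcr4_prevalence`.
#'
#' @param n_wm,n_mzl Group sizes (non-negative).
#' @param compartment `"BM"` or `"PB"`.
#' @param config A `wm_sim_config`.
#' @param seed Optional integer seed.
#' @return List of `wm_profile` with `truth` labels; WM first, then MZL.
#' @export
simulate_cohort <- function(n_wm, n_mzl, compartment = c("BM", "PB"),
                            config = sim_config(), seed = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(n_wm >= 0, n_mzl >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_wm + n_mzl)
  i <- 0
  for (k in seq_len(n_wm)) {
    grp <- if (runif(1) < config$cxcr4_prevalence) "WM_CXCR4mut" else "WM"
    i <- i + 1
    out[[i]] <- simulate_profile(grp, compartment, config)
    out[[i]]$patient_id <- sprintf("WM%03d", k)
  }
  for (k in seq_len(n_mzl)) {
    i <- i + 1
    out[[i]] <- simulate_profile("MZL", compartment, config)
    out[[i]]$patient_id <- sprintf("MZL%03d", k)
  }
  out
}

#' Write a simulated cohort as a summary CSV
#'
#' One row per patient in the layout read back by [read_summary_table()]
#' (percent and MFI columns on the reference scale, clonal fraction, light
#' chain, truth label and CXCR4 status).
#'
#' @param cohort List of `wm_profile`.
#' @param path Output CSV path.
#' @param reference A `wm_reference` supplying the scale for MFI columns.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(cohort, path, reference = default_reference()) {
  rows <- lapply(cohort, function(p) {
    row <- list(patient_id = p$patient_id, compartment = p$compartment,
                clonal_fraction = p$clonal_fraction,
                light_chain = p$light_chain, label = p$truth, cxcr4 = p$cxcr4)
    for (mk in names(p$grades)) {
      g <- p$grades[[mk]]
      row[[paste0(mk, "_pct")]] <- g$percent_positive
      ref_mfi <- if (mk %in% names(reference$mfi)) reference$mfi[[mk]] else NA_real_
      row[[paste0(mk, "_mfi")]] <-
        if (is.na(g$mfi_ratio)) NA_real_ else g$mfi_ratio * ref_mfi
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
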