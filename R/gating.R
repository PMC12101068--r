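# Gating: lymphocytes by CD45/SSC, B cells by CD19, clonal vs residual B
# cells by surface light-chain restriction; per-population percent-positive
# and MFI.
#
# All partitions are deterministic: 2-means runs from fixed quantile-based
# starting centers, so gating never consumes random numbers.

# Deterministic 2-means on a numeric matrix (columns standardised).
# Returns cluster assignment (1/2), centers on the standardised scale and
# the between-SS fraction used to decide whether two modes are really
# present.
two_means <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  q <- apply(z, 2, stats::quantile, probs = c(0.1, 0.9), names = FALSE)
  centers <- rbind(q[1, ], q[2, ])
  if (any(!is.finite(centers)) || all(centers[1, ] == centers[2, ]))
    return(list(cluster = rep(1L, nrow(z)), frac_between = 0, centers = centers))
  km <- suppressWarnings(stats::kmeans(z, centers = centers, iter.max = 50))
  list(cluster = km$cluster, frac_between = km$betweenss / max(km$totss, 1e-12),
       centers = km$centers)
}

log1i <- function(x) log1p(pmax(x, 0))

#' Gate lymphocytes on CD45 versus side scatter
#'
#' Partitions events into two clusters on (log CD45, log SSC) and keeps the
#' CD45-bright / SSC-low cluster. When the two clusters do not explain a
#' substantial share of the variance (below `min_separation`), the input is
#' treated as a single (lymphocyte) population and returned whole, so a
#' pure-lymphocyte sample is not split in half. A user-supplied rectangular
#' gate overrides the automatic partition.
#'
#' @param events A `wm_events` with `CD45` and `SSC` channels.
#' @param min_separation Minimum between-cluster sum-of-squares fraction
#'   (0-1) required to accept a two-population split; default 0.45.
#' @param rect Optional list `list(cd45 = c(lo, hi), ssc = c(lo, hi))`
#'   rectangular gate on raw intensities.
#' @return A `wm_events` subset; the gate parameters are recorded in its
#'   provenance.
#' @export
gate_lymphocytes <- function(events, min_separation = 0.45, rect = NULL) {
  for (ch in c("CD45", "SSC"))
    if (!has_channel(events, ch))
      stop("gating error: channel '", ch, "' required for the lymphocyte gate")
  cd45 <- channel_values(events, "CD45")
  ssc <- channel_values(events, "SSC")
  if (all(!is.finite(cd45)) || all(cd45 == 0))
    stop("gating error: CD45 channel is empty")
  if (!is.null(rect)) {
    keep <- cd45 >= rect$cd45[1] & cd45 <= rect$cd45[2] &
      ssc >= rect$ssc[1] & ssc <= rect$ssc[2]
    return(subset_events(events, keep,
                         gate = list(type = "lymphocytes", method = "rect", rect = rect)))
  }
  tm <- two_means(cbind(cd45 = log1i(cd45), ssc = log1i(ssc)))
  if (tm$frac_between < min_separation) {
    return(subset_events(events, rep(TRUE, n_events(events)),
                         gate = list(type = "lymphocytes", method = "single-mode",
                                     frac_between = tm$frac_between)))
  }
  # lymphocytes: high CD45, low SSC (standardised center score)
  score <- tm$centers[, "cd45"] - tm$centers[, "ssc"]
  keep <- tm$cluster == which.max(score)
  subset_events(events, keep,
                gate = list(type = "lymphocytes", method = "2-means",
                            frac_between = tm$frac_between,
                            retained = mean(keep)))
}

# Negativity cutoff for one marker: the 99th-percentile boundary of the
# channel on an internal negative reference population, estimated robustly
# (median x exp(z_0.99 * MAD of logs)) so that a small admixture of bright
# pathological events in the reference cluster cannot inflate the cutoff.
# Falls back to `default_cutoff` when the reference population is too
# small.
neg_cutoff <- function(ref_values, default_cutoff = 100, min_n = 200) {
  if (length(ref_values) < min_n) return(default_cutoff)
  lx <- log(pmax(ref_values, 1e-6))
  exp(stats::median(lx) + stats::qnorm(0.99) * stats::mad(lx))
}

#' Split B cells into clonal and residual populations by light-chain restriction
#'
#' B cells are the CD19-positive lymphocyte cluster. Among single
#' light-chain-positive B cells, a deterministic two-means split of the
#' expressed-chain log-intensity separates a bright (clonal, strongly
#' light-chain-expressing) mode from residual polytypic B cells. A
#' population is called clonal when the kappa:lambda event ratio within the
#' candidate cluster exceeds `ratio` : 1 (or the reciprocal); with no
#' bright/dim structure the ratio rule is applied to all single-positive
#' B cells. Fewer than `min_b` B-cell events yields `light_chain = "none"`
#' with a low-count flag.
#'
#' @param lymphs A `wm_events` of gated lymphocytes with `CD19`, `kappa`
#'   and `lambda` channels.
#' @param cutoffs Optional named numeric vector of negativity cutoffs for
#'   `CD19`, `kappa`, `lambda`; otherwise placed at the 99th percentile of
#'   the CD19-negative (T-cell) lymphocytes.
#' @param ratio Clonality bound on the kappa:lambda event ratio (default 4,
#'   the conventional clinical bound).
#' @param min_b Minimum B-cell events for a clonality call (default 50).
#' @return List with `clonal`, `residual`, `b_cells`, `t_cells`
#'   (`wm_events`), `light_chain` (`"kappa"`, `"lambda"` or `"none"`),
#'   `clonal_fraction_of_lymphocytes` (percent) and `flags`.
#' @export
partition_b_cells <- function(lymphs, cutoffs = NULL, ratio = 4, min_b = 50) {
  for (ch in c("CD19", "kappa", "lambda"))
    if (!has_channel(lymphs, ch))
      stop("gating error: channel '", ch, "' required for B-cell clonality")
  flags <- character()
  cd19 <- channel_values(lymphs, "CD19")
  lcd19 <- log1i(cd19)
  tm <- two_means(cbind(cd19 = lcd19))
  sep_raw <- abs(diff(tm$centers[, 1])) * stats::sd(lcd19)
  if (tm$frac_between >= 0.3 && is.finite(sep_raw) && sep_raw > log(4)) {
    hi <- which.max(tm$centers[, 1])
    is_b <- tm$cluster == hi
  } else {
    is_b <- rep(TRUE, length(cd19))  # no CD19-negative mode: all B
    flags <- c(flags, "no_t_cell_mode")
  }
  b <- subset_events(lymphs, is_b, gate = list(type = "b_cells", method = "CD19 2-means"))
  tc <- subset_events(lymphs, !is_b, gate = list(type = "t_cells"))
  kcut <- if (!is.null(cutoffs) && "kappa" %in% names(cutoffs)) cutoffs[["kappa"]]
          else neg_cutoff(if (n_events(tc) > 0) channel_values(tc, "kappa") else numeric())
  lcut <- if (!is.null(cutoffs) && "lambda" %in% names(cutoffs)) cutoffs[["lambda"]]
          else neg_cutoff(if (n_events(tc) > 0) channel_values(tc, "lambda") else numeric())
  none <- function(extra_flags = character()) {
    list(clonal = NULL, residual = b, b_cells = b, t_cells = tc,
         light_chain = "none", clonal_fraction_of_lymphocytes = 0,
         flags = c(flags, extra_flags))
  }
  if (n_events(b) < min_b || sum(is_b) == 0) {
    out <- none("low_b_count")
    return(out)
  }
  kv <- channel_values(b, "kappa"); lv <- channel_values(b, "lambda")
  kpos <- kv > kcut; lpos <- lv > lcut
  # single-positive: expressed chain above its cutoff, the other chain not
  # clearly positive (2x cutoff) -- the negativity boundary sits at the
  # 99th percentile of the negative reference, so demanding only > cutoff
  # on the other chain would spuriously discard ~1% of genuine
  # single-positive cells on baseline noise
  konly <- kpos & lv <= 2 * lcut; lonly <- lpos & kv <= 2 * kcut
  single <- konly | lonly
  if (sum(single) < min_b / 2) return(none("few_light_chain_positive"))
  # Bright/dim structure of the expressed chain across single-positive
  # cells: a 1-D two-component Gaussian mixture on the log intensity
  # (clonal cells express their restricted chain strongly; residual
  # polytypic cells sit at the normal level). Model-based clustering is
  # used because the clone and residual proportions are arbitrary.
  expressed <- log(pmax(ifelse(konly, kv, lv)[single], 1))
  # equal-variance components: clonal and residual log-intensity spreads
  # are comparable, and an unequal-variance fit lets the dim component
  # swallow the clone's tail, biasing the mixture weights
  fit <- suppressWarnings(Mclust(expressed, G = 1:2, modelNames = "E",
                                 verbose = FALSE))
  clone_idx <- NULL; chain <- "none"
  if (!is.null(fit) && fit$G == 2 &&
      abs(diff(fit$parameters$mean)) > log(2)) {
    comp_bright <- which.max(fit$parameters$mean)
    bright <- rep(FALSE, n_events(b))
    bright[single] <- fit$classification == comp_bright
    nkb <- sum(konly & bright); nlb <- sum(lonly & bright)
    nkd <- sum(konly & !bright); nld <- sum(lonly & !bright)
    # MAP classification strands the clone's dim tail in the residual
    # population; the mixture weight estimates the clone size without that
    # bias, so take that many brightest events of the restricted chain.
    n_bright_est <- round(fit$parameters$pro[comp_bright] * sum(single))
    take_brightest <- function(sel, v) {
      n_take <- min(sum(sel), max(n_bright_est, 1L))
      idx <- which(sel)
      sel_out <- rep(FALSE, length(sel))
      sel_out[idx[order(v[idx], decreasing = TRUE)][seq_len(n_take)]] <- TRUE
      sel_out
    }
    if (nkb > ratio * nlb && nkb > 0) {
      chain <- "kappa"
      clone_idx <- if (nkd > ratio * max(nld, 0.5)) konly  # dim tail clonal too
                   else take_brightest(konly, kv)
    } else if (nlb > ratio * nkb && nlb > 0) {
      chain <- "lambda"
      clone_idx <- if (nld > ratio * max(nkd, 0.5)) lonly
                   else take_brightest(lonly, lv)
    }
  }
  if (is.null(clone_idx)) {
    nk <- sum(konly); nl <- sum(lonly)
    if (nk > ratio * nl && nk > 0) { chain <- "kappa"; clone_idx <- konly }
    else if (nl > ratio * nk && nl > 0) { chain <- "lambda"; clone_idx <- lonly }
  }
  if (is.null(clone_idx) || sum(clone_idx) == 0) return(none())
  if (sum(clone_idx) < min_b) flags <- c(flags, "low_clonal_count")
  clonal <- subset_events(b, clone_idx,
                          gate = list(type = "clonal_b", light_chain = chain,
                                      kappa_cutoff = kcut, lambda_cutoff = lcut))
  residual <- subset_events(b, !clone_idx, gate = list(type = "residual_b"))
  list(clonal = clonal, residual = residual, b_cells = b, t_cells = tc,
       light_chain = chain,
       clonal_fraction_of_lymphocytes = 100 * sum(clone_idx) / n_events(lymphs),
       flags = flags)
}

#' Percent of a population above a cutoff
#'
#' `100 * #(intensity > cutoff) / n_events`, computed on the entire
#' population (for scoring, the entire pathological B-cell population).
#'
#' @param pop A `wm_events`.
#' @param marker Marker/channel name.
#' @param cutoff Negativity boundary on the raw intensity scale.
#' @return Percent in \[0, 100\].
#' @export
percent_positive <- function(pop, marker, cutoff) {
  if (n_events(pop) == 0) stop("undefined percent: empty population")
  x <- channel_values(pop, marker)
  100 * sum(x > cutoff) / length(x)
}

#' Mean fluorescence intensity of a population
#'
#' Arithmetic mean of the raw instrument-scale intensities of every event
#' in the population.
#'
#' @param pop A `wm_events`.
#' @param marker Marker/channel name.
#' @return Mean intensity.
#' @export
mfi <- function(pop, marker) {
  if (n_events(pop) == 0) stop("MFI undefined: empty population")
  mean(channel_values(pop, marker))
}

pop_summary_row <- function(pop, markers, cutoffs) {
  if (is.null(pop) || n_events(pop) == 0)
    return(list(n_events = 0L, pct = setNames(rep(NA_real_, length(markers)), markers),
                mfi = setNames(rep(NA_real_, length(markers)), markers)))
  present <- markers[markers %in% colnames(pop$values)]
  pct <- setNames(rep(NA_real_, length(markers)), markers)
  mf <- pct
  for (mk in present) {
    pct[mk] <- percent_positive(pop, mk, cutoffs[[mk]])
    mf[mk] <- mfi(pop, mk)
  }
  list(n_events = n_events(pop), pct = pct, mfi = mf)
}

#' Summarise gated populations of a sample
#'
#' Runs the lymphocyte gate, the B-cell/clonality partition and per-marker
#' percent-positive and MFI for the lymphocyte, B-cell, clonal-B,
#' residual-B and T-cell populations. Accepts a single event table with all
#' channels, or a list of per-tube tables (one per panel tube), in which
#' case marker statistics are merged across tubes by population identity
#' and the clonal fraction is taken from a tube carrying the light chains.
#' In tubes without light-chain channels, clonal-B statistics are
#' approximated on the whole B-cell population of that tube (acceptable
#' when the clone dominates the B compartment, and flagged).
#'
#' Negativity cutoffs per marker are placed at the 99th percentile of the
#' marker's intensity on an internal negative population: T cells for
#' B-lineage markers, residual B cells for CD5/CD43/CD13 (see
#' [marker_info()]); a configured default is used when the reference
#' population is too small.
#'
#' @param events A `wm_events` or list of them (one per tube).
#' @param panel A `wm_panel`; defaults to [default_panel()].
#' @param cutoffs Optional named numeric vector of per-marker negativity
#'   cutoff overrides.
#' @param default_cutoff Fallback cutoff when a negative reference
#'   population is unavailable (default 100, instrument units).
#' @return A `wm_population_summary`: per-population `n_events`, `pct` and
#'   `mfi` vectors, plus `light_chain`, `clonal_fraction_of_lymphocytes`,
#'   the cutoffs used and gating flags.
#' @export
summarize_events <- function(events, panel = default_panel(), cutoffs = NULL,
                             default_cutoff = 100) {
  tabs <- if (inherits(events, "wm_events")) list(events) else events
  stopifnot(length(tabs) >= 1)
  pops <- list()
  light_chain <- "none"; clonal_frac <- NA_real_; flags <- character()
  used_cut <- list()
  info <- marker_info()
  for (tab in tabs) {
    ly <- gate_lymphocytes(tab)
    has_lc <- has_channel(ly, "kappa") && has_channel(ly, "lambda")
    if (has_lc) {
      part <- partition_b_cells(ly, cutoffs = cutoffs)
      if (part$light_chain != "none") {
        light_chain <- part$light_chain
        clonal_frac <- part$clonal_fraction_of_lymphocytes
      } else if (is.na(clonal_frac)) clonal_frac <- 0
      flags <- union(flags, part$flags)
    } else {
      # no light chains in this tube: split off T cells by CD19 only and
      # treat all B cells as the pathological population
      cd19 <- channel_values(ly, "CD19")
      tm <- two_means(cbind(log1i(cd19)))
      is_b <- if (tm$frac_between >= 0.45) tm$cluster == which.max(tm$centers[, 1])
              else rep(TRUE, length(cd19))
      part <- list(clonal = subset_events(ly, is_b),
                   residual = NULL,
                   b_cells = subset_events(ly, is_b),
                   t_cells = subset_events(ly, !is_b))
      flags <- union(flags, "clonal_approximated_by_b_cells")
    }
    markers <- intersect(colnames(tab$values), PANEL_MARKERS)
    markers <- setdiff(markers, "CD45")
    tube_cut <- setNames(rep(default_cutoff, length(markers)), markers)
    for (mk in markers) {
      if (!is.null(cutoffs) && mk %in% names(cutoffs)) {
        tube_cut[mk] <- cutoffs[[mk]]
        next
      }
      ref_pop <- if (info$neg_ref[info$marker == mk] == "residual_b")
        part$residual else part$t_cells
      rv <- if (!is.null(ref_pop) && n_events(ref_pop) > 0)
        channel_values(ref_pop, mk) else numeric()
      tube_cut[mk] <- neg_cutoff(rv, default_cutoff = default_cutoff)
    }
    used_cut[markers] <- tube_cut[markers]
    tube_pops <- list(lymphocytes = ly, b_cells = part$b_cells,
                      clonal_b = part$clonal, residual_b = part$residual,
                      t_cells = part$t_cells)
    for (pn in names(tube_pops)) {
      row <- pop_summary_row(tube_pops[[pn]], markers, as.list(tube_cut))
      if (is.null(pops[[pn]])) {
        pops[[pn]] <- row
      } else {
        # merge across tubes: keep first tube's stats for already-seen
        # markers (their primary tube), append new ones
        new <- setdiff(markers, names(pops[[pn]]$pct))
        pops[[pn]]$pct <- c(pops[[pn]]$pct, row$pct[new])
        pops[[pn]]$mfi <- c(pops[[pn]]$mfi, row$mfi[new])
        pops[[pn]]$n_events <- max(pops[[pn]]$n_events, row$n_events)
      }
    }
  }
  structure(list(populations = pops,
                 light_chain = light_chain,
                 clonal_fraction_of_lymphocytes = clonal_frac,
                 cutoffs = unlist(used_cut),
                 flags = flags),
            class = "wm_population_summary")
}

#' @export
print.wm_population_summary <- function(x, ...) {
  cat("wm_population_summary\n")
  for (pn in names(x$populations))
    cat(sprintf("  %-12s %d events\n", pn, x$populations[[pn]]$n_events))
  cat("  light chain:", x$light_chain,
      sprintf("| clonal fraction of lymphocytes: %.1f%%\n",
              x$clonal_fraction_of_lymphocytes))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
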