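# Event-level data: one row per cell, one column per channel.

#' Construct an event table
#'
#' @param values Numeric matrix, one row per event, one column per channel;
#'   column names are channel names (unique).
#' @param tube_id Tube identifier.
#' @param panel Optional `wm_panel` used to resolve channel names to marker
#'   names via its `channel_map`; channels that resolve are renamed to the
#'   marker, unresolvable channels are retained and flagged unmapped.
#' @param transformed Logical flag recording whether intensities are raw
#'   instrument-scale values (`FALSE`, the default -- all scoring math runs
#'   on this scale) or display-transformed.
#' @param metadata List of acquisition metadata (e.g. `total_leukocytes`,
#'   per-event ground-truth labels from the simulator).
#' @return An object of class `wm_events`.
#' @export
event_table <- function(values, tube_id = "tube1", panel = NULL,
                        transformed = FALSE, metadata = list()) {
  values <- as.matrix(values)
  if (nrow(values) < 1) stop("event table must contain at least one event")
  if (is.null(colnames(values))) stop("event table requires channel names")
  if (anyDuplicated(colnames(values))) stop("duplicate channel names")
  storage.mode(values) <- "double"
  unmapped <- character()
  if (!is.null(panel) || TRUE) {
    cn <- colnames(values)
    mapped <- cn
    for (i in seq_along(cn)) {
      mk <- NA_character_
      if (!is.null(panel) && cn[i] %in% names(panel$channel_map))
        mk <- panel$channel_map[[cn[i]]]
      if (is.na(mk)) mk <- match_marker(cn[i])
      if (is.na(mk) && !cn[i] %in% c("FSC", "SSC", "FSC-A", "SSC-A"))
        unmapped <- c(unmapped, cn[i])
      else if (!is.na(mk)) mapped[i] <- mk
    }
    # scatter channels normalised to plain names
    mapped[mapped %in% c("FSC-A")] <- "FSC"
    mapped[mapped %in% c("SSC-A")] <- "SSC"
    if (anyDuplicated(mapped))
      stop("panel configuration error: two channels map to marker ",
           mapped[duplicated(mapped)][1])
    colnames(values) <- mapped
  }
  structure(list(tube_id = tube_id, values = values,
                 transformed = transformed, unmapped = unmapped,
                 metadata = metadata, provenance = list()),
            class = "wm_events")
}

#' @export
print.wm_events <- function(x, ...) {
  cat("wm_events: tube", x$tube_id, "-", nrow(x$values), "events x",
      ncol(x$values), "channels\n")
  cat("  channels:", paste(colnames(x$values), collapse = ", "), "\n")
  if (length(x$unmapped)) cat("  unmapped:", paste(x$unmapped, collapse = ", "), "\n")
  invisible(x)
}

#' Number of events
#' @param events A `wm_events`.
#' @return Integer event count.
#' @export
n_events <- function(events) nrow(events$values)

has_channel <- function(events, marker) marker %in% colnames(events$values)

channel_values <- function(events, marker) {
  if (!has_channel(events, marker))
    stop("gating error: channel for marker '", marker, "' not present")
  events$values[, marker]
}

subset_events <- function(events, idx, gate = NULL) {
  out <- events
  out$values <- events$values[idx, , drop = FALSE]
  if (!is.null(events$metadata$population))
    out$metadata$population <- events$metadata$population[idx]
  if (!is.null(gate)) out$provenance <- c(events$provenance, list(gate))
  out
}

#' Read event-level cytometry data
#'
#' Reads an FCS 3.0/3.1 list-mode file or a CSV event table (header row of
#' channel names, one row per event) into a [event_table()]. The format is
#' detected from the file content (FCS files start with an `FCS` magic
#' string). Channel names are resolved to panel markers; unresolvable
#' channels are retained and flagged, never dropped, and the event count is
#' preserved exactly.
#'
#' @param path File path.
#' @param panel Optional `wm_panel` providing the channel map.
#' @param tube_id Tube identifier for the returned table.
#' @param require Optional character vector of markers that must resolve;
#'   a configuration error listing the missing ones is raised otherwise.
#' @return A `wm_events`.
#' @export
read_events <- function(path, panel = NULL, tube_id = "tube1", require = NULL) {
  if (!file.exists(path)) stop("cannot read events: no such file: ", path)
  magic <- readBin(path, "raw", n = 3)
  if (identical(rawToChar(magic), "FCS")) {
    fcs <- read_fcs(path)
    tab <- event_table(fcs$values, tube_id = tube_id, panel = panel,
                       metadata = fcs$keywords)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!nrow(df)) stop("cannot read events: file has no event rows: ", path)
    if (!all(vapply(df, is.numeric, logical(1))))
      stop("cannot read events: non-numeric channel column in ", path)
    tab <- event_table(as.matrix(df), tube_id = tube_id, panel = panel)
  }
  if (!is.null(require)) {
    missing <- setdiff(require, colnames(tab$values))
    if (length(missing))
      stop("panel configuration error: markers missing from ", path, ": ",
           paste(missing, collapse = ", "))
  }
  tab
}

#' Write event-level cytometry data
#'
#' Writes a [event_table()] to FCS 3.1 (list mode, 32-bit float,
#' little-endian) or CSV. A write/read round trip preserves the value
#' matrix to 32-bit float precision (relative error below 1e-6) for FCS
#' and to full printed precision for CSV.
#'
#' @param table A `wm_events`.
#' @param path Output file path.
#' @param format `"fcs"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("fcs", "csv")) {
  format <- match.arg(format)
  if (!nzchar(path)) stop("I/O error: empty output path")
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  if (format == "csv") {
    utils::write.csv(as.data.frame(table$values), path, row.names = FALSE)
  } else {
    write_fcs(table$values, path)
  }
  invisible(path)
}
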