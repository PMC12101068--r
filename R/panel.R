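# Panel configuration: the 3-tube, 7-colour B-cell panel and the mapping
# from instrument channel names to marker names.

#' Construct a panel configuration
#'
#' A panel describes which markers are acquired in which tube (with their
#' fluorochrome labels) and how instrument channel identifiers map to marker
#' names. Markers acquired in several tubes (CD19, CD45, the light chains)
#' have a designated primary tube used when summaries are merged across
#' tubes.
#'
#' @param tubes Named list; each element is a list with character vectors
#'   `markers` and `fluorochromes` of equal length.
#' @param channel_map Named character vector mapping instrument channel ids
#'   to marker names (e.g. `c("FITC-A" = "FMC7")`). Channel names are also
#'   matched to marker names directly (case-insensitively), so an identity
#'   map may be omitted.
#' @param absent Character vector of scored markers declared absent from
#'   this panel.
#' @return An object of class `wm_panel`.
#' @export
panel_config <- function(tubes, channel_map = character(), absent = character()) {
  stopifnot(is.list(tubes), length(tubes) >= 1)
  for (nm in names(tubes)) {
    tb <- tubes[[nm]]
    if (is.null(tb$markers)) stop("tube '", nm, "' has no markers")
    if (anyDuplicated(tb$markers))
      stop("panel configuration error: duplicated marker within tube '", nm, "'")
    if (!is.null(tb$fluorochromes) && anyDuplicated(tb$fluorochromes[tb$fluorochromes != "FITC/PE"]))
      stop("panel configuration error: one channel mapped to two markers in tube '", nm, "'")
  }
  pan <- structure(list(tubes = tubes, channel_map = channel_map, absent = absent),
                   class = "wm_panel")
  missing <- setdiff(SCORED_MARKERS, c(panel_markers(pan), absent))
  if (length(missing))
    stop("panel configuration error: scored markers neither present nor declared absent: ",
         paste(missing, collapse = ", "))
  pan
}

#' All markers present in a panel
#' @param panel A `wm_panel`.
#' @return Character vector of unique marker names across tubes.
#' @export
panel_markers <- function(panel) {
  unique(unlist(lapply(panel$tubes, `[[`, "markers"), use.names = FALSE))
}

#' Primary tube for a marker
#'
#' @param panel A `wm_panel`.
#' @param marker Marker name.
#' @return Name of the first tube containing the marker, or `NA`.
#' @export
marker_tube <- function(panel, marker) {
  for (nm in names(panel$tubes))
    if (marker %in% panel$tubes[[nm]]$markers) return(nm)
  NA_character_
}

#' The default 7-colour / 3-tube B-lymphocyte panel
#'
#' Tube 1: kappa/lambda-FITC/PE, CD19-PC5.5, CD5-PE-Cy7, CD79b-APC,
#' CD20-PB, CD45-HV500. Tube 2: FMC7-FITC, CD38-PE, CD19-PC5.5, CD5-PE-Cy7,
#' CD23-APC, CD43-APC-AF750, CD45-HV500. Tube 3: kappa/lambda-FITC/PE,
#' CD19-PC5.5, CD13-PE-Cy7, CD22-APC, CD27-BV421, CD45-HV500. Forward and
#' side scatter are implicit in every tube.
#'
#' @return A `wm_panel`.
#' @export
default_panel <- function() {
  panel_config(tubes = list(
    tube1 = list(
      markers = c("kappa", "lambda", "CD19", "CD5", "CD79b", "CD20", "CD45"),
      fluorochromes = c("FITC", "PE", "PC5.5", "PE-Cy7", "APC", "PB", "HV500")),
    tube2 = list(
      markers = c("FMC7", "CD38", "CD19", "CD5", "CD23", "CD43", "CD45"),
      fluorochromes = c("FITC", "PE", "PC5.5", "PE-Cy7", "APC", "APC-AF750", "HV500")),
    tube3 = list(
      markers = c("kappa", "lambda", "CD19", "CD13", "CD22", "CD27", "CD45"),
      fluorochromes = c("FITC", "PE", "PC5.5", "PE-Cy7", "APC", "BV421", "HV500"))
  ))
}

#' Read or write a panel configuration as YAML
#'
#' @param path File path.
#' @return `read_panel` returns a `wm_panel`; `write_panel` is called for
#'   its side effect and returns `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  y <- yaml::read_yaml(path)
  panel_config(tubes = y$tubes,
               channel_map = unlist(y$channel_map %||% list()),
               absent = unlist(y$absent %||% list()))
}

#' @rdname read_panel
#' @param panel A `wm_panel`.
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(list(tubes = panel$tubes,
                        channel_map = as.list(panel$channel_map),
                        absent = panel$absent), path)
  invisible(path)
}

#' @export
print.wm_panel <- function(x, ...) {
  cat("wm_panel:", length(x$tubes), "tube(s);",
      length(panel_markers(x)), "markers\n")
  for (nm in names(x$tubes))
    cat("  ", nm, ": ", paste(x$tubes[[nm]]$markers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
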