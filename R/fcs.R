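# Minimal FCS 3.0/3.1 list-mode codec.
#
# Scope: single-dataset files, $MODE/L list mode, $DATATYPE F (32-bit
# float), D (64-bit float) or I (16/32-bit unsigned integer), little- or
# big-endian. The writer always emits FCS 3.1 float32 little-endian.
# Spillover application is out of scope: intensities are taken as stored
# (pre-compensated acquisition is assumed, as is standard for
# instrument-standardised clinical panels).

FCS_DELIM <- "/"

#' Write a value matrix as an FCS 3.1 file
#'
#' @param values Numeric matrix (events x parameters) with column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_fcs <- function(values, path) {
  values <- as.matrix(values)
  p <- ncol(values); n <- nrow(values)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", i), colnames(values)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
  }
  text_of <- function(bd, ed) {
    body <- paste0(FCS_DELIM, paste(kw, collapse = FCS_DELIM), FCS_DELIM)
    body <- sub("%BD%", sprintf("%010d", bd), body, fixed = TRUE)
    sub("%ED%", sprintf("%010d", ed), body, fixed = TRUE)
  }
  header_len <- 58L
  text_len <- nchar(text_of(0L, 0L))
  data_begin <- header_len + text_len
  data_end <- data_begin + 4L * p * n - 1L
  text <- text_of(data_begin, data_end)
  hdr_num <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   hdr_num(header_len), hdr_num(header_len + text_len - 1L),
                   if (data_end <= 99999999L)
                     paste0(hdr_num(data_begin), hdr_num(data_end))
                   else paste0(hdr_num(0L), hdr_num(0L)),
                   hdr_num(0L), hdr_num(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # list-mode order: all parameters of event 1, then event 2, ...
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file
#'
#' @param path Input path.
#' @return List with `values` (events x parameters matrix, columns named
#'   from `$PnN`) and `keywords` (named character vector of the TEXT
#'   segment).
#' @keywords internal
read_fcs <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (sz < 58) stop("FCS format error at offset 0: truncated header (", sz, " bytes)")
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("FCS format error at offset 0: unsupported version '", version, "'")
  off <- function(a, b) {
    v <- suppressWarnings(as.integer(trimws(rawToChar(raw[a:b]))))
    if (is.na(v)) stop("FCS format error at offset ", a - 1L, ": bad header offset field")
    v
  }
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)
  if (text_end > sz || text_begin >= text_end)
    stop("FCS format error at offset ", text_begin, ": TEXT segment outside file")
  text <- rawToChar(raw[(text_begin + 1L):(text_end + 1L)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) %/% 2 * 2)]
  kwn <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  kw <- stats::setNames(parts[seq(2, length(parts), 2)], kwn)
  kv <- function(name, default = NA_character_) {
    if (name %in% names(kw)) kw[[name]] else default
  }
  par <- as.integer(kv("$PAR")); tot <- as.integer(kv("$TOT"))
  if (is.na(par) || is.na(tot))
    stop("FCS format error at offset ", text_begin, ": missing $PAR/$TOT")
  dtype <- kv("$DATATYPE", "F")
  mode <- kv("$MODE", "L")
  if (mode != "L") stop("FCS format error: only list mode ($MODE/L) is supported")
  byteord <- kv("$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (data_begin == 0L) data_begin <- as.integer(kv("$BEGINDATA", "0"))
  if (data_end == 0L) data_end <- as.integer(kv("$ENDDATA", "0"))
  bits <- as.integer(kv("$P1B", if (dtype == "D") "64" else "32"))
  bytes_per <- switch(dtype,
                      F = 4L, D = 8L,
                      I = as.integer(bits / 8),
                      stop("FCS format error: unsupported $DATATYPE '", dtype, "'"))
  expected <- as.numeric(par) * tot * bytes_per
  avail <- min(sz, data_end) - data_begin + 1L
  if (data_end > sz || avail < expected)
    stop("FCS format error at offset ", data_begin, ": data segment holds ",
         max(avail, 0), " bytes but $PAR=", par, " x $TOT=", tot,
         " requires ", expected)
  con <- rawConnection(raw[(data_begin + 1L):(data_begin + expected)])
  on.exit(close(con))
  vals <- switch(dtype,
                 F = readBin(con, "double", n = par * tot, size = 4L, endian = endian),
                 D = readBin(con, "double", n = par * tot, size = 8L, endian = endian),
                 I = readBin(con, "integer", n = par * tot, size = bytes_per,
                             signed = bytes_per > 2L, endian = endian))
  m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  cn <- vapply(seq_len(par), function(i) kv(sprintf("$P%dN", i), sprintf("P%d", i)),
               character(1))
  colnames(m) <- cn
  list(values = m, keywords = as.list(kw))
}
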