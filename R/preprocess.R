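#' Two-channel EEG record
#'
#' Container for one record of the two-column Bern-Barcelona style: two
#' adjacent-channel time series `x` and `y` sampled at `fs` Hz, plus an
#' optional class label.
#'
#' @param x,y Numeric vectors of equal length, one sample pair per time
#'   point (microvolts).
#' @param fs Sampling rate in Hz (default 512, the Bern-Barcelona rate).
#' @param label One of `"focal"`, `"nonfocal"`, `"unknown"`.
#' @return An object of class `eeg_record`.
#' @examples
#' r <- eeg_record(sin(1:100), cos(1:100))
#' length(r$x)
#' @export
eeg_record <- function(x, y, fs = 512, label = c("unknown", "focal", "nonfocal")) {
  label <- match.arg(label)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("channels 'x' and 'y' must have equal length (got ",
         length(x), " and ", length(y), ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  structure(list(x = x, y = y, fs = fs, label = label), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples @ %g Hz (%.3g s), label: %s\n",
              length(x$x), x$fs, length(x$x) / x$fs, x$label))
  invisible(x)
}

#' Single-channel signal
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_signal` (a numeric vector with an `fs`
#'   attribute).
#' @export
eeg_signal <- function(samples, fs = 512) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  structure(samples, fs = fs, class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d samples @ %g Hz\n", length(x), attr(x, "fs")))
  invisible(x)
}

#' Read a two-column ASCII EEG record
#'
#' Parses one record in the Bern-Barcelona dialect: one `"x, y"` sample
#' pair per line, comma- or whitespace-separated.  The class label is not
#' stored in the file; it is taken from the `label` argument (callers
#' typically derive it from the filename convention of the dataset).
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz (the dataset's rate, 512, by default).
#' @param label Record label; see [eeg_record()].
#' @return An [eeg_record()].
#' @seealso [write_eeg_record()] for the inverse.
#' @export
read_eeg_record <- function(path, fs = 512, label = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("format error: '", path, "' contains no data lines", call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  n_fields <- lengths(fields)
  if (any(n_fields != 2L)) {
    bad <- which(n_fields != 2L)[1L]
    stop("format error in '", path, "' line ", bad, ": expected 2 columns, got ",
         n_fields[bad], call. = FALSE)
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad) > 0L) {
    stop("parse error in '", path, "' line ", bad[1L],
         ": not a pair of real numbers: '", lines[bad[1L]], "'", call. = FALSE)
  }
  m <- do.call(rbind, vals)
  eeg_record(m[, 1L], m[, 2L], fs = fs, label = label)
}

#' Write a two-column ASCII EEG record
#'
#' Emits the same dialect [read_eeg_record()] parses, with 17 significant
#' digits so that write-then-read round-trips are bit-exact for doubles.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  writeLines(sprintf("%.17g, %.17g", record$x, record$y), path)
  invisible(path)
}

#' Channel difference X - Y
#'
#' The two columns of a record are adjacent channels; their difference
#' cancels interference common to both (the reason the difference channel,
#' not either raw channel, is analysed downstream).
#'
#' @param record An [eeg_record()].
#' @return An [eeg_signal()] with `samples = x - y` at the record's rate.
#' @export
channel_difference <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  eeg_signal(record$x - record$y, fs = record$fs)
}

#' First-difference operator
#'
#' Maps a length-n sequence to its n - 1 successive differences
#' `out[i] = in[i + 1] - in[i]`, accentuating the high-frequency content
#' before wavelet decomposition.
#'
#' @param signal An [eeg_signal()] or plain numeric vector of length >= 2.
#' @return Same type as the input, one sample shorter.
#' @examples
#' differencing(c(1, 3, 6))
#' @export
differencing <- function(signal) {
  n <- length(signal)
  if (n < 2L) stop("differencing needs at least 2 samples", call. = FALSE)
  out <- diff(as.numeric(signal))
  if (inherits(signal, "eeg_signal")) out <- eeg_signal(out, attr(signal, "fs"))
  out
}
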