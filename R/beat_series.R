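#' Beat-to-beat interval series
#'
#' A `beat_series` is a chronologically ordered numeric vector of
#' beat-to-beat (RR) durations in milliseconds. Missing samples — beats the
#' monitor failed to record — are stored as `NA`. Every defined value must be
#' a finite, strictly positive duration no larger than `max_rr_ms`
#' (the default 5000 ms corresponds to 12 bpm and rejects corrupt rows).
#'
#' @param x numeric vector of durations in ms; `NA`/`NaN` mark missing beats.
#' @param max_rr_ms upper sanity bound on a single beat duration (ms).
#' @return an object of class `beat_series` (a numeric vector).
#' @examples
#' rr <- beat_series(c(500, 510, NA, 505))
#' n_missing(rr)
#' @export
beat_series <- function(x, max_rr_ms = 5000) {
  x <- as.numeric(unclass(x))
  if (length(x) == 0) stop("empty series")
  x[is.nan(x)] <- NA_real_
  def <- which(!is.na(x))
  if (any(!is.finite(x[def]))) {
    stop("non-finite beat duration at index ", def[!is.finite(x[def])][1])
  }
  if (any(x[def] <= 0)) {
    stop("non-positive beat duration at index ", def[x[def] <= 0][1])
  }
  if (any(x[def] > max_rr_ms)) {
    stop("beat duration exceeds ", max_rr_ms, " ms at index ",
         def[x[def] > max_rr_ms][1])
  }
  structure(x, class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<beat_series> %d beats, %d missing, mean %.1f ms, total %.1f s\n",
              length(v), sum(is.na(v)), mean(v, na.rm = TRUE),
              sum(v, na.rm = TRUE) / 1000))
  invisible(x)
}

# strip the class, validating on the way in when needed
as_rr_values <- function(rr) {
  if (inherits(rr, "beat_series")) as.numeric(unclass(rr))
  else as.numeric(unclass(beat_series(rr)))
}

#' Count missing beats in a series
#' @param rr a [beat_series()] or numeric vector.
#' @return integer count of missing markers.
#' @export
n_missing <- function(rr) sum(is.na(as_rr_values(rr)))

# -- plain-text / CSV input-output --------------------------------------------

# `source` may be a file path or the literal text content (possibly with
# embedded newlines); returns one character element per line.
source_lines <- function(source) {
  source <- as.character(source)
  if (length(source) == 1 && !grepl("\n", source, fixed = TRUE) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  if (length(source) == 1) {
    return(strsplit(source, "\n", fixed = TRUE)[[1]])
  }
  source
}

#' Read a beat-to-beat interval series
#'
#' Accepts plain text with one duration (ms) per line, or a one-column CSV
#' with the header `rr_ms`. A missing beat is encoded as an empty line or the
#' literal token `NaN` (both are read; [write_rr()] always writes `NaN`).
#'
#' @param source a file path or the text content itself.
#' @param max_rr_ms upper sanity bound on a single duration (ms).
#' @return a [beat_series()].
#' @examples
#' read_rr("500\n510\nNaN\n505")
#' @export
read_rr <- function(source, max_rr_ms = 5000) {
  lines <- trimws(source_lines(source))
  lineno <- seq_along(lines)
  if (length(lines) > 0 && tolower(lines[1]) == "rr_ms") {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (length(lines) == 0) stop("empty series")
  miss <- lines == "" | tolower(lines) == "nan"
  vals <- rep(NA_real_, length(lines))
  parsed <- suppressWarnings(as.numeric(lines[!miss]))
  if (anyNA(parsed)) {
    bad <- lineno[!miss][which(is.na(parsed))[1]]
    stop("parse error: non-numeric value at line ", bad)
  }
  vals[!miss] <- parsed
  bad <- !miss & (vals <= 0 | vals > max_rr_ms)
  if (any(bad)) {
    stop("validation error: beat duration out of (0, ", max_rr_ms,
         "] ms at line ", lineno[bad][1])
  }
  beat_series(vals, max_rr_ms = max_rr_ms)
}

#' Write a beat-to-beat interval series
#'
#' One duration per line in ms; missing beats are written as the canonical
#' token `NaN` so files stay line-diffable.
#'
#' @param rr a [beat_series()] or numeric vector.
#' @param path output file path; with `NULL` the lines are returned instead.
#' @return invisibly, the character vector of lines written.
#' @export
write_rr <- function(rr, path = NULL) {
  x <- as_rr_values(rr)
  lines <- vapply(x, function(v) {
    if (is.na(v)) "NaN" else format(v, trim = TRUE, scientific = FALSE)
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
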