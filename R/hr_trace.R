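#' Equisampled instantaneous heart-rate trace
#'
#' Continuous heart-rate monitors record, alongside the beat-to-beat series,
#' an automatically smoothed instantaneous pulse trace sampled on a uniform
#' grid (1 sample/s for the devices considered here). The trace is the
#' auxiliary input that guides gap filling: unlike the RR channel it is
#' gap-free by construction.
#'
#' @param bpm numeric vector of pulse values in beats per minute; all values
#'   must lie strictly inside (20, 250).
#' @param dt sampling interval in seconds (default 1).
#' @param t0 time of the first sample in seconds (default 0).
#' @return an object of class `hr_trace`.
#' @export
hr_trace <- function(bpm, dt = 1, t0 = 0) {
  bpm <- as.numeric(bpm)
  if (length(bpm) == 0) stop("empty trace")
  if (anyNA(bpm) || any(!is.finite(bpm))) stop("non-finite heart-rate value")
  if (any(bpm <= 20 | bpm >= 250)) {
    stop("validation error: heart rate outside (20, 250) bpm at sample ",
         which(bpm <= 20 | bpm >= 250)[1])
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  structure(list(bpm = bpm, dt = dt, t0 = t0), class = "hr_trace")
}

#' @export
print.hr_trace <- function(x, ...) {
  cat(sprintf("<hr_trace> %d samples at %g s, duration %.1f s, mean %.1f bpm\n",
              length(x$bpm), x$dt, hr_duration_s(x), mean(x$bpm)))
  invisible(x)
}

#' Duration covered by a heart-rate trace
#' @param hr an [hr_trace()].
#' @return duration in seconds (`n * dt`).
#' @export
hr_duration_s <- function(hr) length(hr$bpm) * hr$dt

#' Read a heart-rate trace from CSV
#'
#' Two formats are accepted: a two-column CSV `time_s,hr_bpm` whose time
#' stamps must be uniformly spaced (within 1e-6 s), or a one-column CSV
#' `hr_bpm` with the sampling interval supplied through `dt`.
#'
#' @param source a file path or the text content itself.
#' @param dt sampling interval (s) used for the one-column format.
#' @return an [hr_trace()].
#' @examples
#' read_hr("time_s,hr_bpm\n0,120\n1,121")
#' @export
read_hr <- function(source, dt = 1) {
  lines <- trimws(source_lines(source))
  lines <- lines[lines != ""]
  if (length(lines) < 2) stop("empty trace")
  header <- tolower(gsub("\\s", "", lines[1]))
  body <- lines[-1]
  if (header == "time_s,hr_bpm") {
    parts <- strsplit(body, ",", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("format error: expected two columns")
    tt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
    hh <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    if (anyNA(tt) || anyNA(hh)) stop("parse error: non-numeric value")
    if (length(tt) >= 2) {
      d <- diff(tt)
      if (any(abs(d - d[1]) > 1e-6) || d[1] <= 0) {
        stop("format error: non-uniform time spacing")
      }
      dt <- d[1]
    }
    hr_trace(hh, dt = dt, t0 = tt[1])
  } else if (header == "hr_bpm") {
    hh <- suppressWarnings(as.numeric(body))
    if (anyNA(hh)) stop("parse error: non-numeric value")
    hr_trace(hh, dt = dt)
  } else {
    stop("format error: expected header 'time_s,hr_bpm' or 'hr_bpm'")
  }
}

#' Instantaneous heart rate at a time offset
#'
#' Looks up the pulse value at an arbitrary time by linear interpolation
#' between the two bracketing samples (the default, which keeps the gap
#' filler's corrective factor continuous in time) or by nearest-sample
#' lookup. Times beyond either end of the trace clamp to the end value.
#'
#' @param hr an [hr_trace()].
#' @param t_ms time offset in milliseconds (>= 0), measured on the same clock
#'   as the RR series (see [beat_time()]).
#' @param method `"linear"` (default) or `"nearest"`.
#' @return pulse value(s) in bpm.
#' @export
hr_at_time <- function(hr, t_ms, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!inherits(hr, "hr_trace")) stop("hr must be an hr_trace")
  if (any(t_ms < 0)) stop("t_ms must be >= 0")
  n <- length(hr$bpm)
  if (n == 1) return(rep(hr$bpm, length(t_ms)))
  times <- hr$t0 + (seq_len(n) - 1) * hr$dt
  t_s <- t_ms / 1000
  if (method == "linear") {
    approx(times, hr$bpm, xout = t_s, rule = 2)$y
  } else {
    idx <- clamp(round((t_s - hr$t0) / hr$dt) + 1, 1, n)
    hr$bpm[idx]
  }
}
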