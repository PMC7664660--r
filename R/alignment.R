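#' Check RR-to-heart-rate time alignment
#'
#' The sum of all beat-to-beat durations should (approximately) equal the
#' total time for which the parallel heart-rate trace was recorded; this is
#' the constraint the gap filler relies on to translate beat indices into
#' trace time. The check is purely diagnostic: a mismatch beyond
#' `tolerance_s` raises a warning, never an error, because misalignments do
#' not accumulate with recording length.
#'
#' @param rr a [beat_series()] or numeric vector (ms). Missing beats do not
#'   contribute to the sum.
#' @param hr an [hr_trace()].
#' @param tolerance_s warn when the absolute mismatch exceeds this (default 2 s).
#' @return an `alignment_report`: list with `rr_total_ms`, `hr_duration_ms`,
#'   `mismatch_ms` (= `rr_total_ms - hr_duration_ms`, exactly) and
#'   `missing_count`.
#' @export
check_alignment <- function(rr, hr, tolerance_s = 2) {
  x <- as_rr_values(rr)
  if (!inherits(hr, "hr_trace")) stop("hr must be an hr_trace")
  rr_total <- sum(x, na.rm = TRUE)
  hr_dur <- hr_duration_s(hr) * 1000
  mismatch <- rr_total - hr_dur
  if (abs(mismatch) > tolerance_s * 1000) {
    warning(sprintf("RR/HR misalignment of %.0f ms exceeds %.0f ms tolerance",
                    mismatch, tolerance_s * 1000))
  }
  structure(list(rr_total_ms = rr_total, hr_duration_ms = hr_dur,
                 mismatch_ms = mismatch, missing_count = sum(is.na(x))),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(
    "<alignment_report> sum(RR) %.1f s, HR duration %.1f s, mismatch %+.0f ms, %d missing\n",
    x$rr_total_ms / 1000, x$hr_duration_ms / 1000, x$mismatch_ms,
    x$missing_count))
  invisible(x)
}

# Replace each missing sample by the mean of its nearest defined neighbour on
# each side (the single available neighbour at the boundaries), so cumulative
# time stays defined mid-correction.
substitute_missing <- function(x) {
  if (!anyNA(x)) return(x)
  def <- which(!is.na(x))
  if (length(def) == 0) stop("all samples missing")
  idx <- seq_along(x)
  prev <- approx(def, x[def], xout = idx, method = "constant",
                 f = 0, rule = 2)$y
  nxt <- approx(def, x[def], xout = idx, method = "constant",
                f = 1, rule = 2)$y
  x[is.na(x)] <- ((prev + nxt) / 2)[is.na(x)]
  x
}

#' Time offset of a beat
#'
#' Returns the cumulative duration of all beats preceding the `index`-th one,
#' i.e. the time at which that beat starts, in ms; `beat_time(rr, 1)` is 0
#' and `beat_time(rr, n + 1)` is the total duration of the series. Missing
#' beats inside the prefix are substituted by the mean of the nearest defined
#' neighbour on each side, so the mapping from beat index to trace time stays
#' defined while a correction is in progress.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param index beat index, `1 <= index <= length(rr) + 1`.
#' @return time offset in ms.
#' @examples
#' beat_time(beat_series(rep(500, 10)), 5) # 2000
#' @export
beat_time <- function(rr, index) {
  x <- as_rr_values(rr)
  n <- length(x)
  if (length(index) != 1 || is.na(index) || index < 1 || index > n + 1 ||
      index != round(index)) {
    stop("index out of range: must be an integer in [1, ", n + 1, "]")
  }
  if (index == 1) return(0)
  sum(substitute_missing(x)[seq_len(index - 1)])
}
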