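# Artifact detection: single-sample (or clustered) too-long intervals, and
# runs of missing samples.

# median of the defined samples inside the centred window, excluding i;
# one-sided (clipped) near the boundaries
local_baseline <- function(x, i, h) {
  win <- setdiff(max(1, i - h):min(length(x), i + h), i)
  v <- x[win]
  v <- v[!is.na(v)]
  if (length(v) < 2) return(NA_real_)
  median(v)
}

#' Detect spuriously long beat-to-beat intervals
#'
#' A missed beat makes the monitor report one interval that is (close to) an
#' integer multiple of the true local beat duration. A defined sample is
#' flagged as a peak when it exceeds the local baseline — the median of the
#' defined samples in the centred window, excluding the sample itself — both
#' by the ratio `ratio_threshold` and by the absolute excess
#' `abs_threshold_ms` (the empirical ~300 ms guard keeps ordinary variability
#' at low heart rates from being flagged). Runs of adjacent flagged samples
#' are merged into a single event anchored at the leftmost sample, with the
#' beat multiple re-estimated from their sum.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param ratio_threshold flag when `value > baseline * ratio_threshold`.
#' @param abs_threshold_ms and when `value - baseline > abs_threshold_ms`.
#' @param window odd window width (samples) for the local median baseline.
#' @return a data frame of peak events ordered by `loc`, with columns `loc`
#'   (index of the first flagged sample), `width` (number of merged samples),
#'   `est_beats` (estimated number of true beats hidden in the event, >= 2)
#'   and `peak_value_ms` (summed duration of the flagged samples).
#' @examples
#' detect_peaks(beat_series(c(rep(500, 10), 1000, rep(500, 10))))
#' @export
detect_peaks <- function(rr, ratio_threshold = 1.5, abs_threshold_ms = 300,
                         window = 11) {
  x <- as_rr_values(rr)
  if (window < 3 || !is_odd(window)) stop("window must be odd and >= 3")
  if (sum(!is.na(x)) < window) stop("series too short: fewer defined samples than window")
  h <- (window - 1) / 2
  empty <- data.frame(loc = integer(0), width = integer(0),
                      est_beats = integer(0), peak_value_ms = numeric(0))

  base <- rep(NA_real_, length(x))
  cand <- which(!is.na(x))
  for (i in cand) base[i] <- local_baseline(x, i, h)
  flagged <- which(!is.na(x) & !is.na(base) &
                     x > base * ratio_threshold &
                     x - base > abs_threshold_ms)
  if (length(flagged) == 0) return(empty)

  grp <- cumsum(c(1L, diff(flagged) != 1L))
  events <- lapply(split(flagged, grp), function(locs) {
    total <- sum(x[locs])
    b <- base[locs[1]]
    data.frame(loc = locs[1], width = length(locs),
               est_beats = max(2L, as.integer(round(total / b))),
               peak_value_ms = total)
  })
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out[order(out$loc), , drop = FALSE]
}

#' Detect runs of missing beats
#'
#' Reports every maximal run of consecutive missing markers once, ordered by
#' position.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @return a data frame of gap events with columns `loc` (index of the first
#'   missing sample) and `width` (run length).
#' @examples
#' detect_miss(beat_series(c(500, NA, NA, 510)))
#' @export
detect_miss <- function(rr) {
  x <- as_rr_values(rr)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(loc = starts[r$values], width = r$lengths[r$values])
}
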