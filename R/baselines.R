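# Reference correction methods the stochastic algorithms are compared
# against: sliding median filter, threshold-based cubic interpolation in the
# spirit of common HRV software, and deterministic cubic-spline gap filling.

#' Sliding median filter
#'
#' Replaces every defined sample that has a complete, fully defined centred
#' window by the median of that window. Boundary samples with incomplete
#' windows, missing samples, and samples whose window contains a missing
#' value are left untouched — the median filter is a spike tool, not a gap
#' filler.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param width odd window width, >= 3.
#' @return a filtered [beat_series()].
#' @export
median_filter <- function(rr, width = 3) {
  x <- as_rr_values(rr)
  if (width < 3 || !is_odd(width)) stop("width must be odd and >= 3")
  n <- length(x)
  if (n < width) return(beat_series(x))
  if (!anyNA(x)) {
    return(beat_series(runmed(x, width, endrule = "keep")))
  }
  h <- (width - 1) / 2
  out <- x
  for (i in (h + 1):(n - h)) {
    win <- x[(i - h):(i + h)]
    if (!anyNA(win)) out[i] <- median(win)
  }
  beat_series(out)
}

#' Threshold-based cubic interpolation
#'
#' A defined sample is flagged when it deviates from the local median by more
#' than `threshold` robust standard deviations, where the robust SD is
#' 1.4826 times the median absolute deviation of the centred window
#' (excluding the sample). When the window is degenerate (robust SD 0), the
#' absolute fallback `abs_fallback_ms` is used instead. Flagged samples are
#' replaced by a cubic-spline evaluation fitted on the nearest non-flagged
#' defined neighbours. Mirroring the behaviour of the software this filter
#' is modelled after, missing samples are never filled, and flagged runs
#' wider than half the window are left as they are — longer holes stay
#' unfilled.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param threshold flagging threshold in robust standard deviations.
#' @param window odd window width for the local median and MAD.
#' @param abs_fallback_ms absolute deviation threshold used when the local
#'   robust SD is zero.
#' @return a filtered [beat_series()]; missing markers are preserved.
#' @export
threshold_cubic <- function(rr, threshold = 5, window = 11,
                            abs_fallback_ms = 300) {
  x <- as_rr_values(rr)
  if (window < 3 || !is_odd(window)) stop("window must be odd and >= 3")
  n <- length(x)
  h <- (window - 1) / 2
  flagged <- logical(n)
  for (i in which(!is.na(x))) {
    win <- setdiff(max(1, i - h):min(n, i + h), i)
    v <- x[win]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    med <- median(v)
    sigma <- 1.4826 * median(abs(v - med))
    dev <- abs(x[i] - med)
    flagged[i] <- if (sigma > 0) dev > threshold * sigma else dev > abs_fallback_ms
  }
  if (!any(flagged)) return(beat_series(x))
  out <- x
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  usable <- which(!flagged & !is.na(x))
  for (k in which(runs$values)) {
    run <- starts[k]:ends[k]
    if (length(run) > h) next  # longer holes are not filled
    left <- utils::tail(usable[usable < run[1]], h)
    right <- utils::head(usable[usable > run[length(run)]], h)
    if (length(left) < 2 || length(right) < 2) next
    fit <- splinefun(c(left, right), x[c(left, right)], method = "fmm")
    out[run] <- fit(run)
  }
  beat_series(out)
}

#' Deterministic cubic-spline gap filling
#'
#' Fills every run of missing beats by evaluating a cubic spline fitted on
#' the `2 * width` nearest defined samples on each side of the gap, at the
#' missing indices. The interpolant reproduces polynomial series of degree
#' <= 3 exactly. Gaps touching either series boundary, or with fewer than
#' two defined context samples on a side, are rejected.
#'
#' @param rr a [beat_series()] or numeric vector (ms) with missing markers.
#' @return a gap-free [beat_series()] of the same length.
#' @export
cubic_spline_fill <- function(rr) {
  x <- as_rr_values(rr)
  gaps <- detect_miss(x)
  if (nrow(gaps) == 0) return(beat_series(x))
  out <- x
  defined <- which(!is.na(x))
  for (k in seq_len(nrow(gaps))) {
    loc <- gaps$loc[k]
    w <- gaps$width[k]
    if (loc == 1) stop("no left context: gap at series start")
    if (loc + w - 1 == length(x)) stop("no right context: gap at series end")
    left <- utils::tail(defined[defined < loc], 2 * w)
    right <- utils::head(defined[defined >= loc + w], 2 * w)
    if (length(left) < 2 || length(right) < 2) {
      stop("insufficient context around gap at index ", loc)
    }
    fit <- splinefun(c(left, right), x[c(left, right)], method = "fmm")
    out[loc:(loc + w - 1)] <- fit(loc:(loc + w - 1))
  }
  beat_series(out)
}
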