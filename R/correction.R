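# The two stochastic correction procedures: replacement of missed-beat peaks
# and heart-rate-guided filling of gaps.

#' Context statistics around an artifact
#'
#' Estimates the expected beat duration and its dispersion from the defined
#' samples in two windows, `span_beats_per_side` beats immediately before the
#' artifact and the same number immediately after it. The mean is taken over
#' both windows combined; standard deviations are computed per side with the
#' sample (n-1) convention. A side with fewer than two defined samples
#' borrows the SD (and, when entirely empty, the mean) of the opposite side,
#' which is how artifacts touching the series boundary are handled.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param loc index of the first artifact sample.
#' @param span_beats_per_side context window extent per side, in beats.
#' @param width artifact width in samples (1 for a single-sample peak).
#' @return a list with `mean_ms`, `sd_before_ms`, `sd_after_ms`,
#'   `mean_before_ms`, `mean_after_ms` and `span_used` (defined samples
#'   actually available per side).
#' @examples
#' surrounding_stats(c(800, 810, 1600, 790, 805), loc = 3, span_beats_per_side = 2)
#' @export
surrounding_stats <- function(rr, loc, span_beats_per_side, width = 1) {
  x <- if (inherits(rr, "beat_series")) as.numeric(unclass(rr)) else as.numeric(rr)
  n <- length(x)
  span <- span_beats_per_side
  if (span < 1) stop("span_beats_per_side must be >= 1")
  if (loc < 1 || loc + width - 1 > n) stop("artifact outside series")
  before_idx <- if (loc > 1) max(1, loc - span):(loc - 1) else integer(0)
  after_start <- loc + width
  after_idx <- if (after_start <= n) {
    after_start:min(n, after_start + span - 1)
  } else integer(0)
  vb <- x[before_idx]; vb <- vb[!is.na(vb)]
  va <- x[after_idx];  va <- va[!is.na(va)]
  if (length(vb) == 0 && length(va) == 0) {
    stop("no defined context on either side of the artifact")
  }
  if (length(vb) < 2 && length(va) < 2) {
    stop("insufficient context: need >= 2 defined samples on at least one side")
  }
  sdb <- if (length(vb) >= 2) sd(vb) else sd(va)
  sda <- if (length(va) >= 2) sd(va) else sd(vb)
  mb <- if (length(vb) >= 1) mean(vb) else mean(va)
  ma <- if (length(va) >= 1) mean(va) else mean(vb)
  list(mean_ms = mean(c(vb, va)),
       sd_before_ms = sdb, sd_after_ms = sda,
       mean_before_ms = mb, mean_after_ms = ma,
       span_used = c(before = length(vb), after = length(va)))
}

correction_result <- function(series, total_new, edits) {
  structure(list(series = series, total_new = total_new, edits = edits),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> %d beats, total_new %d, %d edit(s)\n",
              length(unclass(x$series)), x$total_new, nrow(x$edits)))
  invisible(x)
}

empty_edits <- function() {
  data.frame(kind = character(0), loc = integer(0), width = integer(0),
             values = I(list()))
}

# one rbind-able edit row
edit_row <- function(kind, loc, width, values) {
  data.frame(kind = kind, loc = loc, width = width,
             values = I(list(as.numeric(values))))
}

# Draw `k` beats from Normal(mean_ms, sd_ms), clamped to mean +/- 3 sd and to
# strictly positive durations. With sd 0 the draws collapse to the mean and
# the result is deterministic.
draw_beats <- function(k, mean_ms, sd_ms, clamp_draws = TRUE) {
  d <- rnorm(k, mean_ms, sd_ms)
  if (clamp_draws) {
    d <- clamp(d, mean_ms - 3 * sd_ms, mean_ms + 3 * sd_ms)
  }
  pmax(d, 1e-6)
}

#' Correct missed-beat peaks
#'
#' Implements the stochastic short-peak correction: each detected
#' spuriously long interval (see [detect_peaks()]) that hides at most
#' `max_multiple` true beats is replaced by `est_beats` durations drawn from
#' a normal distribution whose mean and SD come from [surrounding_stats()]
#' with a context of `2 * est_beats` beats per side (the SD used for the
#' draws is the mean of the before/after SDs). Peaks estimated to hide more
#' than `max_multiple` beats are converted into a gap of `est_beats` missing
#' markers, to be reconstructed by the more careful [fill_gaps()]. Output
#' indices are shifted as the series grows, so the corrected series has
#' length `N + total_new`.
#'
#' Draws are clamped to mean +/- 3 SD and to positive durations
#' (`clamp_draws = FALSE` gives the unbounded literal draws). With
#' `rescale = TRUE` the replacement beats are additionally scaled by a common
#' factor so that their sum equals the recorded peak duration exactly,
#' conserving cumulative time; this is appropriate for genuine missed-beat
#' artifacts, where the too-long interval really does span the hidden beats.
#' The default is `FALSE` (plain draws from the local statistics), which is
#' the behaviour whose measure-preservation the evaluation harness
#' quantifies; see the package vignette for the trade-off.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param max_multiple largest beat multiple replaced in place; larger peaks
#'   become gaps.
#' @param seed optional integer seed giving bit-reproducible output; with
#'   `NULL` the current RNG stream is used.
#' @param rescale rescale each replacement so its sum equals the original
#'   peak value (exact per-event time conservation).
#' @param ratio_threshold,abs_threshold_ms,window passed to [detect_peaks()].
#' @param clamp_draws clamp generated beats to mean +/- 3 SD.
#' @return a `correction_result`: list with `series` (the corrected
#'   [beat_series()]), `total_new` (number of inserted beats) and `edits`
#'   (one row per event: kind `replaced` or `converted_to_gap`, location in
#'   the output series, width replaced, generated values).
#' @examples
#' rr <- beat_series(c(rep(500, 10), 1000, rep(500, 10)))
#' correct_peaks(rr, seed = 1)
#' @export
correct_peaks <- function(rr, max_multiple = 3, seed = NULL, rescale = FALSE,
                          ratio_threshold = 1.5, abs_threshold_ms = 300,
                          window = 11, clamp_draws = TRUE) {
  x <- as_rr_values(rr)
  events <- detect_peaks(x, ratio_threshold = ratio_threshold,
                         abs_threshold_ms = abs_threshold_ms, window = window)
  if (nrow(events) == 0) {
    return(correction_result(beat_series(x), 0L, empty_edits()))
  }
  with_seed(seed, {
    out <- x
    shift <- 0L
    total_new <- 0L
    edits <- list()
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      loc <- ev$loc + shift
      w <- ev$width
      est <- ev$est_beats
      if (est <= max_multiple) {
        st <- surrounding_stats(out, loc, span_beats_per_side = 2 * est,
                                width = w)
        sd_use <- mean(c(st$sd_before_ms, st$sd_after_ms))
        newvals <- draw_beats(est, st$mean_ms, sd_use, clamp_draws)
        if (rescale) {
          s <- sum(newvals)
          if (s > 0) newvals <- newvals * (ev$peak_value_ms / s)
        }
        kind <- "replaced"
      } else {
        newvals <- rep(NA_real_, est)
        kind <- "converted_to_gap"
      }
      out <- c(out[seq_len(loc - 1)], newvals,
               if (loc + w <= length(out)) out[(loc + w):length(out)])
      edits[[k]] <- edit_row(kind, loc, w, newvals)
      shift <- shift + (est - w)
      total_new <- total_new + (est - w)
    }
    correction_result(beat_series(out), as.integer(total_new),
                      do.call(rbind, edits))
  })
}

#' Corrective scale factor for heart-rate-guided gap filling
#'
#' Ratio of the heart rate expected under a linear change across the gap to
#' the heart rate the monitor actually measured at that moment, clamped to
#' `[0.5, 2]`. The factor multiplies an interpolated beat duration: when the
#' measured rate is above the linear expectation the heart is beating faster
#' than interpolation assumes and the generated beat is shortened, and vice
#' versa. When the heart rate changes exactly linearly across the gap the
#' factor equals 1.
#'
#' @param hr_linear_bpm heart rate expected from linear interpolation between
#'   the gap endpoints (bpm, > 0).
#' @param hr_measured_bpm heart rate measured at the beat's provisional time
#'   (bpm, > 0).
#' @return unitless factor in `[0.5, 2]`.
#' @examples
#' corrective_scale_factor(120, 150) # heart faster than linear: 0.8
#' @export
corrective_scale_factor <- function(hr_linear_bpm, hr_measured_bpm) {
  if (any(hr_linear_bpm <= 0) || any(hr_measured_bpm <= 0)) {
    stop("heart rates must be > 0")
  }
  clamp(hr_linear_bpm / hr_measured_bpm, 0.5, 2.0)
}

#' Fill gaps of missing beats using the heart-rate trace
#'
#' Reconstructs every run of missing beats (see [detect_miss()]). For a gap
#' of width `w`, context means and SDs are estimated from `2 * w` beats on
#' each side ([surrounding_stats()]); the gap's start and (nominal) end times
#' are mapped into the heart-rate trace via [beat_time()]. Each missing beat
#' is then interpolated linearly between the before/after context statistics
#' according to its fractional position in the gap, drawn from a normal
#' distribution with the interpolated mean and SD (clamped as in
#' [correct_peaks()]), and finally multiplied by the corrective scale factor
#' ([corrective_scale_factor()]) comparing the measured heart rate at the
#' beat's provisional time with the linear expectation — so non-linear
#' heart-rate changes across the gap bend the reconstruction accordingly.
#' The running time cursor advances by each generated beat, so subsequent
#' heart-rate lookups use generated, not nominal, positions. Gaps touching
#' the series boundary fall back to one-sided context.
#'
#' @param rr a [beat_series()] or numeric vector (ms) containing missing
#'   markers.
#' @param hr the parallel [hr_trace()]; it must cover the duration of the RR
#'   series (checked against [check_alignment()] up to `tolerance_s`).
#' @param seed optional integer seed giving bit-reproducible output; with
#'   `NULL` the current RNG stream is used.
#' @param tolerance_s alignment tolerance passed to the coverage check (s).
#' @param hr_lookup heart-rate lookup mode, see [hr_at_time()].
#' @param clamp_draws clamp generated beats to mean +/- 3 SD.
#' @return a `correction_result` whose `series` has the same length as the
#'   input and no missing markers; `total_new` is 0 (nothing is inserted),
#'   and `edits` holds one `filled` row per gap with the generated values.
#' @export
fill_gaps <- function(rr, hr, seed = NULL, tolerance_s = 2,
                      hr_lookup = c("linear", "nearest"), clamp_draws = TRUE) {
  hr_lookup <- match.arg(hr_lookup)
  x <- as_rr_values(rr)
  if (!inherits(hr, "hr_trace")) stop("hr must be an hr_trace")
  est_total <- beat_time(x, length(x) + 1)
  if (hr_duration_s(hr) * 1000 <
        est_total - max(tolerance_s * 1000, est_total / length(x))) {
    stop("HR trace shorter than the RR series duration")
  }
  gaps <- detect_miss(x)
  if (nrow(gaps) == 0) {
    return(correction_result(beat_series(x), 0L, empty_edits()))
  }
  with_seed(seed, {
    out <- x
    edits <- list()
    for (k in seq_len(nrow(gaps))) {
      loc <- gaps$loc[k]
      w <- gaps$width[k]
      st <- surrounding_stats(out, loc, span_beats_per_side = 2 * w, width = w)
      t_start <- beat_time(out, loc)
      t_end <- beat_time(out, loc + w)
      hr_s <- hr_at_time(hr, t_start, method = hr_lookup)
      hr_e <- hr_at_time(hr, t_end, method = hr_lookup)
      cursor <- t_start
      vals <- numeric(w)
      for (j in seq_len(w)) {
        d <- j / (w + 1)
        est <- (1 - d) * st$mean_before_ms + d * st$mean_after_ms
        sd_j <- (1 - d) * st$sd_before_ms + d * st$sd_after_ms
        t_j <- cursor + est
        hr_lin <- hr_s + (t_j - t_start) / (t_end - t_start) * (hr_e - hr_s)
        fac <- corrective_scale_factor(hr_lin,
                                       hr_at_time(hr, t_j, method = hr_lookup))
        v <- draw_beats(1, est, sd_j, clamp_draws) * fac
        vals[j] <- v
        out[loc + j - 1] <- v
        cursor <- cursor + v
      }
      edits[[k]] <- edit_row("filled", loc, w, vals)
    }
    correction_result(beat_series(out), 0L, do.call(rbind, edits))
  })
}
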