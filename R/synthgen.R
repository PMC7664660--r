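# Synthetic paired RR/HR signal generation and artifact injection. The
# generator emulates the two exercise regimes the correction methods are
# validated on: very-low-variability chest-strap recordings from strenuous
# cycling (SDNN of order 13 ms with RMSSD of order 3 ms) and
# higher-variability treadmill recordings (SDNN of order 57 ms, RMSSD of
# order 32 ms).

#' Synthetic tachogram profile
#'
#' Describes the generative model for a paired RR/HR recording: the RR
#' series is a mean level plus a linear drift, a low-frequency and a
#' high-frequency sinusoidal modulation (random phases), and white Gaussian
#' beat-to-beat noise; the HR trace is derived from the smoothed RR series
#' (see [generate_rr_hr()]).
#'
#' @param mean_rr_ms mean beat duration (ms), in (250, 1500).
#' @param sdnn_target_ms nominal overall variability the profile aims at
#'   (ms); recorded for reference, the realized SDNN follows from the
#'   components.
#' @param lf_amp_ms,lf_freq_hz low-frequency modulation amplitude (ms) and
#'   frequency (Hz).
#' @param hf_amp_ms,hf_freq_hz high-frequency modulation amplitude (ms) and
#'   frequency (Hz).
#' @param trend_ms total linear drift of the mean level across the segment
#'   (ms, centred so the series mean stays `mean_rr_ms`).
#' @param noise_sd_ms SD of the white beat-to-beat noise (ms).
#' @param duration_s segment duration (s), >= 60.
#' @return an object of class `hrv_profile`.
#' @export
hrv_profile <- function(mean_rr_ms, sdnn_target_ms, lf_amp_ms, lf_freq_hz,
                        hf_amp_ms, hf_freq_hz, trend_ms = 0, noise_sd_ms = 0,
                        duration_s = 300) {
  if (mean_rr_ms <= 250 || mean_rr_ms >= 1500) {
    stop("mean_rr_ms must be in (250, 1500)")
  }
  if (any(c(lf_amp_ms, hf_amp_ms, noise_sd_ms, sdnn_target_ms) < 0)) {
    stop("amplitudes and SDs must be >= 0")
  }
  if (duration_s < 60) stop("duration_s must be >= 60")
  structure(list(mean_rr_ms = mean_rr_ms, sdnn_target_ms = sdnn_target_ms,
                 lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
                 hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
                 trend_ms = trend_ms, noise_sd_ms = noise_sd_ms,
                 duration_s = duration_s),
            class = "hrv_profile")
}

#' Named synthetic profiles for the two validated regimes
#'
#' `needed_like` emulates a 5-min strenuous-cycling chest-strap segment:
#' mean RR 550 ms, SDNN of order 13 ms dominated by a slow drift, RMSSD of
#' order 3 ms dominated by small white beat-to-beat noise. `physionet_like`
#' emulates a 5-min uphill treadmill-walk recording: mean RR 800 ms, SDNN of
#' order 57 ms, RMSSD of order 32 ms, with much stronger modulation and
#' noise. Component amplitudes were sized once from those regime statistics;
#' the vignette details the choices.
#'
#' @param name `"needed_like"` or `"physionet_like"`.
#' @param duration_s segment duration (s).
#' @param ... overrides passed to [hrv_profile()].
#' @return an `hrv_profile`.
#' @export
hrv_profile_preset <- function(name = c("needed_like", "physionet_like"),
                               duration_s = 300, ...) {
  name <- match.arg(name)
  base <- switch(name,
    needed_like = list(mean_rr_ms = 550, sdnn_target_ms = 13,
                       lf_amp_ms = 3.3, lf_freq_hz = 0.09,
                       hf_amp_ms = 2.1, hf_freq_hz = 0.25,
                       trend_ms = 38, noise_sd_ms = 2),
    physionet_like = list(mean_rr_ms = 800, sdnn_target_ms = 57,
                          lf_amp_ms = 51, lf_freq_hz = 0.08,
                          hf_amp_ms = 28, hf_freq_hz = 0.25,
                          trend_ms = 130, noise_sd_ms = 12))
  args <- utils::modifyList(c(base, list(duration_s = duration_s)), list(...))
  do.call(hrv_profile, args)
}

# centred moving average with shrinking windows at the ends
moving_average <- function(x, k = 5) {
  n <- length(x)
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Generate a mutually consistent RR series and heart-rate trace
#'
#' Beats are generated sequentially: the i-th duration is the profile mean
#' plus the (centred) linear trend, the two sinusoidal modulations evaluated
#' at the beat's cumulative start time, and white noise; generation stops
#' when the cumulative time reaches the profile duration, so the sum of the
#' beat durations exceeds the heart-rate trace duration by less than one
#' beat. The heart-rate trace is the reciprocal of the 5-beat moving average
#' of the RR series (emulating the automatic smoothing the monitors apply to
#' their HR channel), resampled at 1 Hz over the same span — so the pair
#' satisfies the alignment constraint by construction.
#'
#' @param profile an [hrv_profile()].
#' @param seed optional integer seed for bit-reproducible output; with
#'   `NULL` the current RNG stream is used.
#' @return a list with elements `rr` (a [beat_series()]), `hr` (an
#'   [hr_trace()] at 1 Hz) and `profile`.
#' @examples
#' pair <- generate_rr_hr(hrv_profile_preset("needed_like"), seed = 1)
#' check_alignment(pair$rr, pair$hr)
#' @export
generate_rr_hr <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "hrv_profile"))
  p <- profile
  with_seed(seed, {
    phi_lf <- runif(1, 0, 2 * pi)
    phi_hf <- runif(1, 0, 2 * pi)
    dur_ms <- p$duration_s * 1000
    rr <- numeric(ceiling(dur_ms / p$mean_rr_ms * 1.5) + 8)
    t <- 0
    i <- 0L
    while (t < dur_ms) {
      t_s <- t / 1000
      v <- p$mean_rr_ms +
        p$trend_ms * (t_s / p$duration_s - 0.5) +
        p$lf_amp_ms * sin(2 * pi * p$lf_freq_hz * t_s + phi_lf) +
        p$hf_amp_ms * sin(2 * pi * p$hf_freq_hz * t_s + phi_hf) +
        rnorm(1, 0, p$noise_sd_ms)
      v <- max(v, 0.3 * p$mean_rr_ms)  # guard against non-physiological draws
      i <- i + 1L
      rr[i] <- v
      t <- t + v
    }
    rr <- rr[seq_len(i)]
    sm <- moving_average(rr, 5)
    beat_end_s <- cumsum(rr) / 1000
    grid <- 0:(p$duration_s - 1)
    bpm <- approx(beat_end_s, 60000 / sm, xout = grid, rule = 2)$y
    list(rr = beat_series(rr), hr = hr_trace(bpm, dt = 1), profile = p)
  })
}

#' Inject a single-sample peak artifact
#'
#' Replaces one beat by `multiple` times the global mean of the series,
#' mimicking the spike a missed beat produces. The position is drawn
#' uniformly from the interior (at least `margin` beats from either
#' boundary) unless given explicitly.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param multiple peak size as a multiple of the series mean (2 or 3 in the
#'   validation protocol, any value >= 1 accepted).
#' @param seed optional integer seed for the position draw; with `NULL` the
#'   current RNG stream is used.
#' @param pos explicit position (overrides the random draw).
#' @param margin minimum distance from either boundary (beats).
#' @return a list with `series` (the contaminated [beat_series()]), `pos`
#'   and `original` (the replaced ground-truth value).
#' @export
inject_peak <- function(rr, multiple, seed = NULL, pos = NULL, margin = 10) {
  x <- as_rr_values(rr)
  n <- length(x)
  if (n < 2 * margin + 3) stop("series too short for interior injection")
  with_seed(seed, {
    if (is.null(pos)) {
      cand <- which(!is.na(x))
      cand <- cand[cand > margin & cand <= n - margin]
      if (length(cand) == 0) stop("no defined interior position available")
      pos <- if (length(cand) == 1) cand else sample(cand, 1)
    } else {
      if (pos <= margin || pos > n - margin) {
        stop("pos must be at least ", margin, " beats from either boundary")
      }
      if (is.na(x[pos])) stop("pos falls on a missing sample")
    }
    original <- x[pos]
    x[pos] <- multiple * mean(x, na.rm = TRUE)
    list(series = beat_series(x), pos = pos, original = original)
  })
}

#' Inject a gap of missing beats
#'
#' Replaces `width` consecutive beats by missing markers at a position with
#' at least `2 * width` defined beats on each side (the context the fillers
#' need), drawn uniformly unless given explicitly. The removed ground-truth
#' values are returned so reconstruction error can be measured.
#'
#' @param rr a [beat_series()] or numeric vector (ms).
#' @param width gap width in beats (3, 5 or 7 in the validation protocol).
#' @param seed optional integer seed for the position draw; with `NULL` the
#'   current RNG stream is used.
#' @param pos explicit position of the first missing sample.
#' @return a list with `series` (the contaminated [beat_series()]), `event`
#'   (a one-row gap data frame with `loc` and `width`) and `truth` (the
#'   removed values).
#' @export
inject_gap <- function(rr, width, seed = NULL, pos = NULL) {
  x <- as_rr_values(rr)
  n <- length(x)
  ok_pos <- function(p) {
    lo <- p - 2 * width
    hi <- p + width - 1 + 2 * width
    lo >= 1 && hi <= n && !anyNA(x[lo:hi])
  }
  with_seed(seed, {
    if (is.null(pos)) {
      cand <- (2 * width + 1):(n - 3 * width + 1)
      cand <- cand[vapply(cand, ok_pos, logical(1))]
      if (length(cand) == 0) stop("insufficient margins for a width-", width, " gap")
      pos <- if (length(cand) == 1) cand else sample(cand, 1)
    } else if (!ok_pos(pos)) {
      stop("insufficient margins around pos for a width-", width, " gap")
    }
    idx <- pos:(pos + width - 1)
    truth <- x[idx]
    x[idx] <- NA_real_
    list(series = beat_series(x),
         event = data.frame(loc = pos, width = width),
         truth = truth)
  })
}
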