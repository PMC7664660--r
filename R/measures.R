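# The eight HRV measures: time domain (RMSSD, SDNN, SDSD), frequency domain
# (total, LF and HF band power of the resampled tachogram) and the Poincare
# descriptors SD1/SD2.

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Time-domain HRV measures
#'
#' RMSSD is the root mean square of successive differences, SDNN the sample
#' (n-1) standard deviation of the intervals, and SDSD the sample standard
#' deviation of the successive differences.
#'
#' @param rr a gap-free [beat_series()] or numeric vector (ms), n >= 3.
#' @return named numeric vector `c(rmssd, sdnn, sdsd)` in ms.
#' @examples
#' time_domain(c(800, 810, 790, 805))
#' @export
time_domain <- function(rr) {
  x <- as_rr_values(rr)
  if (anyNA(x)) stop("missing values present; correct or fill the series first")
  if (length(x) < 3) stop("need at least 3 beats")
  d <- diff(x)
  c(rmssd = sqrt(mean(d^2)), sdnn = sd(x), sdsd = sd(d))
}

#' Poincare descriptors from SDNN and SDSD
#'
#' The Poincare scattergram of consecutive interval pairs is summarised by
#' the dispersion perpendicular to the identity line (SD1, fast beat-to-beat
#' variability) and along it (SD2, longer-term variability). Both follow
#' algebraically from the second moments of the series via the ellipse
#' identities `SD1 = SDSD / sqrt(2)` and
#' `SD2 = sqrt(2 * SDNN^2 - 0.5 * SDSD^2)` (with the population convention
#' for SDSD the identities are exact; printed sample values reproduce them
#' to rounding).
#'
#' @param sdnn_ms standard deviation of the intervals (ms, >= 0).
#' @param sdsd_ms standard deviation of successive differences (ms, >= 0).
#' @return named numeric vector `c(sd1, sd2)` in ms.
#' @examples
#' poincare(13.13, 3.10)
#' @export
poincare <- function(sdnn_ms, sdsd_ms) {
  if (sdnn_ms < 0 || sdsd_ms < 0) stop("inputs must be >= 0")
  rad <- 2 * sdnn_ms^2 - 0.5 * sdsd_ms^2
  if (rad < 0) stop("degenerate series: 2*SDNN^2 < 0.5*SDSD^2")
  c(sd1 = sdsd_ms / sqrt(2), sd2 = sqrt(rad))
}

# Welch periodogram: Hann-windowed segments of length <= seg_len with 50%
# overlap, one-sided density scaled so that integrating the PSD over
# frequency recovers the signal variance (units ms^2/Hz for a ms signal).
welch_psd <- function(x, fs, seg_len = 256) {
  n <- length(x)
  L <- min(seg_len, n)
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    p <- abs(fft(x[s:(s + L - 1)] * w))^2 / scale
    p1 <- p[1:nf]
    dbl <- if (L %% 2 == 0) 2:(nf - 1) else 2:nf
    p1[dbl] <- 2 * p1[dbl]
    acc <- acc + p1
  }
  list(freq = (0:(nf - 1)) * fs / L, psd = acc / length(starts))
}

#' Frequency-domain HRV measures
#'
#' The tachogram (interval duration against cumulative time) is resampled
#' onto a uniform grid at `resample_hz` by cubic interpolation, linearly
#' detrended, and its power spectral density estimated by Welch's method
#' (Hann-windowed segments of at most 256 samples, 50% overlap). Band powers
#' are integrals of the density over the conventional short-term bands by
#' the trapezoidal rule: total power 0.0033-0.40 Hz, LF 0.04-0.15 Hz and
#' HF 0.15-0.40 Hz.
#'
#' @param rr a gap-free [beat_series()] or numeric vector (ms) covering at
#'   least 30 s (a warning is issued below 60 s, where LF content is not
#'   meaningful).
#' @param resample_hz uniform resampling rate (Hz).
#' @param bands named list of `c(lo, hi)` frequency bands (Hz) for `tp`,
#'   `lf` and `hf`.
#' @return named numeric vector `c(tp, lf, hf)` in ms^2.
#' @export
spectral <- function(rr, resample_hz = 4,
                     bands = list(tp = c(0.0033, 0.40),
                                  lf = c(0.04, 0.15),
                                  hf = c(0.15, 0.40))) {
  x <- as_rr_values(rr)
  if (anyNA(x)) stop("missing values present; correct or fill the series first")
  t_s <- cumsum(x) / 1000
  dur <- t_s[length(t_s)] - t_s[1]
  if (dur < 30) stop("series shorter than 30 s")
  if (dur < 60) warning("series shorter than 60 s: LF content is unreliable")
  grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / resample_hz)
  xi <- spline(t_s, x, xout = grid, method = "fmm")$y
  fit <- stats::lm.fit(cbind(1, grid), xi)
  y <- fit$residuals
  out <- c(tp = 0, lf = 0, hf = 0)
  if (var(y) < 1e-12) return(out)
  p <- welch_psd(y, resample_hz)
  for (b in names(out)) {
    sel <- p$freq >= bands[[b]][1] & p$freq <= bands[[b]][2]
    if (sum(sel) >= 2) out[b] <- pracma::trapz(p$freq[sel], p$psd[sel])
  }
  out
}

#' All eight HRV measures of a series
#'
#' Combines [time_domain()], [spectral()] and [poincare()]. SDSD is reported
#' with the sample (n-1) convention; the Poincare descriptors are evaluated
#' from the population-convention SDSD internally so that the ellipse
#' identity `sd1^2 + sd2^2 = 2 * sdnn^2` holds exactly.
#'
#' @param rr a gap-free [beat_series()] or numeric vector (ms).
#' @param ... passed on to [spectral()].
#' @return named numeric vector with elements `rmssd`, `sdnn`, `sdsd`, `tp`,
#'   `lf`, `hf`, `sd1`, `sd2`.
#' @export
all_measures <- function(rr, ...) {
  x <- as_rr_values(rr)
  td <- time_domain(x)
  sp <- spectral(x, ...)
  pc <- poincare(td[["sdnn"]], sd_pop(diff(x)))
  c(rmssd = td[["rmssd"]], sdnn = td[["sdnn"]], sdsd = td[["sdsd"]],
    tp = sp[["tp"]], lf = sp[["lf"]], hf = sp[["hf"]],
    sd1 = pc[["sd1"]], sd2 = pc[["sd2"]])
}
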