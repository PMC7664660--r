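# fixtures built in code, shared across test files

const_series <- function(n = 50, v = 500) beat_series(rep(v, n))

# RR series whose duration is modulated by a single tone at `freq_hz`,
# evaluated at cumulative beat time (a clean tachogram test signal)
tone_series <- function(freq_hz, amp_ms, mean_ms = 500, duration_s = 120) {
  t <- 0
  rr <- numeric(0)
  while (t < duration_s * 1000) {
    v <- mean_ms + amp_ms * sin(2 * pi * freq_hz * t / 1000)
    rr <- c(rr, v)
    t <- t + v
  }
  beat_series(rr)
}

# heart-rate trace exactly linear in time (1 Hz)
linear_hr <- function(bpm0, bpm1, duration_s) {
  hr_trace(bpm0 + (bpm1 - bpm0) * (0:(duration_s - 1)) / (duration_s - 1),
           dt = 1)
}

# direct-formula reference for the time-domain and Poincare measures,
# independent of the package implementation (sum-based, no stats::sd)
oracle_time_poincare <- function(x) {
  n <- length(x)
  d <- x[-1] - x[-n]
  m <- sum(x) / n
  md <- sum(d) / (n - 1)
  sdnn <- sqrt(sum((x - m)^2) / (n - 1))
  sdsd <- sqrt(sum((d - md)^2) / (n - 2))
  sdsd_pop <- sqrt(sum((d - md)^2) / (n - 1))
  c(rmssd = sqrt(sum(d^2) / (n - 1)),
    sdnn = sdnn, sdsd = sdsd,
    sd1 = sdsd_pop / sqrt(2),
    sd2 = sqrt(2 * sdnn^2 - 0.5 * sdsd_pop^2))
}
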