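test_that("median_filter removes spikes, keeps boundaries and missing samples", {
  expect_equal(unclass(median_filter(const_series(20), 3)), rep(500, 20))

  x <- beat_series(c(500, 500, 1000, 500, 500))
  expect_equal(unclass(median_filter(x, 3)), rep(500, 5))

  expect_error(median_filter(const_series(10), 4), "odd")

  # windows touching a missing value, and the NA itself, pass through
  y <- c(500, 520, NA, 480, 500, 1000, 500, 510)
  out <- unclass(median_filter(beat_series(y), 3))
  expect_equal(out[1:4], y[1:4])
  expect_equal(out[6], 500) # spike with clean window is filtered
  expect_equal(out[8], y[8]) # boundary untouched

  # idempotent on its own output on spike-free series
  set.seed(5)
  z <- rep(600, 40) + rnorm(40, 0, 5)
  once <- median_filter(beat_series(z), 3)
  twice <- median_filter(once, 3)
  expect_equal(unclass(twice), unclass(median_filter(once, 3)))
})

test_that("threshold_cubic replaces outliers by a local spline and nothing else", {
  expect_equal(unclass(threshold_cubic(const_series(20))), rep(500, 20))

  set.seed(8)
  x <- rep(500, 40) + rnorm(40, 0, 3)
  x[20] <- 1000
  out <- unclass(threshold_cubic(beat_series(x)))
  expect_lt(abs(out[20] - 500), 15) # spike pulled back to the local level
  expect_equal(out[-20], x[-20]) # below-threshold samples untouched

  # degenerate (zero-MAD) window falls back to the absolute rule
  y <- rep(500, 30)
  y[15] <- 700 # 200 ms < 300 ms fallback: kept
  expect_equal(unclass(threshold_cubic(beat_series(y))), y)
  y[15] <- 900 # 400 ms > fallback: replaced
  expect_equal(unclass(threshold_cubic(beat_series(y)))[15], 500)
})

test_that("threshold_cubic leaves missing samples and long flagged runs unfilled", {
  x <- rep(500, 40)
  x[15:21] <- NA # a 7-sample hole stays a hole
  out <- threshold_cubic(beat_series(x))
  expect_equal(detect_miss(out)$width, 7)

  set.seed(9)
  z <- rep(500, 60) + rnorm(60, 0, 2)
  z[25:32] <- 1400 # flagged run wider than half the window: left as-is
  out2 <- unclass(threshold_cubic(beat_series(z), window = 11))
  expect_equal(out2[25:32], z[25:32])
})

test_that("cubic_spline_fill is exact on polynomials and rejects boundary gaps", {
  # constant and linear
  x <- rep(500, 30); x[12:14] <- NA
  expect_equal(unclass(cubic_spline_fill(x)), rep(500, 30))

  i <- 1:40
  lin <- 400 + 5 * i
  lin[20:24] <- NA
  expect_equal(unclass(cubic_spline_fill(lin)), 400 + 5 * i, tolerance = 1e-9)

  # full cubic polynomial
  cub <- 600 + 2 * i - 0.15 * i^2 + 0.004 * i^3
  truth <- cub
  cub[18:20] <- NA
  expect_equal(unclass(cubic_spline_fill(cub)), truth, tolerance = 1e-8)

  bad <- c(NA, NA, rep(500, 20))
  expect_error(cubic_spline_fill(bad), "no left context")
  bad2 <- c(rep(500, 20), NA)
  expect_error(cubic_spline_fill(bad2), "no right context")
})
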