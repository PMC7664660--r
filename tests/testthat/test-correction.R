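test_that("surrounding_stats combines windows and falls back one-sided", {
  st <- surrounding_stats(c(rep(500, 5), 1000, rep(500, 5)), loc = 6,
                          span_beats_per_side = 4)
  expect_equal(st$mean_ms, 500)
  expect_equal(st$sd_before_ms, 0)
  expect_equal(st$sd_after_ms, 0)

  st2 <- surrounding_stats(c(800, 810, 1600, 790, 805), loc = 3,
                           span_beats_per_side = 2)
  expect_equal(st2$mean_ms, 801.25)
  expect_equal(st2$sd_before_ms, 7.0711, tolerance = 1e-4)
  expect_equal(st2$sd_after_ms, 10.6066, tolerance = 1e-4)

  # all-missing after side borrows the before side's SD
  st3 <- surrounding_stats(c(500, 510, 490, 505, 1000, NA, NA, NA), loc = 5,
                           span_beats_per_side = 4)
  expect_equal(st3$sd_after_ms, st3$sd_before_ms)
  expect_equal(st3$span_used[["after"]], 0)

  expect_error(surrounding_stats(c(NA, NA, 1000, NA, NA), loc = 3,
                                 span_beats_per_side = 2),
               "context")
})

test_that("correct_peaks accounts for length and leaves clean series alone", {
  rr <- const_series(40)
  res <- correct_peaks(rr, seed = 1)
  expect_identical(unclass(res$series), unclass(rr))
  expect_identical(res$total_new, 0L)

  x <- beat_series(c(rep(500, 10), 1000, rep(500, 10)))
  res2 <- correct_peaks(x, seed = 1)
  expect_equal(length(unclass(res2$series)), 21 + res2$total_new)
  expect_identical(res2$total_new, 1L)
  # zero-variance context: draws collapse to the mean exactly
  expect_equal(unclass(res2$series), rep(500, 22))
  expect_equal(sum(unclass(res2$series)), sum(unclass(x)))
  expect_equal(res2$edits$kind, "replaced")
})

test_that("peaks above max_multiple become gaps for the gap filler", {
  x <- beat_series(c(rep(500, 10), 2000, rep(500, 10)))
  res <- correct_peaks(x, seed = 1)
  expect_equal(res$edits$kind, "converted_to_gap")
  expect_identical(res$total_new, 3L)
  out <- unclass(res$series)
  expect_equal(length(out), 24)
  expect_equal(which(is.na(out)), 11:14)
  expect_equal(detect_miss(res$series)$width, 4)
})

test_that("rescale conserves cumulative time exactly per corrected peak", {
  set.seed(11)
  x <- rep(520, 80) + rnorm(80, 0, 6)
  x[30] <- 2.1 * 520
  res <- correct_peaks(beat_series(x), seed = 5, rescale = TRUE)
  expect_equal(sum(unclass(res$series)), sum(x), tolerance = 1e-12)
  # without rescale the draws follow the local level instead
  res2 <- correct_peaks(beat_series(x), seed = 5, rescale = FALSE)
  vals <- res2$edits$values[[1]]
  expect_equal(length(vals), 2)
  expect_true(all(abs(vals - 520) < 40))
})

test_that("correct_peaks is seed-reproducible and idempotent", {
  set.seed(3)
  x <- rep(500, 70) + rnorm(70, 0, 4)
  x[c(20, 45)] <- c(1010, 1530)
  rr <- beat_series(x)
  a <- correct_peaks(rr, seed = 9)
  b <- correct_peaks(rr, seed = 9)
  expect_identical(unclass(a$series), unclass(b$series))

  # second pass with the same parameters detects nothing further
  again <- correct_peaks(a$series, seed = 10)
  expect_identical(unclass(again$series), unclass(a$series))
  expect_identical(again$total_new, 0L)
  expect_equal(nrow(detect_peaks(a$series)), 0)
})

test_that("corrective_scale_factor is the clamped bpm ratio", {
  expect_equal(corrective_scale_factor(120, 120), 1)
  expect_equal(corrective_scale_factor(120, 150), 0.8)
  expect_equal(corrective_scale_factor(150, 60), 2) # raw 2.5, clamped
  expect_equal(corrective_scale_factor(60, 150), 0.5) # raw 0.4, clamped
  expect_error(corrective_scale_factor(0, 100), "> 0")
})

test_that("fill_gaps restores length, removes all gaps and honours zero variance", {
  x <- rep(500, 60)
  x[30:32] <- NA
  hr <- hr_trace(rep(120, 30), dt = 1)
  res <- fill_gaps(beat_series(x), hr, seed = 2)
  out <- unclass(res$series)
  expect_equal(length(out), 60)
  expect_equal(sum(is.na(out)), 0)
  expect_equal(nrow(detect_miss(res$series)), 0)
  # constant context, constant HR: deterministic fill at the context mean
  expect_equal(out[30:32], rep(500, 3))
  expect_identical(res$total_new, 0L)
})

test_that("fill_gaps interpolates between context means with factor 1 under linear HR", {
  # two constant plateaus around the gap; heart rate exactly linear in time
  x <- c(rep(500, 30), rep(NA, 5), rep(530, 30))
  dur <- ceiling((30 * 500 + 5 * 515 + 30 * 530) / 1000) + 2
  hr <- linear_hr(118, 112, dur)
  res <- fill_gaps(beat_series(x), hr, seed = 99)
  filled <- unclass(res$series)[31:35]
  d <- (1:5) / 6
  expect_equal(filled, (1 - d) * 500 + d * 530, tolerance = 1e-9)

  # HR dipping below the linear expectation strictly inside the gap
  # (gap spans ~15.0-17.6 s) lengthens the mid-gap beats
  bpm <- hr$bpm
  bpm[17] <- bpm[17] - 8 # the sample at t = 16 s
  res2 <- fill_gaps(beat_series(x), hr_trace(bpm, dt = 1), seed = 99)
  filled2 <- unclass(res2$series)[31:35]
  expect_true(all(filled2[2:3] > filled[2:3]))
})

test_that("fill_gaps handles boundary gaps one-sided and rejects short traces", {
  x <- c(rep(NA, 3), rep(500, 40))
  hr <- hr_trace(rep(120, 25), dt = 1)
  res <- fill_gaps(beat_series(x), hr, seed = 1)
  expect_equal(unclass(res$series)[1:3], rep(500, 3))

  long <- beat_series(rep(500, 200)) # 100 s of beats
  expect_error(fill_gaps(long, hr_trace(rep(120, 10), dt = 1)), "shorter")
})

test_that("both correction algorithms are deterministic at zero context variance", {
  x <- c(rep(500, 12), 1000, rep(500, 12))
  a <- correct_peaks(beat_series(x), seed = 1)
  b <- correct_peaks(beat_series(x), seed = 12345)
  expect_identical(unclass(a$series), unclass(b$series))

  y <- rep(500, 50)
  y[20:24] <- NA
  hr <- hr_trace(rep(120, 25), dt = 1)
  fa <- fill_gaps(beat_series(y), hr, seed = 1)
  fb <- fill_gaps(beat_series(y), hr, seed = 54321)
  expect_identical(unclass(fa$series), unclass(fb$series))
})
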