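test_that("read_rr parses durations, missing markers and rejects bad rows", {
  rr <- read_rr("500\n510\nNaN\n505")
  expect_s3_class(rr, "beat_series")
  expect_equal(unclass(rr), c(500, 510, NA, 505))
  expect_equal(n_missing(rr), 1)

  # empty lines are missing markers too; a header is skipped
  expect_equal(unclass(read_rr("rr_ms\n500\n\n505")), c(500, NA, 505))

  expect_error(read_rr(""), "empty series")
  expect_error(read_rr("500\n-10"), "line 2")
  expect_error(read_rr("500\n6000"), "line 2")
  expect_error(read_rr("500\nabc\n510"), "line 2")
})

test_that("write_rr round-trips token sequences up to missing canonicalization", {
  txt <- "500\n510.5\nNaN\n\n505"
  rr <- read_rr(txt)
  lines <- write_rr(rr)
  expect_equal(lines, c("500", "510.5", "NaN", "NaN", "505"))
  expect_equal(unclass(read_rr(paste(lines, collapse = "\n"))), unclass(rr))

  path <- withr::local_tempfile(fileext = ".txt")
  write_rr(rr, path)
  expect_equal(unclass(read_rr(path)), unclass(rr))
})

test_that("read_hr parses both CSV layouts and enforces uniform spacing", {
  hr <- read_hr("time_s,hr_bpm\n0,120\n1,120")
  expect_equal(hr$bpm, c(120, 120))
  expect_equal(hr$dt, 1)
  expect_equal(hr_duration_s(hr), 2)

  hr2 <- read_hr("hr_bpm\n100\n110\n120", dt = 0.5)
  expect_equal(hr2$dt, 0.5)

  expect_error(read_hr("time_s,hr_bpm\n0,120\n1,121\n2.5,122"), "non-uniform")
  expect_error(read_hr("hr_bpm\n300"), "validation")
  expect_error(read_hr("hr_bpm\n15"), "validation")
})

test_that("check_alignment reports the exact signed mismatch", {
  rr <- const_series(120, 500) # 60 s of beats
  hr <- hr_trace(rep(120, 60), dt = 1) # 60 s trace
  rep_ <- check_alignment(rr, hr)
  expect_identical(rep_$mismatch_ms, 0)

  rr2 <- const_series(120, 503.3)
  rep2 <- check_alignment(rr2, hr)
  expect_equal(rep2$mismatch_ms, 120 * 503.3 - 60000)

  # missing beats do not contribute to the sum but are counted
  x <- rep(500, 123)
  x[c(5, 6, 100)] <- NA
  rep3 <- check_alignment(beat_series(x), hr)
  expect_equal(rep3$rr_total_ms, 120 * 500)
  expect_equal(rep3$missing_count, 3)

  expect_warning(check_alignment(const_series(130, 500), hr), "misalignment")
})

test_that("alignment mismatch is invariant under appending matched beat/trace pairs", {
  rr <- c(rep(500, 120), 480.5)
  hr <- hr_trace(rep(120, 60), dt = 1)
  base <- check_alignment(beat_series(rr), hr)$mismatch_ms
  for (d in c(1000, 2000, 3000)) {
    rr <- c(rr, d)
    hr <- hr_trace(c(hr$bpm, rep(100, d / 1000)), dt = 1)
    # each appended pair adds d ms of beats and d ms of trace
    expect_equal(check_alignment(beat_series(rr), hr)$mismatch_ms, base)
  }
})

test_that("beat_time accumulates durations and substitutes missing beats locally", {
  rr <- const_series(10, 500)
  expect_identical(beat_time(rr, 1), 0)
  expect_equal(beat_time(rr, 5), 2000)
  expect_equal(beat_time(rr, 11), 5000)
  expect_error(beat_time(rr, 12), "out of range")
  expect_error(beat_time(rr, 0), "out of range")

  expect_equal(beat_time(beat_series(c(500, NA, 500)), 4), 1500)
  # asymmetric neighbours: estimate is their mean
  expect_equal(beat_time(beat_series(c(400, NA, 600)), 4), 1500)

  # strictly increasing in index on gap-free series
  x <- beat_series(runif(30, 400, 900))
  times <- vapply(1:31, function(i) beat_time(x, i), numeric(1))
  expect_true(all(diff(times) > 0))
})

test_that("hr_at_time interpolates linearly and clamps beyond the trace", {
  hr <- hr_trace(c(100, 110), dt = 1)
  expect_equal(hr_at_time(hr, 500), 105)
  expect_equal(hr_at_time(hr, 0), 100)
  expect_equal(hr_at_time(hr, 11000), 110) # past the end: last value
  expect_equal(hr_at_time(hr, 700, method = "nearest"), 110)

  const <- hr_trace(rep(120, 30), dt = 1)
  expect_equal(hr_at_time(const, 12345.6), 120)
})
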