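test_that("recording enforces channel consistency", {
  rec <- recording(sin(1:2500), rep(0, 250), rep(0, 250), rep(1, 250))
  expect_equal(duration(rec), 10)
  expect_equal(rec$fs_ecg, 250)
  # mismatched durations beyond one accelerometer sample period
  expect_error(recording(sin(1:2500), rep(0, 100), rep(0, 100), rep(1, 100)),
               "disagree")
  # unequal accelerometer components
  expect_error(recording(sin(1:2500), rep(0, 250), rep(0, 249), rep(1, 250)),
               "equal length")
  expect_error(recording(numeric(0), 1, 1, 1), "non-empty")
})

test_that("CSV recording round trip is lossless", {
  set.seed(1)
  rec <- recording(rnorm(2500), rnorm(250), rnorm(250), 1 + rnorm(250),
                   id = "t")
  # single-file layout with sparse accelerometer rows
  f <- tempfile(fileext = ".csv")
  save_recording(rec, f)
  r2 <- load_recording(f)
  expect_equal(r2$ecg, rec$ecg, tolerance = 1e-9)
  expect_equal(r2$acc_z, rec$acc_z, tolerance = 1e-9)
  expect_equal(r2$fs_ecg, 250)
  expect_equal(r2$fs_acc, 25)
  # sibling-file layout
  d <- tempfile()
  save_recording(rec, d)
  r3 <- load_recording(d)
  expect_equal(r3$ecg, rec$ecg, tolerance = 1e-9)
  expect_equal(r3$acc_x, rec$acc_x, tolerance = 1e-9)
})

test_that("CSV reader rejects malformed files", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = (0:99) / 250, ecg = rnorm(100),
                              acc_x = NA, acc_y = NA), f, row.names = FALSE)
  expect_error(load_recording(f), "acc_z")
  expect_error(load_recording(tempfile(fileext = ".csv")), "not found")
})

test_that("WFDB round trip is exact to ADC quantization", {
  set.seed(2)
  rec <- recording(rnorm(1000), rnorm(100), rnorm(100), 1 + rnorm(100))
  base <- file.path(tempfile(), "rec")
  save_recording(rec, base, format = "wfdb")
  r2 <- load_recording(base, format = "wfdb")
  expect_equal(r2$fs_ecg, 250)
  expect_equal(r2$fs_acc, 25)
  # gain 1000 => half-step 5e-4
  expect_lt(max(abs(r2$ecg - rec$ecg)), 5.1e-4)
  expect_lt(max(abs(r2$acc_y - rec$acc_y)), 5.1e-4)
})

test_that("interval sets normalize, convert to seconds and round trip", {
  iv <- interval_set(c(30, 10), c(40, 20), fs = 250)
  expect_equal(iv$intervals[, "start"], c(10L, 30L))
  # index/fs arithmetic on write
  f <- tempfile(fileext = ".csv")
  save_intervals(interval_set(c(10, 30), c(20, 40), 250, "qrs"), f)
  d <- utils::read.csv(f)
  expect_equal(d$start_seconds, c(0.04, 0.12))
  r <- load_intervals(f)
  expect_identical(r$intervals, interval_set(c(10, 30), c(20, 40), 250)$intervals)
  expect_equal(r$fs, 250)
  expect_equal(r$label, "qrs")
  # empty set round trip
  f2 <- tempfile(fileext = ".csv")
  save_intervals(interval_set(integer(0), integer(0), 250, "motion"), f2)
  e <- load_intervals(f2, fs = 250, label = "motion")
  expect_equal(length(e), 0)
  # overlapping intervals merge on construction
  m <- interval_set(c(0, 5), c(10, 20), 250)
  expect_identical(m$intervals, interval_set(0, 20, 250)$intervals)
  expect_error(interval_set(5, 5, 250), "start < end")
  expect_error(interval_set(-1, 5, 250), "negative")
})

test_that("interval mask algebra partitions the record", {
  iv <- interval_set(c(10, 50), c(20, 60), fs = 250, label = "motion")
  m <- intervals_mask(iv, 100)
  expect_equal(sum(m), 20)
  comp <- intervals_complement(iv, 100)
  expect_equal(sum(intervals_mask(comp, 100) & m), 0)
  expect_true(all(intervals_mask(comp, 100) | m))
  expect_equal(intervals_jaccard(iv, iv, 100), 1)
  expect_equal(
    intervals_jaccard(iv, interval_set(10, 20, 250), 100),
    10 / 20
  )
  # dilation merges grown neighbours
  d <- intervals_dilate(iv, pad_s = 0.06, n = 100) # 15 samples each side
  expect_equal(nrow(d$intervals), 1)
})
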