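test_that("second derivative is the central second difference", {
  k <- 0:19
  d <- second_derivative(k^2)
  expect_equal(d[2:19], rep(2, 18))
  expect_equal(second_derivative(3 * k + 1)[2:19], rep(0, 18))
  imp <- numeric(21)
  imp[11] <- 1
  d2 <- second_derivative(imp)
  expect_equal(d2[10:12], c(1, -2, 1))
  expect_error(second_derivative(1:2), "3 samples")
})

test_that("frame energy sums squares over shifted windows", {
  fe <- frame_energy(rep(1, 8), fs = 250, win_ms = 32, shift_ms = 16)
  expect_equal(fe$energies, 8)
  expect_equal(frame_energy(numeric(20), 250)$energies, rep(0, 4))
  # win 8, shift 4 on 1..12 -> frames [1..8] and [5..12]
  fe2 <- frame_energy(1:12, fs = 1000, win_ms = 8, shift_ms = 4)
  expect_equal(fe2$energies, c(sum((1:8)^2), sum((5:12)^2)))
  expect_equal(fe2$energies, c(204, 620))
  expect_error(frame_energy(1:4, 250), "shorter than one window")
})

test_that("threshold is the midpoint of the median energy extrema", {
  mk <- function(e) structure(
    list(energies = e, frame_len = 8, frame_shift = 4, fs = 250,
         n = length(e) * 4 + 4),
    class = "swmar_energy"
  )
  # all energies equal c -> threshold c
  expect_equal(estimate_qrs_threshold(mk(rep(3, 200)))$threshold, 3)
  # alternating 0/10 in every interval -> LM 10, Lm 0, threshold 5
  th <- estimate_qrs_threshold(mk(rep(c(0, 10), 100)))
  expect_equal(th$lm_median, 10)
  expect_equal(th$lm_min_median, 0)
  expect_equal(th$threshold, 5)
  expect_error(estimate_qrs_threshold(mk(rep(1, 5))), "full")
})

test_that("threshold separates QRS frames from baseline on synthetic ECG", {
  e1 <- generate_ecg(60, seed = 1)
  bp <- bandpass_ecg(e1$ecg)
  fe <- frame_energy(second_derivative(bp), 250)
  th <- estimate_qrs_threshold(fe)
  qm <- intervals_mask(e1$qrs_truth, length(bp))
  starts <- (seq_along(fe$energies) - 1) * fe$frame_shift
  # every true complex contains a frame above threshold
  per_complex <- vapply(seq_len(nrow(e1$qrs_truth$intervals)), function(i) {
    iv <- e1$qrs_truth$intervals[i, ]
    max(fe$energies[starts >= iv[1] & starts + fe$frame_len <= iv[2]])
  }, numeric(1))
  expect_true(all(per_complex > th$threshold))
  # threshold clears the bulk of the baseline energies
  baseline <- vapply(starts, function(s) {
    !any(qm[(s + 1):min(s + fe$frame_len, length(qm))])
  }, logical(1))
  expect_gt(th$threshold,
            stats::quantile(fe$energies[baseline], 0.95))
})

test_that("detector finds every beat of a clean regular rhythm", {
  expect_equal(length(detect_qrs(numeric(5000), 250)), 0)
  e <- generate_ecg(60, mean_rr_s = 1.5, rr_jitter = 0, seed = 3)
  det <- detect_qrs(bandpass_ecg(e$ecg), 250)
  expect_true(abs(length(det) - 40) <= 1)
  # each detection contains its true R sample
  m <- qrs_match(det, e$r_peaks, 250, tol_s = 0)
  expect_equal(m$sensitivity, 1)
})

test_that("detection is invariant to amplitude scaling and well-formed", {
  e <- generate_ecg(30, noise_snr_db = 20, seed = 4)
  bp <- bandpass_ecg(e$ecg)
  det <- detect_qrs(bp, 250)
  for (c0 in c(3.7, 1e-3)) {
    expect_identical(detect_qrs(c0 * bp, 250)$intervals, det$intervals)
  }
  iv <- det$intervals
  expect_true(all(diff(iv[, 1]) > 0))
  expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
})

test_that("detector keeps sensitivity and precision at 20 dB SNR", {
  sens <- prec <- gap_ms <- numeric(10)
  for (k in 1:10) {
    e <- generate_ecg(60, mean_rr_s = 1.5, noise_snr_db = 20, seed = k)
    det <- detect_qrs(bandpass_ecg(e$ecg), 250)
    m <- qrs_match(det, e$r_peaks, 250)
    sens[k] <- m$sensitivity
    prec[k] <- m$precision
    gap_ms[k] <- stats::median(vapply(
      e$qrs_truth$intervals[, 1],
      function(a) min(abs(det$intervals[, 1] - a)), numeric(1)
    )) / 250 * 1000
  }
  expect_true(all(sens >= 0.95))
  expect_true(all(prec >= 0.95))
  # onset markers land within the matching tolerance of the true onsets
  expect_lte(stats::median(gap_ms), 75)
})
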