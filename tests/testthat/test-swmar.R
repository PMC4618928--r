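# helper: hand-built threshold table in the level_thresholds() layout
mk_thresholds <- function(level, M, m) {
  out <- data.frame(level = c(seq_len(level), NA_integer_),
                    M = M, m = m, mu1 = NA, sigma1 = NA, mu2 = NA,
                    sigma2 = NA)
  class(out) <- c("swmar_level_thresholds", class(out))
  out
}

test_that("robust statistics follow the median/MAD definition", {
  rs <- robust_stats(c(1, 2, 3, 4, 5))
  expect_equal(rs$mu, 3)
  expect_equal(rs$sigma, 1.4826)
  rc <- robust_stats(rep(7, 10))
  expect_equal(rc$mu, 7)
  expect_equal(rc$sigma, 0)
  expect_error(robust_stats(numeric(0)), "empty")
  # brute-force oracle
  set.seed(20)
  x <- rcauchy(301)
  rs2 <- robust_stats(x)
  o <- brute_robust(x)
  expect_equal(rs2$mu, o$mu, tolerance = 1e-12)
  expect_equal(rs2$sigma, o$sigma, tolerance = 1e-12)
})

test_that("scaled MAD estimates the SD consistently for Gaussian data", {
  set.seed(2)
  rs <- robust_stats(rnorm(1e4))
  expect_lt(abs(rs$sigma - 1), 0.05)
})

test_that("gating zeroes artifact-free segments at the listed levels", {
  set.seed(21)
  x <- rnorm(500)
  cf <- swt_decompose(x, 5)
  none <- interval_set(integer(0), integer(0), 250, "motion")
  g0 <- zero_artifact_free(cf, none)
  for (j in 1:3) expect_true(all(g0$details[[j]] == 0))
  expect_identical(g0$details[[4]], cf$details[[4]])
  all_m <- interval_set(0, 500, 250, "motion")
  g1 <- zero_artifact_free(cf, all_m)
  for (j in 1:3) {
    expect_identical(g1$details[[j]][1:500], cf$details[[j]][1:500])
  }
  one <- interval_set(100, 200, 250, "motion")
  g2 <- zero_artifact_free(cf, one)
  expect_true(all(g2$details[[1]][c(1:100, 201:500)] == 0))
  expect_identical(g2$details[[1]][101:200], cf$details[[1]][101:200])
  expect_error(zero_artifact_free(cf, one, levels = 6), "within")
})

test_that("frame extrema are per-second maxima and minima", {
  fx <- frame_extrema(0:499, fs = 250)
  expect_equal(fx$maxima, c(249, 499))
  expect_equal(fx$minima, c(0, 250))
  fc <- frame_extrema(rep(2, 750), fs = 250)
  expect_equal(fc$maxima, rep(2, 3))
  expect_equal(fc$minima, rep(2, 3))
  # trailing partial frame dropped
  expect_length(frame_extrema(rnorm(700), fs = 250)$maxima, 2)
  expect_error(frame_extrema(rnorm(100), fs = 250), "shorter")
  # brute-force per-frame oracle
  set.seed(22)
  x <- rnorm(1000)
  fx2 <- frame_extrema(x, fs = 250)
  for (i in 1:4) {
    seg <- x[((i - 1) * 250 + 1):(i * 250)]
    expect_equal(fx2$maxima[i], max(seg))
    expect_equal(fx2$minima[i], min(seg))
  }
})

test_that("level thresholds implement the robust bound formulas", {
  # every frame has max 4 and min -2 -> M = 4, m = -2 with zero spread
  frame <- c(4, -2, rep(0, 248))
  series <- rep(frame, 3)
  cf <- structure(
    list(details = list(series), approximation = series, level = 1,
         wavelet = "haar", original_length = 750, padded_length = 750),
    class = "swmar_swt"
  )
  th <- level_thresholds(cf, fs = 250)
  expect_equal(th$M, rep(4, 2))
  expect_equal(th$m, rep(-2, 2))
  # frame maxima 1..5 -> M = median + 1.4826 * MAD = 4.4826
  series2 <- as.vector(vapply(1:5, function(k) c(rep(0, 249), k),
                              numeric(250)))
  cf2 <- structure(
    list(details = list(series2), approximation = series2, level = 1,
         wavelet = "haar", original_length = 1250, padded_length = 1250),
    class = "swmar_swt"
  )
  th2 <- level_thresholds(cf2, fs = 250)
  expect_equal(th2$M[1], 3 + 1.4826)
})

test_that("artifact estimation keeps only beyond-threshold coefficients", {
  n <- 256
  zero <- swt_decompose(numeric(n), 5)
  all_m <- interval_set(0, n, 250, "motion")
  wide <- mk_thresholds(5, M = 10, m = -10)
  # nothing beyond thresholds -> zero artifact
  set.seed(23)
  cf <- swt_decompose(0.1 * rnorm(n), 5)
  a0 <- estimate_artifact(cf, wide, all_m)
  expect_equal(a0$artifact_signal, rep(0, n))
  # a single spiking coefficient in full mode reconstructs alone
  spike <- zero
  spike$details[[1]][100] <- 5
  tight <- mk_thresholds(5, M = 1, m = -1)
  a1 <- estimate_artifact(spike, tight, all_m, mode = "full")
  manual <- zero
  manual$details[[1]][100] <- 5
  expect_equal(a1$artifact_signal, swt_reconstruct(manual))
  # exceedance mode subtracts the bound first
  a2 <- estimate_artifact(spike, tight, all_m, mode = "exceedance")
  manual2 <- zero
  manual2$details[[1]][100] <- 4
  expect_equal(a2$artifact_signal, swt_reconstruct(manual2))
})

test_that("no motion means the cleaned ECG is the band-passed ECG exactly", {
  set.seed(24)
  e <- generate_ecg(20, seed = 24)
  rec <- recording(e$ecg, rep(0.3, 500), rep(0.2, 500), rep(0.9, 500))
  res <- remove_artifacts(rec)
  expect_equal(length(res$motion), 0)
  expect_identical(res$cleaned, res$ecg_filt)
  expect_true(all(res$artifact$artifact_signal == 0))
})

test_that("cleaning is local: untouched outside motion intervals", {
  s <- generate_record(60, n_bursts = 2, burst_len_s = 5,
                       target_rms_ratio = 4, seed = 25)
  res <- remove_artifacts(s$recording)
  outside <- !intervals_mask(res$motion, length(res$cleaned))
  expect_identical(res$cleaned[outside], res$ecg_filt[outside])
})

test_that("enlarging motion can only grow the artifact support", {
  s <- generate_record(60, n_bursts = 2, burst_len_s = 5,
                       target_rms_ratio = 4, seed = 26)
  pp <- preprocess_recording(s$recording)
  cf <- swt_decompose(pp$ecg)
  motion_small <- detect_motion(pp$acc, pp$fs)
  motion_big <- intervals_dilate(motion_small, 1, n = length(pp$ecg))
  th <- level_thresholds(zero_artifact_free(cf, motion_small), pp$fs)
  a_small <- estimate_artifact(cf, th, motion_small)$artifact_signal
  a_big <- estimate_artifact(cf, th, motion_big)$artifact_signal
  expect_true(all(which(a_small != 0) %in% which(a_big != 0)))
})

test_that("the pipeline is equivariant under amplitude scaling", {
  s <- generate_record(60, n_bursts = 2, burst_len_s = 5,
                       target_rms_ratio = 4, seed = 27)
  res1 <- remove_artifacts(s$recording)
  rec2 <- s$recording
  rec2$ecg <- 3.5 * rec2$ecg
  res2 <- remove_artifacts(rec2)
  # tolerance reflects rounding drift in the recursive IIR filter state
  expect_equal(res2$cleaned, 3.5 * res1$cleaned, tolerance = 1e-6)
  expect_equal(res2$artifact$thresholds$M,
               3.5 * res1$artifact$thresholds$M, tolerance = 1e-6)
})

test_that("burst coefficients exceed bounds and QRS spans are protected", {
  s <- generate_record(120, n_bursts = 6, burst_len_s = 5,
                       target_rms_ratio = 4.5, seed = 1)
  pp <- preprocess_recording(s$recording)
  cf <- swt_decompose(pp$ecg)
  motion <- detect_motion(pp$acc, pp$fs)
  gated <- zero_artifact_free(cf, motion)
  th <- level_thresholds(gated, pp$fs)
  n <- length(pp$ecg)
  burst <- intervals_mask(s$burst_truth, round(n * s$burst_truth$fs / 250))
  burst250 <- rep(burst, each = 10)[seq_len(n)]
  for (j in 1:3) {
    d <- gated$details[[j]][seq_len(n)]
    beyond <- d > th$M[j] | d < th$m[j]
    # corrupted segments push coefficients out of the robust bounds
    expect_gt(mean(beyond[burst250]), 0.25)
  }
  # QRS protection removes detected spans from the artifact coefficients
  qrs <- detect_qrs(pp$ecg, pp$fs)
  art <- estimate_artifact(gated, th, motion, qrs)
  qmask <- intervals_mask(qrs, n)
  for (j in 1:3) {
    expect_true(all(art$gated_coeffs$details[[j]][seq_len(n)][qmask] == 0))
  }
})

test_that("cleaning reduces error and artifact burden on moderate records", {
  for (sd0 in c(21, 22, 23)) {
    s <- generate_record(120, n_bursts = 6, burst_len_s = 5,
                         target_rms_ratio = 4.5, seed = sd0)
    res <- remove_artifacts(s$recording)
    expect_lt(rmse(res$cleaned, s$clean_ecg),
              rmse(s$recording$ecg, s$clean_ecg))
    raw <- ma_fraction(s$artifact, s$clean_ecg, 250)
    cl <- ma_fraction(res$cleaned - s$clean_ecg, s$clean_ecg, 250)
    expect_gt(100 * (raw - cl) / raw, 40)
    # the estimate tracks the band-limited injected artifact
    mm <- intervals_mask(res$motion, length(res$cleaned))
    expect_gt(stats::cor(res$artifact$artifact_signal[mm],
                         bandpass_ecg(s$artifact)[mm]), 0.8)
  }
})

test_that("a second application does not degrade the result", {
  s <- generate_record(120, n_bursts = 7, burst_len_s = 5,
                       target_rms_ratio = 4.5, seed = 11)
  res1 <- remove_artifacts(s$recording)
  rec2 <- s$recording
  rec2$ecg <- res1$cleaned
  res2 <- remove_artifacts(rec2)
  expect_lt(rmse(res2$cleaned, s$clean_ecg),
            1.05 * rmse(res1$cleaned, s$clean_ecg))
})
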