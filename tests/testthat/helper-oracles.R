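# Independent oracles and small utilities shared across tests.

# Brute-force median/MAD robust location and scale (sort-based, no stats::).
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
brute_robust <- function(x) {
  m <- brute_median(x)
  list(mu = m, sigma = 1.4826 * brute_median(abs(x - m)))
}

# Naive direct-sum stationary wavelet decomposition: for each level the
# filters are applied with explicit loops over taps and circular indexing,
# independent of the package's vectorized implementation.
naive_swt <- function(x, level, h, g) {
  n <- length(x)
  a <- x
  details <- vector("list", level)
  for (j in seq_len(level)) {
    s <- 2^(j - 1)
    anew <- numeric(n)
    d <- numeric(n)
    for (k in seq_len(n)) {
      for (l in seq_along(h)) {
        idx <- ((k - 1 + s * (l - 1)) %% n) + 1
        anew[k] <- anew[k] + h[l] * a[idx]
        d[k] <- d[k] + g[l] * a[idx]
      }
    }
    details[[j]] <- d
    a <- anew
  }
  list(details = details, approximation = a)
}

# Greedy one-to-one matching of detected QRS intervals to true R peaks.
qrs_match <- function(det, r_peaks, fs, tol_s = 0.075) {
  tol <- tol_s * fs
  iv <- det$intervals
  used <- rep(FALSE, nrow(iv))
  tp <- 0
  for (r in r_peaks) {
    hit <- which(!used & iv[, 1] - tol <= r & r < iv[, 2] + tol)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      tp <- tp + 1
    }
  }
  list(
    sensitivity = tp / length(r_peaks),
    precision = if (nrow(iv)) tp / nrow(iv) else NA_real_
  )
}

# Acceleration module of a generate_accel() result, upsampled to 250 Hz.
accel_module_250 <- function(a) {
  acceleration_module(
    upsample_accel(a$acc_x), upsample_accel(a$acc_y),
    upsample_accel(a$acc_z)
  )
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
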