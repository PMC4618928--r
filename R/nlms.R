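#' Normalized LMS adaptive noise cancellation
#'
#' Classic two-input canceller: the filter predicts the interference in
#' the primary input from the last `order` reference samples and subtracts
#' its prediction. Per sample `n`: `y(n) = w' u(n)`,
#' `z(n) = primary(n) - y(n)`,
#' `w <- w + mu / (eps + ||u(n)||^2) * z(n) * u(n)`, with zero-initialized
#' weights. Minimizing the output power leaves the component of the
#' primary that is uncorrelated with the reference (the ECG) untouched, so
#' `z` is the cleaned signal.
#'
#' @param primary corrupted signal (desired + interference).
#' @param reference interference-correlated reference, same length.
#' @param order number of filter taps L (default 32).
#' @param mu adaptation step, in (0, 2); `mu = 0` leaves the filter inert.
#' @param eps regularizer guarding the normalization against a silent
#'   reference.
#' @return List with `cleaned` (the error signal z), `output` (the filter
#'   output y) and `weights` (final taps).
#' @export
nlms_cancel <- function(primary, reference, order = 32, mu = 0.1,
                        eps = 1e-8) {
  n <- length(primary)
  if (length(reference) != n) stop("primary/reference length mismatch")
  if (order < 1) stop("order must be >= 1")
  if (mu < 0 || mu >= 2) stop("mu must lie in [0, 2)")
  if (eps <= 0) stop("eps must be positive")
  w <- numeric(order)
  y <- numeric(n)
  z <- numeric(n)
  # u(n) = reference[n], reference[n-1], ..., reference[n-L+1], zero-padded
  u <- numeric(order)
  for (i in seq_len(n)) {
    u <- c(reference[i], u[-order])
    yi <- sum(w * u)
    zi <- primary[i] - yi
    y[i] <- yi
    z[i] <- zi
    if (mu > 0) w <- w + (mu / (eps + sum(u * u))) * zi * u
  }
  list(cleaned = z, output = y, weights = w)
}

#' NLMS artifact cancellation on a recording
#'
#' Comparator for the wavelet pipeline: band-passes the ECG, builds the
#' acceleration module at the ECG rate and uses its mean-subtracted form
#' as the adaptive filter's reference input (the only artifact-correlated
#' exogenous signal the device records).
#'
#' @param rec a [recording()].
#' @param order,mu,eps see [nlms_cancel()].
#' @param low,high band-pass edges, see [bandpass_ecg()].
#' @return List with `cleaned`, `output`, `weights` (from
#'   [nlms_cancel()]) and `ecg_filt` (the band-passed ECG).
#' @export
nlms_clean_recording <- function(rec, order = 32, mu = 0.1, eps = 1e-8,
                                 low = 0.5, high = 40) {
  pp <- preprocess_recording(rec, low = low, high = high)
  ref <- pp$acc - mean(pp$acc)
  res <- nlms_cancel(pp$ecg, ref, order = order, mu = mu, eps = eps)
  res$ecg_filt <- pp$ecg
  res
}
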