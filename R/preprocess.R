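#' Zero-phase Butterworth band-pass for the ECG
#'
#' Designs an order-`order` Butterworth band-pass (default 0.5-40 Hz, the
#' diagnostic ambulatory ECG band) and applies it forward and backward, so
#' the net filter has zero phase and twice the design order. Transients are
#' suppressed by reflect-padding the signal by `pad_s` seconds (clipped to
#' the signal length) before filtering.
#'
#' @param ecg numeric ECG samples.
#' @param fs sampling rate, Hz; must exceed `2 * high`.
#' @param low,high band edges in Hz.
#' @param order Butterworth design order (effective order is `2 * order`
#'   after the forward-backward pass).
#' @param pad_s reflect-pad length in seconds.
#' @return Filtered series, same length as the input.
#' @export
bandpass_ecg <- function(ecg, fs = 250, low = 0.5, high = 40, order = 4,
                         pad_s = 3) {
  n <- length(ecg)
  if (fs <= 2 * high) stop("fs must exceed twice the upper band edge")
  if (n <= 3 * 2 * order) {
    stop("signal too short to band-pass (need > ", 3 * 2 * order, " samples)")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  p <- min(round(pad_s * fs), n - 1)
  x <- c(rev(ecg[2:(p + 1)]), ecg, rev(ecg[(n - p):(n - 1)]))
  y <- signal::filter(bf, x)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(p + 1):(p + n)]
}

#' Linear-interpolation upsampling of an accelerometer component
#'
#' Upsamples by the integer ratio `fs_out / fs_in` with straight-line
#' interpolation between the original samples; the original samples are
#' preserved exactly at indices `k * r`. The interpolated series has
#' `(n - 1) * r + 1` samples and is right-padded with its edge value to
#' `n * r`, so durations in seconds are preserved.
#'
#' @param x numeric component at `fs_in` Hz.
#' @param fs_in,fs_out input and output rates, Hz; `fs_out` must be an
#'   integer multiple of `fs_in`.
#' @return Numeric series of length `length(x) * r`.
#' @export
upsample_accel <- function(x, fs_in = 25, fs_out = 250) {
  r <- fs_out / fs_in
  if (abs(r - round(r)) > 1e-9) {
    stop("fs_out must be an integer multiple of fs_in")
  }
  r <- round(r)
  n <- length(x)
  if (n < 1) stop("empty series")
  if (n == 1) return(rep(x, r))
  xi <- stats::approx(seq_len(n), x, xout = seq(1, n, by = 1 / r))$y
  c(xi, rep(xi[length(xi)], n * r - length(xi)))
}

#' Acceleration module (Euclidean norm of the triaxial components)
#'
#' Pointwise root-sum-of-squares of the three accelerometer components,
#' giving the orientation-free magnitude of acceleration used by motion
#' detection.
#'
#' @param acc_x,acc_y,acc_z numeric vectors of equal length.
#' @return Nonnegative series of the same length.
#' @examples
#' acceleration_module(3, 4, 0) # 5
#' @export
acceleration_module <- function(acc_x, acc_y, acc_z) {
  n <- length(acc_x)
  if (length(acc_y) != n || length(acc_z) != n) {
    stop("component length mismatch")
  }
  sqrt(acc_x^2 + acc_y^2 + acc_z^2)
}

#' Preprocess a recording
#'
#' Band-limits the ECG, upsamples the accelerometer components to the ECG
#' rate and combines them into the acceleration module, aligned sample to
#' sample with the filtered ECG (the module is trimmed or edge-padded by at
#' most one accelerometer sample period to match the ECG length).
#'
#' @param rec a [recording()].
#' @param low,high,order,pad_s band-pass parameters, see [bandpass_ecg()].
#' @return List with `ecg` (filtered, at `fs_ecg`), `acc` (acceleration
#'   module at `fs_ecg`) and `fs` (the ECG rate).
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 40, order = 4,
                                 pad_s = 3) {
  stopifnot(inherits(rec, "swmar_recording"))
  ecg <- bandpass_ecg(rec$ecg, rec$fs_ecg, low = low, high = high,
                      order = order, pad_s = pad_s)
  ax <- upsample_accel(rec$acc_x, rec$fs_acc, rec$fs_ecg)
  ay <- upsample_accel(rec$acc_y, rec$fs_acc, rec$fs_ecg)
  az <- upsample_accel(rec$acc_z, rec$fs_acc, rec$fs_ecg)
  acc <- acceleration_module(ax, ay, az)
  n <- length(ecg)
  if (length(acc) >= n) {
    acc <- acc[seq_len(n)]
  } else {
    acc <- c(acc, rep(acc[length(acc)], n - length(acc)))
  }
  list(ecg = ecg, acc = acc, fs = rec$fs_ecg)
}
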