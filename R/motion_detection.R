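#' Robust motion threshold on the acceleration module
#'
#' `T = median(x) + 1.4826 * MAD(x)`, where `MAD(x) = median(|x -
#' median(x)|)` and the 1.4826 factor makes the MAD a consistent estimate
#' of the standard deviation for Gaussian data, so the threshold is robust
#' to the heavy-tailed bursts it is meant to flag.
#'
#' @param acc nonnegative acceleration-module samples (or any numeric
#'   series).
#' @return An object of class `swmar_motion_threshold` with fields
#'   `t_value`, `median_acc` and `mad_acc` (the raw, unscaled MAD).
#' @export
motion_threshold <- function(acc) {
  if (length(acc) == 0) stop("empty series")
  med <- stats::median(acc)
  mad_raw <- stats::median(abs(acc - med))
  structure(
    list(t_value = med + 1.4826 * mad_raw, median_acc = med,
         mad_acc = mad_raw),
    class = "swmar_motion_threshold"
  )
}

#' @export
print.swmar_motion_threshold <- function(x, ...) {
  cat(sprintf("<swmar_motion_threshold: T = %.4g (median %.4g, MAD %.4g)>\n",
              x$t_value, x$median_acc, x$mad_acc))
  invisible(x)
}

#' Detect movement segments able to generate ECG artifacts
#'
#' The acceleration module is compared against the robust threshold of
#' [motion_threshold()]; above-threshold samples form candidate
#' intervals. Because `T` sits only one robust standard deviation above
#' the quiet noise floor, isolated noise crossings are expected in any
#' quiet stretch, so detection uses hysteresis: a candidate interval is
#' kept only when it contains at least one strong sample exceeding
#' `median + strong_k * 1.4826 * MAD` (default three robust SDs, the
#' usual robust outlier cut). Kept intervals are then cleaned
#' morphologically — sub-threshold dips shorter than `close_gap_s` are
#' closed and episodes shorter than `min_dur_s` discarded — and each
#' surviving interval is dilated by `pad_s` on both sides
#' (electrode-potential artifacts outlast the mechanical burst) with
#' overlaps merged.
#'
#' With `variant = "raw"` (default) the threshold and the comparison are
#' computed on the module as given; because the median and MAD are
#' equivariant, detection is invariant to a constant offset (the gravity
#' component) and to positive scaling. `variant = "rectified"` first
#' mean-subtracts and rectifies the module; note that when movement
#' occupies a substantial fraction of the record the mean is pulled up by
#' the bursts and the quiet-level deviation approaches the robust
#' threshold, costing specificity.
#'
#' @param acc acceleration-module samples at `fs` Hz.
#' @param fs sampling rate, Hz.
#' @param pad_s dilation pad in seconds.
#' @param strong_k hysteresis seed level in robust SD units.
#' @param close_gap_s sub-threshold gaps shorter than this are closed.
#' @param min_dur_s episodes shorter than this are discarded.
#' @param variant where the median/MAD and the comparison are computed.
#' @return A `swmar_intervals` labelled `"motion"`; the threshold object is
#'   attached as attribute `"threshold"`.
#' @export
detect_motion <- function(acc, fs = 250, pad_s = 0.5, strong_k = 3,
                          close_gap_s = 0.25, min_dur_s = 0.5,
                          variant = c("raw", "rectified")) {
  variant <- match.arg(variant)
  if (length(acc) == 0) stop("empty series")
  z <- if (variant == "rectified") abs(acc - mean(acc)) else acc
  th <- motion_threshold(z)
  raw <- intervals_from_mask(z > th$t_value, fs = fs, label = "motion")
  iv <- raw$intervals
  if (nrow(iv) > 0 && strong_k > 1) {
    t_strong <- th$median_acc + strong_k * 1.4826 * th$mad_acc
    seeded <- vapply(seq_len(nrow(iv)), function(i) {
      any(z[(iv[i, 1] + 1):iv[i, 2]] > t_strong)
    }, logical(1))
    iv <- iv[seeded, , drop = FALSE]
  }
  if (nrow(iv) > 1 && close_gap_s > 0) {
    gap <- round(close_gap_s * fs)
    keep_s <- iv[1, 1]
    ends <- integer(0)
    starts <- integer(0)
    cur_e <- iv[1, 2]
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] - cur_e <= gap) {
        cur_e <- iv[i, 2]
      } else {
        starts <- c(starts, keep_s)
        ends <- c(ends, cur_e)
        keep_s <- iv[i, 1]
        cur_e <- iv[i, 2]
      }
    }
    starts <- c(starts, keep_s)
    ends <- c(ends, cur_e)
    iv <- cbind(starts, ends)
  }
  if (nrow(iv) > 0 && min_dur_s > 0) {
    iv <- iv[iv[, 2] - iv[, 1] >= round(min_dur_s * fs), , drop = FALSE]
  }
  out <- if (nrow(iv) > 0) {
    intervals_dilate(
      interval_set(iv[, 1], iv[, 2], fs = fs, label = "motion",
                   n = length(acc)),
      pad_s, n = length(acc)
    )
  } else {
    interval_set(integer(0), integer(0), fs = fs, label = "motion")
  }
  attr(out, "threshold") <- th
  out
}
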