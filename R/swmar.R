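#' Robust mean and standard deviation
#'
#' `mu = median(x)`, `sigma = 1.4826 * median(|x - median(x)|)`; the scale
#' factor makes the MAD a consistent estimator of the standard deviation
#' under Gaussian data while staying insensitive to the outliers the
#' pipeline is trying to find.
#'
#' @param x numeric vector, non-empty.
#' @return List with `mu` and `sigma`.
#' @examples
#' robust_stats(c(1, 2, 3, 4, 5)) # mu 3, sigma 1.4826
#' @export
robust_stats <- function(x) {
  if (length(x) == 0) stop("empty series")
  mu <- stats::median(x)
  list(mu = mu, sigma = 1.4826 * stats::median(abs(x - mu)))
}

#' Zero wavelet coefficients of artifact-free segments
#'
#' Within the listed detail levels (by default the first three, which carry
#' most of the cardiac information), every coefficient sample lying outside
#' the motion intervals is set to zero; other levels and the approximation
#' are untouched. Samples in the padding region beyond the original signal
#' are treated as artifact-free.
#'
#' @param coeffs a [swt_decompose()] result.
#' @param motion a `swmar_intervals` on the same time base as the signal.
#' @param levels integer detail levels to gate (within `1..coeffs$level`).
#' @return A `swmar_swt` with gated detail levels.
#' @export
zero_artifact_free <- function(coeffs, motion, levels = 1:3) {
  stopifnot(inherits(coeffs, "swmar_swt"), inherits(motion, "swmar_intervals"))
  if (any(levels < 1) || any(levels > coeffs$level)) {
    stop("levels must lie within 1..", coeffs$level)
  }
  mask <- c(intervals_mask(motion, coeffs$original_length),
            rep(FALSE, coeffs$padded_length - coeffs$original_length))
  for (j in levels) {
    d <- coeffs$details[[j]]
    d[!mask] <- 0
    coeffs$details[[j]] <- d
  }
  coeffs
}

#' Per-frame extrema of a coefficient series
#'
#' Maximum and minimum of the series within non-overlapping frames of
#' `frame_s` seconds; a trailing partial frame is dropped.
#'
#' @param coeff numeric series at `fs` Hz.
#' @param fs sampling rate, Hz.
#' @param frame_s frame length in seconds (default 1).
#' @return List with numeric vectors `maxima` and `minima`, one value per
#'   full frame.
#' @export
frame_extrema <- function(coeff, fs, frame_s = 1) {
  w <- round(frame_s * fs)
  if (w < 1) stop("frame must span at least 1 sample")
  nf <- floor(length(coeff) / w)
  if (nf < 1) stop("series shorter than one frame")
  m <- matrix(coeff[seq_len(nf * w)], nrow = w)
  list(maxima = apply(m, 2, max), minima = apply(m, 2, min))
}

#' Per-level robust coefficient thresholds
#'
#' For every detail level (and the final approximation) the per-1 s frame
#' maxima and minima are collected and summarized robustly
#' ([robust_stats()]); the upper and lower bounds are
#' `M_j = mu1_j + sigma1_j` and `m_j = mu2_j - sigma2_j`. Coefficients
#' outside `[m_j, M_j]` are regarded as movement-artifact related.
#'
#' Call this on coefficients already gated by [zero_artifact_free()]; the
#' zero-valued frames at the gated levels then pull the robust statistics
#' toward zero, which is the intended conservative behaviour.
#'
#' @param coeffs a `swmar_swt` (typically gated).
#' @param fs sampling rate of the decomposed signal, Hz.
#' @param frame_s extrema frame length in seconds.
#' @return An object of class `swmar_level_thresholds`: a data frame with
#'   one row per detail level plus one for the approximation (`level` NA),
#'   columns `M`, `m`, `mu1`, `sigma1`, `mu2`, `sigma2`.
#' @export
level_thresholds <- function(coeffs, fs, frame_s = 1) {
  stopifnot(inherits(coeffs, "swmar_swt"))
  one <- function(series, lev) {
    fx <- frame_extrema(series, fs, frame_s)
    s1 <- robust_stats(fx$maxima)
    s2 <- robust_stats(fx$minima)
    data.frame(level = lev, M = s1$mu + s1$sigma, m = s2$mu - s2$sigma,
               mu1 = s1$mu, sigma1 = s1$sigma, mu2 = s2$mu, sigma2 = s2$sigma)
  }
  rows <- lapply(seq_len(coeffs$level), function(j) {
    one(coeffs$details[[j]], j)
  })
  rows <- c(rows, list(one(coeffs$approximation, NA_integer_)))
  out <- do.call(rbind, rows)
  class(out) <- c("swmar_level_thresholds", class(out))
  out
}

#' @export
print.swmar_level_thresholds <- function(x, ...) {
  cat("<swmar_level_thresholds>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Estimate the movement-artifact waveform
#'
#' Builds per-level artifact coefficients from the thresholded
#' decomposition and reconstructs them into a time-domain artifact signal.
#' A coefficient contributes only when it lies beyond its level's bounds
#' (`c > M_j` or `c < m_j`) and inside a motion interval. With
#' `mode = "full"` (default) the whole beyond-threshold coefficient is
#' attributed to the artifact; `mode = "exceedance"` attributes only the
#' excess over the bound (`c - M_j` or `c - m_j`), a gentler variant that
#' keeps the within-band component but leaves a threshold-scale residual
#' behind. Detected QRS spans are protected (excluded) at the first
#' three levels so the estimate does not eat the QRS complexes. The
#' reconstructed artifact is finally gated to the motion intervals in the
#' time domain, so it is identically zero outside them.
#'
#' @param coeffs a gated `swmar_swt` (see [zero_artifact_free()]).
#' @param thresholds a [level_thresholds()] result.
#' @param motion motion intervals (`swmar_intervals`).
#' @param qrs detected QRS intervals, or NULL.
#' @param mode `"full"` or `"exceedance"`.
#' @param qrs_protect exclude QRS spans at levels 1-3 (default TRUE).
#' @param threshold_approx also threshold the approximation sequence
#'   (default TRUE).
#' @return An object of class `swmar_artifact` with fields
#'   `artifact_signal`, `gated_coeffs` (the artifact's coefficients),
#'   `thresholds`, `motion` and `qrs`.
#' @export
estimate_artifact <- function(coeffs, thresholds, motion, qrs = NULL,
                              mode = c("full", "exceedance"),
                              qrs_protect = TRUE, threshold_approx = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(coeffs, "swmar_swt"),
            inherits(thresholds, "swmar_level_thresholds"),
            inherits(motion, "swmar_intervals"))
  n0 <- coeffs$original_length
  np <- coeffs$padded_length
  mmask <- c(intervals_mask(motion, n0), rep(FALSE, np - n0))
  qmask <- if (!is.null(qrs) && qrs_protect) {
    c(intervals_mask(qrs, n0), rep(FALSE, np - n0))
  } else {
    rep(FALSE, np)
  }
  pick <- function(series, M, m, protect) {
    sel <- mmask & (series > M | series < m)
    if (protect) sel <- sel & !qmask
    out <- numeric(length(series))
    if (mode == "full") {
      out[sel] <- series[sel]
    } else {
      hi <- sel & series > M
      lo <- sel & series < m
      out[hi] <- series[hi] - M
      out[lo] <- series[lo] - m
    }
    out
  }
  art <- coeffs
  for (j in seq_len(coeffs$level)) {
    th <- thresholds[which(thresholds$level == j), ]
    if (nrow(th) != 1) stop("no thresholds for level ", j)
    art$details[[j]] <- pick(coeffs$details[[j]], th$M, th$m, j <= 3)
  }
  tha <- thresholds[is.na(thresholds$level), ]
  if (threshold_approx && nrow(tha) == 1) {
    art$approximation <- pick(coeffs$approximation, tha$M, tha$m, FALSE)
  } else {
    art$approximation <- numeric(np)
  }
  sig <- swt_reconstruct(art)
  sig[!mmask[seq_len(n0)]] <- 0
  structure(
    list(artifact_signal = sig, gated_coeffs = art, thresholds = thresholds,
         motion = motion, qrs = qrs, mode = mode),
    class = "swmar_artifact"
  )
}

#' @export
print.swmar_artifact <- function(x, ...) {
  nz <- sum(x$artifact_signal != 0)
  cat(sprintf(
    "<swmar_artifact (%s): %d/%d samples nonzero, max |a| = %.4g>\n",
    x$mode, nz, length(x$artifact_signal),
    if (nz) max(abs(x$artifact_signal)) else 0
  ))
  invisible(x)
}

#' Remove movement artifacts from a recording (SWMAR pipeline)
#'
#' End-to-end pipeline: band-pass the ECG and build the acceleration
#' module ([preprocess_recording()]), detect QRS complexes
#' ([detect_qrs()]) and motion segments ([detect_motion()]), decompose the
#' filtered ECG with the stationary wavelet transform
#' ([swt_decompose()]), zero the artifact-free coefficient segments at the
#' first three levels, compute per-level robust thresholds, estimate the
#' artifact waveform and subtract it. Wherever the artifact estimate is
#' zero (in particular outside every motion interval) the cleaned output
#' equals the band-passed ECG exactly.
#'
#' @param rec a [recording()].
#' @param level,wavelet decomposition settings, see [swt_decompose()].
#' @param mode,qrs_protect,threshold_approx artifact-estimate settings,
#'   see [estimate_artifact()].
#' @param motion_pad_s motion-interval dilation, see [detect_motion()].
#' @param low,high,order band-pass settings, see [bandpass_ecg()].
#' @param gate_levels detail levels zeroed outside motion, see
#'   [zero_artifact_free()].
#' @return List with `cleaned` (ECG at `fs_ecg`), `artifact`
#'   (`swmar_artifact`), `motion`, `qrs` and `ecg_filt` (the band-passed
#'   ECG the subtraction started from).
#' @export
remove_artifacts <- function(rec, level = 5, wavelet = "haar",
                             mode = c("full", "exceedance"),
                             qrs_protect = TRUE, threshold_approx = TRUE,
                             motion_pad_s = 0.5, low = 0.5, high = 40,
                             order = 4, gate_levels = 1:3) {
  mode <- match.arg(mode)
  pp <- preprocess_recording(rec, low = low, high = high, order = order)
  qrs <- detect_qrs(pp$ecg, pp$fs)
  motion <- detect_motion(pp$acc, pp$fs, pad_s = motion_pad_s)
  coeffs <- swt_decompose(pp$ecg, level = level, wavelet = wavelet)
  gated <- zero_artifact_free(coeffs, motion, levels = gate_levels)
  th <- level_thresholds(gated, pp$fs)
  art <- estimate_artifact(gated, th, motion, qrs, mode = mode,
                           qrs_protect = qrs_protect,
                           threshold_approx = threshold_approx)
  list(cleaned = pp$ecg - art$artifact_signal, artifact = art,
       motion = motion, qrs = qrs, ecg_filt = pp$ecg)
}
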