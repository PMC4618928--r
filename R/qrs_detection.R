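#' Central second difference of a series
#'
#' `y[k] = x[k+1] - 2 x[k] + x[k-1]` at interior points, with the edge
#' values replicated so the output has the input's length. The second
#' derivative accentuates the steep QRS deflections relative to the slower
#' P and T waves.
#'
#' @param x numeric vector, length >= 3.
#' @return Numeric vector, same length as `x`.
#' @export
second_derivative <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  y <- numeric(n)
  y[2:(n - 1)] <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
  y[1] <- y[2]
  y[n] <- y[n - 1]
  y
}

#' Short-time energy of a series
#'
#' Sum of squares within a moving window. The defaults (32 ms window,
#' 16 ms shift) give a 50% overlap and integer sample counts at 250 Hz
#' (8 and 4 samples).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param win_ms,shift_ms window length and shift in milliseconds.
#' @return An object of class `swmar_energy` with fields `energies`
#'   (per-frame sum of squares), `frame_len`, `frame_shift` (samples),
#'   `fs` and `n` (input length). Frame `i` covers samples
#'   `[(i-1)*shift, (i-1)*shift + win)` (0-based).
#' @export
frame_energy <- function(x, fs, win_ms = 32, shift_ms = 16) {
  win <- round(win_ms * fs / 1000)
  shift <- round(shift_ms * fs / 1000)
  if (win < 2) stop("window must span at least 2 samples")
  if (shift < 1) stop("shift must span at least 1 sample")
  n <- length(x)
  if (n < win) stop("signal shorter than one window")
  nf <- floor((n - win) / shift) + 1
  cs <- c(0, cumsum(x^2))
  starts <- (seq_len(nf) - 1) * shift # 0-based
  energies <- cs[starts + win + 1] - cs[starts + 1]
  structure(
    list(energies = energies, frame_len = win, frame_shift = shift,
         fs = fs, n = n),
    class = "swmar_energy"
  )
}

#' @export
print.swmar_energy <- function(x, ...) {
  cat(sprintf("<swmar_energy: %d frames (win %d, shift %d samples @ %g Hz)>\n",
              length(x$energies), x$frame_len, x$frame_shift, x$fs))
  invisible(x)
}

#' Adaptive QRS energy threshold from local extrema
#'
#' Splits the frame-energy series into non-overlapping intervals of
#' `interval_s` seconds (sized so that at least one heart beat falls in
#' each; 1.5 s matches the longest mean equine RR interval), records the
#' local maximum (LM) and minimum (Lm) of the energy in each interval, and
#' sets the detection threshold to the median of the two series' medians,
#' i.e. their midpoint.
#'
#' @param fe a [frame_energy()] result.
#' @param interval_s extrema interval length in seconds.
#' @return An object of class `swmar_qrs_threshold` with fields `lm`
#'   (per-interval maxima), `lm_min` (per-interval minima), `lm_median`,
#'   `lm_min_median` and `threshold`.
#' @export
estimate_qrs_threshold <- function(fe, interval_s = 1.5) {
  stopifnot(inherits(fe, "swmar_energy"))
  if (length(fe$energies) == 0) stop("empty energy series")
  frames_per <- floor(interval_s * fe$fs / fe$frame_shift)
  if (frames_per < 1 || length(fe$energies) < frames_per) {
    stop("need at least one full ", interval_s, " s interval")
  }
  nint <- floor(length(fe$energies) / frames_per)
  idx <- rep(seq_len(nint), each = frames_per)
  e <- fe$energies[seq_len(nint * frames_per)]
  lm <- tapply(e, idx, max)
  lmn <- tapply(e, idx, min)
  lm_med <- stats::median(lm)
  lmn_med <- stats::median(lmn)
  structure(
    list(lm = as.numeric(lm), lm_min = as.numeric(lmn),
         lm_median = lm_med, lm_min_median = lmn_med,
         threshold = (lm_med + lmn_med) / 2),
    class = "swmar_qrs_threshold"
  )
}

#' @export
print.swmar_qrs_threshold <- function(x, ...) {
  cat(sprintf(
    "<swmar_qrs_threshold: %.4g (median LM %.4g, median Lm %.4g, %d intervals)>\n",
    x$threshold, x$lm_median, x$lm_min_median, length(x$lm)
  ))
  invisible(x)
}

#' Detect QRS complexes by second-derivative energy thresholding
#'
#' Pipeline: second derivative of the (band-passed) ECG, short-time energy
#' (32/16 ms frames), adaptive threshold from per-1.5 s energy extrema,
#' then maximal runs of above-threshold frames. Each run maps to the sample
#' interval from the first frame's start (marker A, QRS onset) to the last
#' frame's end (marker B, QRS offset); runs closer than `merge_gap_ms` are
#' merged since distinct equine beats are never that close.
#'
#' @param ecg band-passed ECG samples.
#' @param fs sampling rate, Hz.
#' @param win_ms,shift_ms energy frame parameters, see [frame_energy()].
#' @param interval_s extrema interval for the threshold, see
#'   [estimate_qrs_threshold()].
#' @param merge_gap_ms gap below which neighbouring detections are merged.
#' @return A `swmar_intervals` labelled `"qrs"`; the threshold object is
#'   attached as attribute `"threshold"`.
#' @export
detect_qrs <- function(ecg, fs = 250, win_ms = 32, shift_ms = 16,
                       interval_s = 1.5, merge_gap_ms = 100) {
  fe <- frame_energy(second_derivative(ecg), fs, win_ms, shift_ms)
  th <- estimate_qrs_threshold(fe, interval_s)
  above <- fe$energies > th$threshold
  r <- rle(above)
  ends_f <- cumsum(r$lengths)
  starts_f <- ends_f - r$lengths # 0-based frame index of run start
  keep <- r$values
  if (!any(keep)) {
    out <- interval_set(integer(0), integer(0), fs, label = "qrs")
    attr(out, "threshold") <- th
    return(out)
  }
  s <- starts_f[keep] * fe$frame_shift
  e <- (ends_f[keep] - 1) * fe$frame_shift + fe$frame_len
  # merge runs separated by less than merge_gap_ms
  gap <- merge_gap_ms * fs / 1000
  ms <- s[1]
  me <- e[1]
  rs <- integer(0)
  re <- integer(0)
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] - me < gap) {
        me <- max(me, e[i])
      } else {
        rs <- c(rs, ms)
        re <- c(re, me)
        ms <- s[i]
        me <- e[i]
      }
    }
  }
  rs <- c(rs, ms)
  re <- c(re, me)
  out <- interval_set(rs, pmin(re, length(ecg)), fs, label = "qrs",
                      n = length(ecg))
  attr(out, "threshold") <- th
  out
}
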