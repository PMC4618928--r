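#' Orthonormal wavelet filter pairs
#'
#' Returns the analysis lowpass/highpass taps for the named wavelet. Only
#' short orthonormal FIR pairs are provided; the default Haar pair is
#' exactly invertible with no edge effects and is the pair used throughout
#' the artifact-removal pipeline.
#'
#' @param wavelet `"haar"` (default) or `"db2"`.
#' @return List with `h` (lowpass) and `g` (highpass) tap vectors, each of
#'   unit norm, with the conjugate-quadrature relation
#'   `g[l] = (-1)^l h[L-1-l]`.
#' @export
wavelet_filters <- function(wavelet = "haar") {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop("unknown wavelet: ", wavelet)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

#' Haar analysis filter pair
#'
#' Convenience accessor for the default pair: lowpass `(1, 1)/sqrt(2)`,
#' highpass `(1, -1)/sqrt(2)`.
#'
#' @return List with `h` (lowpass) and `g` (highpass).
#' @export
haar_filters <- function() wavelet_filters("haar")

# circular shift: y[k] = x[(k + s) mod n], 0-based
cshift <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  c(x[(s + 1):n], x[1:s])
}

#' Stationary (undecimated) wavelet decomposition
#'
#' A trous scheme: at level `j` the filters are upsampled by inserting
#' `2^(j-1) - 1` zeros between taps and applied by circular convolution
#' with no decimation, so every level's coefficient sequence has the
#' (padded) signal's length and the transform is shift-invariant. The input
#' is padded to the next multiple of `2^level` by replicating its last
#' sample; the original length is recorded and restored on reconstruction.
#' Filters carry the sqrt(2)-normalized orthonormal convention, so the
#' approximation of a constant signal c is `c * 2^(level/2)`.
#'
#' Level 1 is the finest scale: low levels carry the fast-changing parts of
#' the ECG (the QRS complexes), high levels the slower P/T waves.
#'
#' @param x numeric signal.
#' @param level decomposition depth J (default 5).
#' @param wavelet wavelet name, see [wavelet_filters()].
#' @return An object of class `swmar_swt` with fields `details` (list of J
#'   series, fine to coarse), `approximation`, `level`, `wavelet`,
#'   `original_length` and `padded_length`.
#' @export
swt_decompose <- function(x, level = 5, wavelet = "haar") {
  n0 <- length(x)
  if (n0 == 0) stop("empty signal")
  if (level < 1) stop("level must be >= 1")
  flt <- wavelet_filters(wavelet)
  blk <- 2^level
  n <- ceiling(n0 / blk) * blk
  if (n > n0) x <- c(x, rep(x[n0], n - n0))
  a <- x
  details <- vector("list", level)
  for (j in seq_len(level)) {
    s <- 2^(j - 1)
    anew <- 0
    d <- 0
    for (l in seq_along(flt$h)) {
      sh <- cshift(a, s * (l - 1))
      anew <- anew + flt$h[l] * sh
      d <- d + flt$g[l] * sh
    }
    details[[j]] <- d
    a <- anew
  }
  structure(
    list(details = details, approximation = a, level = level,
         wavelet = wavelet, original_length = n0, padded_length = n),
    class = "swmar_swt"
  )
}

#' @export
print.swmar_swt <- function(x, ...) {
  cat(sprintf(
    "<swmar_swt: %d-level %s decomposition of %d samples (padded to %d)>\n",
    x$level, x$wavelet, x$original_length, x$padded_length
  ))
  invisible(x)
}

#' Inverse stationary wavelet transform
#'
#' Exact inverse of [swt_decompose()]: at each level the two redundant
#' phase reconstructions are averaged,
#' `A_{j-1}[k] = (1/2) * sum_l (h[l] A_j[k - s l] + g[l] D_j[k - s l])`
#' with circular indexing, which reproduces the input to machine precision
#' and degrades gracefully when coefficients have been modified. The result
#' is trimmed to the recorded original length.
#'
#' @param coeffs a `swmar_swt`.
#' @return Numeric signal of length `coeffs$original_length`.
#' @export
swt_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "swmar_swt"))
  n <- coeffs$padded_length
  if (length(coeffs$approximation) != n ||
      any(lengths(coeffs$details) != n)) {
    stop("coefficient series lengths inconsistent with padded length")
  }
  if (n %% 2^coeffs$level != 0) {
    stop("padded length not divisible by 2^level")
  }
  flt <- wavelet_filters(coeffs$wavelet)
  a <- coeffs$approximation
  for (j in coeffs$level:1) {
    s <- 2^(j - 1)
    d <- coeffs$details[[j]]
    anew <- 0
    for (l in seq_along(flt$h)) {
      anew <- anew + flt$h[l] * cshift(a, -s * (l - 1)) +
        flt$g[l] * cshift(d, -s * (l - 1))
    }
    a <- anew / 2
  }
  a[seq_len(coeffs$original_length)]
}
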