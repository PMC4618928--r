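#' Movement-artifact-affected percentage of a record
#'
#' Windowed-RMS criterion standing in for expert labelling: the record is
#' split into non-overlapping windows of `window_s` seconds, and a window
#' counts as artifact-affected when the RMS of the residual artifact
#' inside it exceeds `beta` times the overall RMS of the clean reference.
#' Before cleaning the residual is the injected artifact itself; after
#' cleaning it is whatever the method left behind.
#'
#' @param residual_artifact residual artifact samples.
#' @param clean_ref clean reference ECG, same length.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param beta RMS ratio above which a window counts as affected.
#' @return Percentage of affected windows in `[0, 100]`.
#' @export
ma_fraction <- function(residual_artifact, clean_ref, fs = 250,
                        window_s = 1, beta = 1) {
  n <- length(residual_artifact)
  if (n == 0) stop("empty input")
  if (length(clean_ref) != n) stop("residual/reference length mismatch")
  w <- round(window_s * fs)
  nf <- floor(n / w)
  if (nf < 1) stop("record shorter than one window")
  ref_rms <- sqrt(mean(clean_ref^2))
  m <- matrix(residual_artifact[seq_len(nf * w)]^2, nrow = w)
  win_rms <- sqrt(colMeans(m))
  100 * mean(win_rms > beta * ref_rms)
}

#' Bland-Altman agreement statistics
#'
#' For paired series `a`, `b`: bias = mean of the differences `d = a - b`,
#' limits of agreement = bias +/- 1.96 times the sample SD of `d`, and the
#' least-squares slope of `d` against the pair means `(a + b)/2` as a
#' trend check.
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return An object of class `swmar_agreement` with fields `bias`,
#'   `sd_diff`, `loa_low`, `loa_high` and `trend`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  m <- (a + b) / 2
  trend <- if (stats::var(m) > 0) {
    unname(stats::coef(stats::lm(d ~ m))[2])
  } else {
    0
  }
  structure(
    list(bias = bias, sd_diff = sdd, loa_low = bias - 1.96 * sdd,
         loa_high = bias + 1.96 * sdd, trend = trend),
    class = "swmar_agreement"
  )
}

#' @export
print.swmar_agreement <- function(x, ...) {
  cat(sprintf(
    "<swmar_agreement: bias %.4g, SD %.4g, LoA [%.4g, %.4g], trend %.4g>\n",
    x$bias, x$sd_diff, x$loa_low, x$loa_high, x$trend
  ))
  invisible(x)
}

#' Compare artifact-removal methods on a synthetic study
#'
#' Runs each method on every subject of the study and scores it with the
#' windowed-RMS movement-artifact percentage ([ma_fraction()]) before and
#' after cleaning. Residuals are taken against the ground-truth clean ECG:
#' before cleaning the residual is the injected artifact; after cleaning it
#' is `cleaned - clean`. Methods: `"swmar"` ([remove_artifacts()]),
#' `"nlms"` ([nlms_clean_recording()]) and `"none"` (pass-through of the
#' observed ECG, as a no-op control).
#'
#' @param suite a [make_study()] result (or list of `swmar_truth`).
#' @param methods character vector of method names.
#' @param window_s,beta scoring parameters, see [ma_fraction()].
#' @param ... further arguments passed to the method functions.
#' @return A data frame with one row per subject and method: `subject`,
#'   `method`, `raw_pct`, `cleaned_pct`, `delta` (cleaned - raw,
#'   percentage points) and `relative_reduction` (percent of the raw
#'   percentage removed). A `summary` attribute holds per-method mean
#'   reductions, the count of subjects where the wavelet pipeline beats
#'   the adaptive filter, and Friedman / Wilcoxon signed-rank tests when
#'   both methods were run.
#' @export
compare_methods <- function(suite, methods = c("swmar", "nlms"),
                            window_s = 1, beta = 1, ...) {
  if (length(suite) == 0) stop("empty suite")
  bad <- setdiff(methods, c("swmar", "nlms", "none"))
  if (length(bad)) stop("unknown method: ", paste(bad, collapse = ", "))
  rows <- list()
  for (si in seq_along(suite)) {
    truth <- suite[[si]]
    stopifnot(inherits(truth, "swmar_truth"))
    fs <- truth$recording$fs_ecg
    raw_pct <- ma_fraction(truth$artifact, truth$clean_ecg, fs,
                           window_s = window_s, beta = beta)
    for (m in methods) {
      cleaned <- switch(m,
        swmar = remove_artifacts(truth$recording, ...)$cleaned,
        nlms = nlms_clean_recording(truth$recording, ...)$cleaned,
        none = truth$recording$ecg
      )
      res <- cleaned - truth$clean_ecg
      cleaned_pct <- ma_fraction(res, truth$clean_ecg, fs,
                                 window_s = window_s, beta = beta)
      rows[[length(rows) + 1]] <- data.frame(
        subject = truth$recording$id, method = m,
        raw_pct = raw_pct, cleaned_pct = cleaned_pct,
        delta = cleaned_pct - raw_pct,
        relative_reduction = if (raw_pct > 0) {
          100 * (raw_pct - cleaned_pct) / raw_pct
        } else {
          0
        }
      )
    }
  }
  out <- do.call(rbind, rows)
  summ <- list(
    mean_relative_reduction = tapply(out$relative_reduction, out$method,
                                     mean),
    mean_delta = tapply(out$delta, out$method, mean)
  )
  if (all(c("swmar", "nlms") %in% methods)) {
    sw <- out[out$method == "swmar", ]
    nl <- out[out$method == "nlms", ]
    summ$swmar_beats_nlms <- sum(sw$delta < nl$delta)
    pct <- cbind(raw = sw$raw_pct, nlms = nl$cleaned_pct,
                 swmar = sw$cleaned_pct)
    if (nrow(pct) >= 2) {
      summ$friedman_p <- stats::friedman.test(pct)$p.value
      # exact signed-rank p-values where possible; ties/zero differences
      # (possible on tiny suites) fall back to the normal approximation
      summ$wilcoxon_p <- suppressWarnings(c(
        raw_vs_nlms = stats::wilcox.test(pct[, "raw"], pct[, "nlms"],
                                         paired = TRUE)$p.value,
        raw_vs_swmar = stats::wilcox.test(pct[, "raw"], pct[, "swmar"],
                                          paired = TRUE)$p.value,
        nlms_vs_swmar = stats::wilcox.test(pct[, "nlms"], pct[, "swmar"],
                                           paired = TRUE)$p.value
      ))
    }
  }
  attr(out, "summary") <- summ
  out
}
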