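#' Synchronized ECG + accelerometer recording
#'
#' Container for a time-aligned single-lead ECG and a triaxial accelerometer
#' acquired by the same device. The two channels share a start time; no
#' cross-channel lag estimation is performed.
#'
#' @param ecg numeric vector, ECG samples in millivolts at `fs_ecg` Hz.
#' @param acc_x,acc_y,acc_z numeric vectors of equal length, accelerometer
#'   components (g) at `fs_acc` Hz.
#' @param fs_ecg ECG sampling rate in Hz (default 250).
#' @param fs_acc accelerometer sampling rate in Hz (default 25).
#' @param start_time offset of the first sample in seconds.
#' @param id free-text identifier.
#' @return An object of class `swmar_recording`.
#' @examples
#' rec <- recording(sin(2 * pi * (0:2499) / 250), rep(0, 250), rep(0, 250),
#'                  rep(1, 250))
#' duration(rec)
#' @export
recording <- function(ecg, acc_x, acc_y, acc_z, fs_ecg = 250, fs_acc = 25,
                      start_time = 0, id = "") {
  if (!is.numeric(ecg) || length(ecg) < 1) {
    stop("`ecg` must be a non-empty numeric vector")
  }
  if (fs_ecg <= 0 || fs_acc <= 0) stop("sampling rates must be positive")
  na <- length(acc_x)
  if (length(acc_y) != na || length(acc_z) != na) {
    stop("accelerometer components must have equal length")
  }
  if (na < 1) stop("accelerometer series must be non-empty")
  # channel durations must agree to within one accelerometer sample period
  d_ecg <- length(ecg) / fs_ecg
  d_acc <- na / fs_acc
  if (abs(d_ecg - d_acc) > 1 / fs_acc + 1e-9) {
    stop(sprintf(
      "ECG duration (%.3f s) and accelerometer duration (%.3f s) disagree by more than one accelerometer sample period",
      d_ecg, d_acc
    ))
  }
  structure(
    list(
      ecg = as.numeric(ecg),
      acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
      acc_z = as.numeric(acc_z),
      fs_ecg = fs_ecg, fs_acc = fs_acc,
      start_time = start_time, id = as.character(id)
    ),
    class = "swmar_recording"
  )
}

#' Recording duration in seconds
#' @param rec a `swmar_recording`.
#' @return Duration of the ECG channel in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "swmar_recording"))
  length(rec$ecg) / rec$fs_ecg
}

#' @export
print.swmar_recording <- function(x, ...) {
  cat(sprintf(
    "<swmar_recording%s: %.1f s, ECG %d samples @ %g Hz, accel %d samples @ %g Hz>\n",
    if (nzchar(x$id)) paste0(" ", x$id) else "",
    duration(x), length(x$ecg), x$fs_ecg, length(x$acc_x), x$fs_acc
  ))
  invisible(x)
}

#' Set of half-open sample-index intervals
#'
#' Intervals are half-open `[start, end)` pairs of 0-based sample indices on
#' a series sampled at `fs` Hz. On construction the set is normalized:
#' intervals are sorted by start and overlapping or abutting intervals are
#' merged, so the stored set is always sorted and pairwise disjoint.
#'
#' @param starts,ends integer vectors of equal length; `0 <= start < end`.
#' @param fs sampling rate of the indexed series, Hz.
#' @param label free text, e.g. `"qrs"`, `"motion"`, `"artifact"`.
#' @param n optional series length; when given, `end <= n` is enforced.
#' @return An object of class `swmar_intervals` with a two-column integer
#'   matrix `$intervals`.
#' @examples
#' interval_set(c(30, 10), c(40, 20), fs = 250, label = "motion")
#' @export
interval_set <- function(starts, ends, fs, label = "", n = NULL) {
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (length(starts) > 0) {
    if (any(starts < 0)) stop("negative start index")
    if (any(ends <= starts)) stop("intervals must satisfy start < end")
    if (!is.null(n) && any(ends > n)) stop("interval end beyond series length")
    o <- order(starts, ends)
    starts <- as.integer(round(starts[o]))
    ends <- as.integer(round(ends[o]))
    # merge overlapping or abutting intervals
    ms <- starts[1]
    me <- ends[1]
    rs <- integer(0)
    re <- integer(0)
    if (length(starts) > 1) {
      for (i in 2:length(starts)) {
        if (starts[i] <= me) {
          me <- max(me, ends[i])
        } else {
          rs <- c(rs, ms)
          re <- c(re, me)
          ms <- starts[i]
          me <- ends[i]
        }
      }
    }
    rs <- c(rs, ms)
    re <- c(re, me)
    starts <- rs
    ends <- re
  } else {
    starts <- integer(0)
    ends <- integer(0)
  }
  structure(
    list(
      intervals = cbind(start = as.integer(starts), end = as.integer(ends)),
      fs = fs, label = as.character(label)
    ),
    class = "swmar_intervals"
  )
}

#' @export
print.swmar_intervals <- function(x, ...) {
  cat(sprintf(
    "<swmar_intervals \"%s\": %d interval(s) @ %g Hz, %.2f s total>\n",
    x$label, nrow(x$intervals), x$fs,
    sum(x$intervals[, 2] - x$intervals[, 1]) / x$fs
  ))
  invisible(x)
}

#' @export
length.swmar_intervals <- function(x) nrow(x$intervals)

#' Logical sample mask of an interval set
#' @param iv a `swmar_intervals`.
#' @param n series length in samples.
#' @return Logical vector of length `n`, TRUE inside the intervals.
#' @export
intervals_mask <- function(iv, n) {
  stopifnot(inherits(iv, "swmar_intervals"))
  m <- logical(n)
  if (nrow(iv$intervals) > 0) {
    for (i in seq_len(nrow(iv$intervals))) {
      a <- max(iv$intervals[i, 1] + 1L, 1L)
      b <- min(iv$intervals[i, 2], n)
      if (a <= b) m[a:b] <- TRUE
    }
  }
  m
}

#' Build an interval set from a logical mask
#' @param mask logical vector; runs of TRUE become intervals.
#' @inheritParams interval_set
#' @return A `swmar_intervals`.
#' @export
intervals_from_mask <- function(mask, fs, label = "") {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  interval_set(starts[keep], ends[keep], fs = fs, label = label,
               n = length(mask))
}

#' Dilate every interval by a fixed time pad
#' @param iv a `swmar_intervals`.
#' @param pad_s pad in seconds added to both sides of every interval.
#' @param n series length used to clip; defaults to no clipping.
#' @return A normalized (merged) `swmar_intervals`.
#' @export
intervals_dilate <- function(iv, pad_s, n = NULL) {
  stopifnot(inherits(iv, "swmar_intervals"))
  if (nrow(iv$intervals) == 0) return(iv)
  p <- round(pad_s * iv$fs)
  s <- pmax(iv$intervals[, 1] - p, 0)
  e <- iv$intervals[, 2] + p
  if (!is.null(n)) e <- pmin(e, n)
  interval_set(s, e, fs = iv$fs, label = iv$label, n = n)
}

#' Complement of an interval set on [0, n)
#' @inheritParams intervals_mask
#' @param label label for the complement set.
#' @return A `swmar_intervals` covering exactly the samples outside `iv`.
#' @export
intervals_complement <- function(iv, n, label = paste0("non-", iv$label)) {
  intervals_from_mask(!intervals_mask(iv, n), fs = iv$fs, label = label)
}

#' Jaccard overlap of two interval sets
#'
#' Sample-level intersection over union, computed on a common series length.
#' Both sets must be on the same time base.
#'
#' @param a,b `swmar_intervals` objects with equal `fs`.
#' @param n series length in samples.
#' @return Jaccard index in `[0, 1]` (1 when both sets are empty).
#' @export
intervals_jaccard <- function(a, b, n) {
  stopifnot(a$fs == b$fs)
  ma <- intervals_mask(a, n)
  mb <- intervals_mask(b, n)
  u <- sum(ma | mb)
  if (u == 0) return(1)
  sum(ma & mb) / u
}

#' Read a recording from disk
#'
#' CSV layout: either a single file with columns `time, ecg, acc_x, acc_y,
#' acc_z` where accelerometer rows are sparse at their own rate (blank/NA on
#' ECG-only rows), or a directory containing sibling files `ecg.csv`
#' (`time, ecg`) and `acc.csv` (`time, acc_x, acc_y, acc_z`). Sampling rates
#' are recovered from the time columns. WFDB layout: a record basename
#' `<base>` resolving to `<base>_ecg.hea/.dat` and `<base>_acc.hea/.dat`
#' (format 16 signal files).
#'
#' @param path file path (single CSV), directory (CSV pair) or WFDB record
#'   basename.
#' @param format `"csv"` or `"wfdb"`.
#' @return A [recording()].
#' @export
load_recording <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(load_recording_wfdb(path))
  if (dir.exists(path)) {
    f_ecg <- file.path(path, "ecg.csv")
    f_acc <- file.path(path, "acc.csv")
    if (!file.exists(f_ecg) || !file.exists(f_acc)) {
      stop("directory must contain ecg.csv and acc.csv")
    }
    de <- utils::read.csv(f_ecg)
    da <- utils::read.csv(f_acc)
    if (!all(c("time", "ecg") %in% names(de))) {
      stop("ecg.csv must have columns time, ecg")
    }
    if (!all(c("time", "acc_x", "acc_y", "acc_z") %in% names(da))) {
      stop("acc.csv must have columns time, acc_x, acc_y, acc_z")
    }
    fs_ecg <- infer_fs(de$time)
    fs_acc <- infer_fs(da$time)
    return(recording(de$ecg, da$acc_x, da$acc_y, da$acc_z,
                     fs_ecg = fs_ecg, fs_acc = fs_acc,
                     start_time = de$time[1],
                     id = basename(path)))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("time", "ecg", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(d))) {
    stop("CSV must have columns ", paste(need, collapse = ", "))
  }
  acc_rows <- !is.na(d$acc_x)
  if (any(is.na(d$acc_y[acc_rows])) || any(is.na(d$acc_z[acc_rows]))) {
    stop("acc_y/acc_z missing on accelerometer rows")
  }
  fs_ecg <- infer_fs(d$time)
  fs_acc <- infer_fs(d$time[acc_rows])
  recording(d$ecg, d$acc_x[acc_rows], d$acc_y[acc_rows], d$acc_z[acc_rows],
            fs_ecg = fs_ecg, fs_acc = fs_acc, start_time = d$time[1],
            id = sub("\\.csv$", "", basename(path)))
}

infer_fs <- function(time) {
  if (length(time) < 2) stop("cannot infer sampling rate from < 2 samples")
  dt <- stats::median(diff(time))
  if (dt <= 0) stop("non-increasing time column")
  # snap to an integer rate when the time stamps are quantized
  fs <- 1 / dt
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  fs
}

#' Write a recording to disk
#'
#' Inverse of [load_recording()]; the CSV single-file layout interleaves the
#' accelerometer rows at their own rate (every `fs_ecg/fs_acc`-th row).
#'
#' @param rec a [recording()].
#' @param path destination: `.csv` file, directory (written as `ecg.csv` +
#'   `acc.csv`) or WFDB basename.
#' @param format `"csv"` or `"wfdb"`.
#' @param digits significant digits written for CSV samples.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path, format = c("csv", "wfdb"), digits = 15) {
  stopifnot(inherits(rec, "swmar_recording"))
  format <- match.arg(format)
  if (format == "wfdb") return(save_recording_wfdb(rec, path))
  r <- rec$fs_ecg / rec$fs_acc
  t_ecg <- rec$start_time + (seq_along(rec$ecg) - 1) / rec$fs_ecg
  if (grepl("\\.csv$", path)) {
    ax <- ay <- az <- rep(NA_real_, length(rec$ecg))
    idx <- 1 + (seq_along(rec$acc_x) - 1) * r
    idx <- idx[idx <= length(rec$ecg)]
    k <- seq_along(idx)
    ax[idx] <- rec$acc_x[k]
    ay[idx] <- rec$acc_y[k]
    az[idx] <- rec$acc_z[k]
    d <- data.frame(
      time = signif(t_ecg, digits), ecg = signif(rec$ecg, digits),
      acc_x = signif(ax, digits), acc_y = signif(ay, digits),
      acc_z = signif(az, digits)
    )
    utils::write.csv(d, path, row.names = FALSE, na = "")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    t_acc <- rec$start_time + (seq_along(rec$acc_x) - 1) / rec$fs_acc
    utils::write.csv(
      data.frame(time = signif(t_ecg, digits), ecg = signif(rec$ecg, digits)),
      file.path(path, "ecg.csv"), row.names = FALSE
    )
    utils::write.csv(
      data.frame(time = signif(t_acc, digits),
                 acc_x = signif(rec$acc_x, digits),
                 acc_y = signif(rec$acc_y, digits),
                 acc_z = signif(rec$acc_z, digits)),
      file.path(path, "acc.csv"), row.names = FALSE
    )
  }
  invisible(path)
}

# ---- minimal WFDB (header + format-16 signal) support ----------------------
# Two sibling records <base>_ecg and <base>_acc, one .hea + one .dat each.
# Samples are stored as little-endian int16: adc = round(x * gain) + baseline.

write_wfdb_record <- function(name, dirn, series, fs, units, gain) {
  nsig <- length(series)
  nsamp <- length(series[[1]])
  dat <- paste0(basename(name), ".dat")
  hea <- file.path(dirn, paste0(basename(name), ".hea"))
  lines <- sprintf("%s %d %g %d", basename(name), nsig, fs, nsamp)
  adc <- integer(0)
  for (i in seq_len(nsig)) {
    lines <- c(lines, sprintf("%s 16 %g(0)/%s 16 0 0 0 0 %s",
                              dat, gain, units, names(series)[i]))
    v <- as.integer(round(series[[i]] * gain))
    if (any(abs(v) > 32767)) stop("signal exceeds 16-bit range at gain ", gain)
    adc <- cbind(adc, v)
  }
  writeLines(lines, hea)
  con <- file(file.path(dirn, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(NULL)
}

read_wfdb_record <- function(name) {
  hea <- paste0(name, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sig <- vector("list", nsig)
  gains <- numeric(nsig)
  bases <- numeric(nsig)
  datf <- character(nsig)
  for (i in seq_len(nsig)) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    datf[i] <- tok[1]
    if (tok[2] != "16") stop("only format 16 supported, got ", tok[2])
    gspec <- tok[3] # gain(baseline)/units
    g <- sub("^([-0-9.eE+]+).*$", "\\1", gspec)
    b <- if (grepl("\\(", gspec)) sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec) else "0"
    gains[i] <- as.numeric(g)
    bases[i] <- as.numeric(b)
  }
  if (length(unique(datf)) != 1) stop("multi-file records not supported")
  con <- file(file.path(dirname(name), datf[1]), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nsig * nsamp, size = 2,
                 endian = "little", signed = TRUE)
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  for (i in seq_len(nsig)) sig[[i]] <- (m[, i] - bases[i]) / gains[i]
  names(sig) <- vapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(tok) >= 9) tok[length(tok)] else paste0("sig", i)
  }, character(1))
  list(signals = sig, fs = fs)
}

save_recording_wfdb <- function(rec, path) {
  dirn <- dirname(path)
  if (!dir.exists(dirn)) dir.create(dirn, recursive = TRUE)
  base <- basename(path)
  write_wfdb_record(paste0(base, "_ecg"), dirn,
                    list(ecg = rec$ecg), rec$fs_ecg, "mV", gain = 1000)
  write_wfdb_record(paste0(base, "_acc"), dirn,
                    list(acc_x = rec$acc_x, acc_y = rec$acc_y,
                         acc_z = rec$acc_z),
                    rec$fs_acc, "g", gain = 1000)
  invisible(path)
}

load_recording_wfdb <- function(path) {
  e <- read_wfdb_record(paste0(path, "_ecg"))
  a <- read_wfdb_record(paste0(path, "_acc"))
  recording(e$signals$ecg, a$signals$acc_x, a$signals$acc_y, a$signals$acc_z,
            fs_ecg = e$fs, fs_acc = a$fs, id = basename(path))
}

#' Write an interval set as CSV
#'
#' Columns: `label, start_index, end_index, start_seconds, end_seconds`.
#' The index round trip through [load_intervals()] is lossless.
#'
#' @param iv a `swmar_intervals` (normalization is applied on construction,
#'   so the stored file is always sorted/disjoint).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
save_intervals <- function(iv, path) {
  stopifnot(inherits(iv, "swmar_intervals"))
  d <- data.frame(
    label = rep(iv$label, nrow(iv$intervals)),
    start_index = iv$intervals[, 1],
    end_index = iv$intervals[, 2],
    start_seconds = iv$intervals[, 1] / iv$fs,
    end_seconds = iv$intervals[, 2] / iv$fs
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an interval set written by [save_intervals()]
#'
#' The sampling rate is recovered from the index/seconds columns; for an
#' empty (header-only) file, `fs` falls back to the `fs` argument.
#'
#' @param path CSV path.
#' @param fs fallback sampling rate for empty files.
#' @param label fallback label for empty files.
#' @return A `swmar_intervals`.
#' @export
load_intervals <- function(path, fs = 250, label = "") {
  d <- utils::read.csv(path)
  need <- c("label", "start_index", "end_index", "start_seconds",
            "end_seconds")
  if (!all(need %in% names(d))) {
    stop("interval CSV must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(d) == 0) return(interval_set(integer(0), integer(0), fs, label))
  pos <- which(d$end_seconds > 0)[1]
  fs_file <- d$end_index[pos] / d$end_seconds[pos]
  if (abs(fs_file - round(fs_file)) < 1e-6 * fs_file) {
    fs_file <- round(fs_file)
  }
  interval_set(d$start_index, d$end_index, fs = fs_file, label = d$label[1])
}
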