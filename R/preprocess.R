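## Preprocessing chain: resampling, 3-sample median filtering, magnitude,
## and sliding-window bookkeeping.
##
## Window convention used throughout the package: 0-based, half-open
## [start, end).  `window_slice()` translates to R's 1-based indexing.

#' Acceleration magnitude (signal magnitude vector)
#'
#' Elementwise Euclidean norm of the tri-axial acceleration,
#' `SMV = sqrt(ax^2 + ay^2 + az^2)`, in g.  Near 1 g at rest, it dips
#' towards 0 during free fall and spikes at impact.
#'
#' @param A an `n x 3` matrix of acceleration vectors, or an
#'   [imu_recording] (its `A` field is used).
#' @return numeric vector of length `n`.
#' @export
magnitude <- function(A) {
  if (inherits(A, "imu_recording")) A <- A$A
  A <- as.matrix(A)
  sqrt(rowSums(A^2))
}

## Running median of window 3 with edge replication; vectorized.
med3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xp <- c(x[1], x, x[n])
  a <- xp[1:n]; b <- xp[2:(n + 1)]; d <- xp[3:(n + 2)]
  pmax(pmin(a, b), pmin(pmax(a, b), d))  # median of three
}

#' 3-sample median filter
#'
#' Running median of window 3 applied to every channel; edges are handled
#' by edge replication so the length is unchanged.  Removes isolated
#' one-sample spikes while leaving monotone stretches untouched.
#'
#' @param x an [imu_recording], a numeric matrix (filtered columnwise), or
#'   a numeric vector.
#' @return same shape as the input.
#' @export
median_filter3 <- function(x) {
  if (inherits(x, "imu_recording")) {
    x$A <- apply(x$A, 2, med3); colnames(x$A) <- c("ax", "ay", "az")
    x$G <- apply(x$G, 2, med3); colnames(x$G) <- c("gx", "gy", "gz")
    return(x)
  }
  if (is.matrix(x)) return(apply(x, 2, med3))
  med3(x)
}

#' Resample a recording
#'
#' Downsamples to `target_fs`.  For integer decimation ratios an
#' anti-aliasing zero-phase Butterworth low-pass (cutoff 0.8 of the new
#' Nyquist) is applied before subsampling unless `antialias = FALSE`
#' (pure subsampling); non-integer ratios fall back to linear
#' interpolation.  Upsampling is refused unless `upsample = TRUE`, since
#' the standard pipeline only ever downsamples.
#'
#' @param rec an [imu_recording].
#' @param target_fs target sampling rate in Hz.
#' @param upsample allow `target_fs > rec$fs`.
#' @param antialias apply the anti-aliasing filter before integer
#'   decimation.
#' @return resampled [imu_recording] with `fs == target_fs`.
#' @export
resample <- function(rec, target_fs, upsample = FALSE, antialias = TRUE) {
  stopifnot(inherits(rec, "imu_recording"))
  if (target_fs <= 0) ff_config_error("target_fs must be positive")
  n <- nrow(rec$A)
  if (n == 0L) ff_contract_error("cannot resample an empty recording")
  if (abs(target_fs - rec$fs) < 1e-9) return(rec)
  if (target_fs > rec$fs && !upsample)
    ff_config_error("target_fs exceeds the recording rate; set upsample = TRUE")

  ratio <- rec$fs / target_fs
  if (target_fs < rec$fs && abs(ratio - round(ratio)) < 1e-9) {
    r <- as.integer(round(ratio))
    A <- rec$A; G <- rec$G
    if (antialias && n > 24) {
      cutoff <- 0.8 * target_fs / 2
      A <- apply(A, 2, lowpass, fs = rec$fs, cutoff = cutoff)
      G <- apply(G, 2, lowpass, fs = rec$fs, cutoff = cutoff)
    }
    keep <- seq(1L, n, by = r)
    A <- A[keep, , drop = FALSE]; G <- G[keep, , drop = FALSE]
  } else {
    new_t <- seq(rec$t[1], rec$t[n], by = 1 / target_fs)
    interp <- function(y) stats::approx(rec$t, y, xout = new_t)$y
    A <- apply(rec$A, 2, interp); G <- apply(rec$G, 2, interp)
  }
  imu_recording(A, G, fs = target_fs, label = rec$label,
                is_fall = rec$is_fall, subject_id = rec$subject_id)
}

#' Sliding windows
#'
#' Enumerates 0-based half-open windows `[start, end)` of a given width
#' and stride over a signal of length `n`; the last partial window is
#' dropped.  A width longer than the signal yields zero windows.
#'
#' @param n signal length in samples.
#' @param width_s window width in seconds.
#' @param stride_s stride in seconds (default 0.5).
#' @param fs sampling rate in Hz.
#' @return a data.frame with columns `start`, `end` (0-based, half-open).
#' @export
sliding_windows <- function(n, width_s, stride_s = 0.5, fs) {
  w <- as.integer(round(width_s * fs))
  if (w < 1L) ff_config_error("window width must cover at least one sample")
  s <- max(1L, as.integer(round(stride_s * fs)))
  if (n < w) return(data.frame(start = integer(0), end = integer(0)))
  start <- seq.int(0L, n - w, by = s)
  data.frame(start = start, end = start + w)
}

## 1-based R indices of a 0-based half-open window.
window_slice <- function(start, end) seq.int(start + 1L, end)

#' Standard preprocessing chain
#'
#' Downsamples to `target_fs` (default 50 Hz) and applies the 3-sample
#' median low-pass filter, in that order (configurable).  Recordings whose
#' native rate is already below `target_fs` are left at their native rate
#' with a warning rather than upsampled.
#'
#' @param rec an [imu_recording].
#' @param target_fs target rate in Hz.
#' @param median apply the median filter.
#' @param median_first run the median filter before downsampling instead
#'   of after.
#' @return preprocessed [imu_recording].
#' @export
preprocess <- function(rec, target_fs = 50, median = TRUE,
                       median_first = FALSE) {
  if (median && median_first) rec <- median_filter3(rec)
  if (rec$fs < target_fs - 1e-9) {
    warning(sprintf(
      "recording rate %g Hz below target %g Hz; keeping native rate",
      rec$fs, target_fs))
  } else {
    rec <- resample(rec, target_fs)
  }
  if (median && !median_first) rec <- median_filter3(rec)
  rec
}
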