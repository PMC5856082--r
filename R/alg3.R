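## Algorithm 3: pattern correlation.  A 5 s fall pattern (per-axis mean of
## aligned excerpts) is correlated with sliding signal segments; a match
## on acceleration is refined by gyroscope correlation, z-axis first.

#' Build an activity pattern from recordings of one class
#'
#' Averages 5 s excerpts, centred on the aligned event, across the input
#' recordings: per-axis acceleration templates plus z- and y-axis
#' gyroscope templates.  The event time is the `impact_time` annotation
#' when present (as set by [generate_fall()]) and the SMV argmax
#' otherwise.  Recordings that cannot host a centred 5 s excerpt are
#' excluded with a warning.
#'
#' @param recordings list of [imu_recording]s of a single class, all at
#'   the same sampling rate.
#' @param duration_s pattern length in seconds (default 5).
#' @param label pattern label.
#' @return an object of class `activity_pattern` with fields `fs`,
#'   `duration_s`, `acc` (`L x 3`), `gyro_z`, `gyro_y`, `label`, `n_used`.
#' @export
build_pattern <- function(recordings, duration_s = 5, label = "fall") {
  if (!length(recordings)) ff_contract_error("need at least one recording")
  fs <- recordings[[1]]$fs
  L <- as.integer(round(duration_s * fs))
  half <- duration_s / 2
  acc <- matrix(0, L, 3); gz <- numeric(L); gy <- numeric(L)
  n_used <- 0L
  for (rec in recordings) {
    if (abs(rec$fs - fs) > 1e-9)
      ff_contract_error("all recordings must share one sampling rate")
    ev <- attr(rec, "impact_time")
    if (is.null(ev)) ev <- rec$t[which.max(magnitude(rec$A))]
    start <- as.integer(round((ev - half) * fs)) + 1L
    if (start < 1L || start + L - 1L > nrow(rec$A)) {
      warning(sprintf("recording '%s' too short for a centred %g s excerpt; excluded",
                      rec$label, duration_s))
      next
    }
    idx <- start:(start + L - 1L)
    acc <- acc + rec$A[idx, ]
    gz <- gz + rec$G[idx, 3]; gy <- gy + rec$G[idx, 2]
    n_used <- n_used + 1L
  }
  if (n_used == 0L) ff_data_error("no recording could host the pattern excerpt")
  structure(list(fs = fs, duration_s = duration_s, acc = acc / n_used,
                 gyro_z = gz / n_used, gyro_y = gy / n_used,
                 label = label, n_used = n_used),
            class = "activity_pattern")
}

#' Pearson correlation with a zero-variance guard
#'
#' Correlation between a signal segment and a template of equal length.
#' If either input has zero variance the correlation is defined as 0:
#' a constant segment carries no pattern evidence.
#'
#' @param segment,template numeric vectors of equal length (>= 2).
#' @return correlation in `[-1, 1]`.
#' @export
correlate <- function(segment, template) {
  if (length(segment) != length(template))
    ff_contract_error("segment and template must have equal length")
  if (length(segment) < 2) ff_contract_error("need at least two samples")
  sa <- stats::sd(segment); sb <- stats::sd(template)
  if (sa < 1e-12 || sb < 1e-12) return(0)
  stats::cor(segment, template)
}

#' Threshold set for the pattern detector
#'
#' `th_ca`: acceleration-correlation threshold in (0, 1); `th_g`: angular
#' velocity magnitude in rad/s deciding which gyro axis is meaningful;
#' `th_cg`: gyroscope-correlation threshold in (0, 1).  One value serves
#' both gyro axes.
#'
#' @param th_ca,th_g,th_cg threshold values.
#' @return a named list of class `alg3_thresholds`.
#' @export
alg3_thresholds <- function(th_ca, th_g, th_cg) {
  structure(list(th_ca = th_ca, th_g = th_g, th_cg = th_cg),
            class = "alg3_thresholds")
}

## Per-segment correlations and gyro stats, threshold-independent given
## the pattern.  One row per 5 s segment.
alg3_featurize <- function(rec, pattern, stride_s = 0.25) {
  if (abs(pattern$fs - rec$fs) > 1e-9)
    ff_contract_error("pattern and recording sampling rates differ")
  L <- nrow(pattern$acc)
  n <- nrow(rec$A)
  win <- sliding_windows(n, pattern$duration_s, stride_s, rec$fs)
  if (!nrow(win))
    return(data.frame(t_mid = numeric(0), r_acc = numeric(0),
                      max_gz = numeric(0), max_gy = numeric(0),
                      r_gz = numeric(0), r_gy = numeric(0)))
  rows <- lapply(seq_len(nrow(win)), function(k) {
    idx <- window_slice(win$start[k], win$end[k])
    r_acc <- mean(vapply(1:3, function(j)
      correlate(rec$A[idx, j], pattern$acc[, j]), numeric(1)))
    data.frame(t_mid = rec$t[idx[1]] + pattern$duration_s / 2,
               r_acc = r_acc,
               max_gz = max(abs(rec$G[idx, 3])),
               max_gy = max(abs(rec$G[idx, 2])),
               r_gz = correlate(rec$G[idx, 3], pattern$gyro_z),
               r_gy = correlate(rec$G[idx, 2], pattern$gyro_y))
  })
  do.call(rbind, rows)
}

alg3_decide <- function(feat, th) {
  acc_match <- feat$r_acc > th$th_ca
  gyro_match <- ifelse(feat$max_gz > th$th_g, feat$r_gz > th$th_cg,
                       ifelse(feat$max_gy > th$th_g, feat$r_gy > th$th_cg,
                              FALSE))
  merge_detections(sort(feat$t_mid[acc_match & gyro_match]), refractory_s = 1)
}

#' Algorithm 3 fall detector (pattern correlation)
#'
#' Slides 5 s segments over the recording; a segment matches on
#' acceleration when the mean of the three per-axis Pearson correlations
#' with the pattern exceeds `th_ca`.  The gyroscope then refines the
#' match: if `max |G_z|` in the segment exceeds `th_g` (the z-axis is
#' "meaningful"), the z-axis correlation must exceed `th_cg`; otherwise
#' the same test is applied to the y-axis; if neither axis is meaningful
#' the match is rejected.  Detections (segment centres) within 1 s are
#' merged.
#'
#' @param rec a preprocessed [imu_recording].
#' @param pattern an [build_pattern()] result at the recording's rate.
#' @param th an [alg3_thresholds].
#' @param stride_s segment stride in seconds (default 0.25; correlation is
#'   alignment-sensitive, hence finer than the other detectors).
#' @return numeric vector of detection times (segment centres, s).
#' @export
detect_alg3 <- function(rec, pattern, th, stride_s = 0.25) {
  alg3_decide(alg3_featurize(rec, pattern, stride_s), th)
}

#' @export
print.activity_pattern <- function(x, ...) {
  cat(sprintf("<activity_pattern> '%s': %g s @ %g Hz, averaged over %d recording(s)\n",
              x$label, x$duration_s, x$fs, x$n_used))
  invisible(x)
}
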