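## Algorithm 1: complementary-filter sensor fusion + two-phase
## (free-fall then impact) thresholding on both the acceleration magnitude
## (SMV) and the absolute vertical acceleration (AV).

#' Accelerometer tilt angles
#'
#' Roll/pitch estimate from a single acceleration sample:
#' `theta_az = atan2(ax, sqrt(ay^2 + az^2))`,
#' `theta_ay = atan2(-ay, sqrt(ax^2 + az^2))`.
#'
#' @param a length-3 acceleration vector in g.
#' @return named numeric `c(theta_z, theta_y)` in radians, each in
#'   `(-pi, pi]`.
#' @export
accel_angles <- function(a) {
  if (!all(is.finite(a)) || all(a == 0))
    ff_data_error("orientation undefined for an all-zero acceleration vector")
  c(theta_z = atan2(a[1], sqrt(a[2]^2 + a[3]^2)),
    theta_y = atan2(-a[2], sqrt(a[1]^2 + a[3]^2)))
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)   # keep the convention (-pi, pi]
}

#' One complementary-filter step
#'
#' Blends gyroscope integration with the accelerometer tilt:
#' `theta' = alpha * (theta + g * dt) + (1 - alpha) * theta_accel`,
#' applied to the roll axis (`gz`) and pitch axis (`gy`).  `alpha = 1` is
#' pure gyro integration (drift-prone), `alpha = 0` is the memoryless
#' accelerometer estimate (noise-prone); values in 0.9--0.98 are typical.
#'
#' @param state named numeric `c(theta_z, theta_y)` in radians.
#' @param a length-3 acceleration vector (g).
#' @param g length-3 angular velocity vector (rad/s).
#' @param alpha blend coefficient in `[0, 1]`.
#' @param dt integration step in seconds (`1/fs`).
#' @return updated `c(theta_z, theta_y)`.
#' @export
complementary_update <- function(state, a, g, alpha, dt) {
  if (alpha < 0 || alpha > 1) ff_config_error("alpha must be in [0, 1]")
  if (dt <= 0) ff_config_error("dt must be positive")
  acc <- if (alpha < 1) accel_angles(a) else c(0, 0)
  new <- c(alpha * (state[1] + g[3] * dt) + (1 - alpha) * acc[1],
           alpha * (state[2] + g[2] * dt) + (1 - alpha) * acc[2])
  stats::setNames(wrap_angle(new), c("theta_z", "theta_y"))
}

#' Complementary filter over a whole recording
#'
#' @param A `n x 3` acceleration matrix (g).
#' @param G `n x 3` angular velocity matrix (rad/s).
#' @param alpha blend coefficient (default 0.95).
#' @param dt sample interval in seconds.
#' @param init initial `c(theta_z, theta_y)`; defaults to the
#'   accelerometer angles of the first sample, which avoids a start-up
#'   transient.
#' @return `n x 2` matrix of `(theta_z, theta_y)` in radians.
#' @export
complementary_filter <- function(A, G, alpha = 0.95, dt, init = NULL) {
  n <- nrow(A)
  th <- matrix(0, n, 2, dimnames = list(NULL, c("theta_z", "theta_y")))
  if (n == 0L) return(th)
  state <- if (is.null(init)) {
    if (alpha < 1) accel_angles(A[1, ]) else c(0, 0)
  } else init
  for (i in seq_len(n)) {
    state <- complementary_update(state, A[i, ], G[i, ], alpha, dt)
    th[i, ] <- state
  }
  th
}

#' Absolute vertical acceleration
#'
#' Projection of the acceleration onto the estimated gravity axis:
#' `|ax sin(theta_z) + ay sin(theta_y) - az cos(theta_y) cos(theta_z)|`.
#'
#' @param A `n x 3` acceleration matrix (or a single vector).
#' @param theta `n x 2` matrix of `(theta_z, theta_y)` (or a single pair).
#' @return nonnegative numeric vector, in g.
#' @export
vertical_acceleration <- function(A, theta) {
  if (is.null(dim(A))) A <- matrix(A, 1)
  if (is.null(dim(theta))) theta <- matrix(theta, 1)
  abs(A[, 1] * sin(theta[, 1]) + A[, 2] * sin(theta[, 2]) -
        A[, 3] * cos(theta[, 2]) * cos(theta[, 1]))
}

#' Threshold set for the two-phase detector
#'
#' Four thresholds in g: free-fall (`smv_ff`, `av_ff`) and impact
#' (`smv_ip`, `av_ip`) amplitude swings for the SMV and AV channels.  The
#' free-fall statistic is the max-min swing within a 0.1 s window; the
#' impact must follow within 1 s.
#'
#' @param smv_ff,smv_ip,av_ff,av_ip thresholds in g.
#' @param freefall_window_s,impact_window_s phase window lengths in
#'   seconds.
#' @return a named list of class `alg1_thresholds`.
#' @export
alg1_thresholds <- function(smv_ff, smv_ip, av_ff, av_ip,
                            freefall_window_s = 0.1, impact_window_s = 1) {
  if (smv_ip <= smv_ff)
    ff_config_error("smv_ip must exceed smv_ff")
  structure(list(smv_ff = smv_ff, smv_ip = smv_ip, av_ff = av_ff,
                 av_ip = av_ip, freefall_window_s = freefall_window_s,
                 impact_window_s = impact_window_s),
            class = "alg1_thresholds")
}

## Rolling max - min over windows of w samples, 1-sample stride.
## Element i refers to the window starting at sample i; length n - w + 1.
rolling_range <- function(x, w) {
  n <- length(x)
  if (w < 1L || n < w) return(numeric(0))
  hi <- x[seq_len(n - w + 1)]
  lo <- hi
  for (k in seq_len(w - 1)) {
    xs <- x[(1 + k):(n - w + 1 + k)]
    hi <- pmax(hi, xs); lo <- pmin(lo, xs)
  }
  hi - lo
}

## TRUE at i when any(flag[(i+1):(i+L)]) (indices clipped to range).
any_ahead <- function(flag, L, include_self = FALSE) {
  cs <- c(0, cumsum(flag))
  n <- length(flag)
  i <- seq_len(n)
  from <- if (include_self) i - 1L else i
  to <- pmin(i + L, n)
  cs[to + 1L] - cs[pmin(from, n) + 1L] > 0
}

#' Two-phase fall detection on SMV and AV channels
#'
#' A detection requires four window exceedances: the max-min swing of SMV
#' within some `freefall_window_s` window above `smv_ff`, a second SMV
#' swing above `smv_ip` within the following `impact_window_s`, and the
#' same two-phase pattern on the AV channel, whose free-fall window must
#' start within the same `impact_window_s` interval as the SMV free-fall
#' window.  Detections closer than 1 s are merged (earliest kept), and the
#' reported time is the sample of maximum SMV inside the impact window.
#'
#' @param smv,av scalar sequences of equal length (g).
#' @param fs sampling rate in Hz.
#' @param th an [alg1_thresholds].
#' @return numeric vector of detection times in seconds.
#' @export
detect_two_phase <- function(smv, av, fs, th) {
  if (length(smv) != length(av))
    ff_contract_error("smv and av must have equal length")
  feat <- alg1_featurize_series(smv, av, fs, th$freefall_window_s,
                                th$impact_window_s)
  alg1_decide(feat, th)
}

## Threshold-independent per-recording statistics (cached during search).
alg1_featurize_series <- function(smv, av, fs, freefall_window_s = 0.1,
                                  impact_window_s = 1) {
  w <- max(1L, as.integer(round(freefall_window_s * fs)))
  list(rr_smv = rolling_range(smv, w), rr_av = rolling_range(av, w),
       smv = smv, fs = fs, w = w,
       L = max(1L, as.integer(round(impact_window_s * fs))))
}

alg1_decide <- function(feat, th) {
  rr_s <- feat$rr_smv; rr_a <- feat$rr_av
  m <- length(rr_s)
  if (m == 0L) return(numeric(0))
  L <- feat$L
  ff_s <- rr_s > th$smv_ff; ip_s <- rr_s > th$smv_ip
  ff_a <- rr_a > th$av_ff;  ip_a <- rr_a > th$av_ip
  ## AV windows that start a complete two-phase AV pattern
  good_av <- ff_a & any_ahead(ip_a, L)
  ok_av_near <- any_ahead(good_av, L, include_self = TRUE)
  cand <- which(ff_s & any_ahead(ip_s, L) & ok_av_near)
  if (!length(cand)) return(numeric(0))
  times <- vapply(cand, function(i) {
    ahead <- (i + 1):min(i + L, m)
    j <- ahead[which(ip_s[ahead])[1]]                   # first impact window
    idx <- j:min(j + feat$w - 1L, length(feat$smv))
    (idx[which.max(feat$smv[idx])] - 1) / feat$fs
  }, numeric(1))
  merge_detections(sort(times), refractory_s = 1)
}

## Keep the earliest of any cluster of detections closer than refractory_s.
merge_detections <- function(times, refractory_s = 1) {
  if (!length(times)) return(numeric(0))
  keep <- times[1]
  for (tm in times[-1]) if (tm - keep[length(keep)] >= refractory_s)
    keep <- c(keep, tm)
  keep
}

#' Algorithm 1 fall detector
#'
#' Runs the complementary filter, computes the SMV and AV channels, and
#' applies the two-phase detector.
#'
#' @param rec a preprocessed [imu_recording] (50 Hz, median-filtered).
#' @param th an [alg1_thresholds].
#' @param alpha complementary-filter blend coefficient.
#' @return numeric vector of detection times in seconds.
#' @export
detect_alg1 <- function(rec, th, alpha = 0.95) {
  feat <- alg1_featurize(rec, alpha)
  alg1_decide(feat, th)
}

alg1_featurize <- function(rec, alpha = 0.95) {
  smv <- magnitude(rec$A)
  theta <- complementary_filter(rec$A, rec$G, alpha, dt = 1 / rec$fs)
  av <- vertical_acceleration(rec$A, theta)
  alg1_featurize_series(smv, av, rec$fs)
}
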