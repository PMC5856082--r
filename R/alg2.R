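## Algorithm 2: feature-level fusion.  Low-pass filtered accelerometer and
## gyroscope channels, 2 s sliding windows, five features (SV, angle
## variation, orientation change, SV_G, SV_GA) compared against thresholds
## in a short-circuiting cascade gated by the SV maximum.

#' Sum of absolute components (L1 norm)
#'
#' `SV = |x| + |y| + |z|`; applied to acceleration (g), angular velocity
#' (rad/s) or angular acceleration (rad/s^2) vectors.
#'
#' @param v length-3 vector, or an `n x 3` matrix (rowwise).
#' @return nonnegative scalar (or vector of length `n`).
#' @export
sum_abs <- function(v) {
  if (is.matrix(v)) rowSums(abs(v)) else sum(abs(v))
}

## Angles (degrees) between successive rows of an n x 3 matrix; length n-1.
successive_angles <- function(A) {
  n <- nrow(A)
  if (n < 2) ff_contract_error("need at least two vectors")
  nrm <- sqrt(rowSums(A^2))
  if (any(nrm < 1e-12))
    ff_data_error("angle undefined for a zero-norm vector")
  dot <- rowSums(A[-n, , drop = FALSE] * A[-1, , drop = FALSE])
  cosang <- pmin(1, pmax(-1, dot / (nrm[-n] * nrm[-1])))
  acos(cosang) * 180 / pi
}

#' Angle variation within a window
#'
#' Angle between successive acceleration vectors,
#' `acos(A_n . A_{n+1} / (|A_n| |A_{n+1}|))` in degrees.  A window of N
#' samples yields N-1 successive angles; the window statistic returned is
#' their maximum (a fall is a burst event, so a threshold reading matches
#' the largest single-sample direction jump).
#'
#' @param A_window `N x 3` matrix of acceleration vectors, `N >= 2`.
#' @param statistic `"max"` (default) or `"sum"`; the sum of successive
#'   angles over a clean rotation recovers the total rotated angle.
#' @return angle in degrees, in `[0, 180]` for `"max"`.
#' @export
angle_variation <- function(A_window, statistic = c("max", "sum")) {
  statistic <- match.arg(statistic)
  ang <- successive_angles(A_window)
  if (statistic == "max") max(ang) else sum(ang)
}

#' Orientation change across an event
#'
#' Angle between the mean acceleration vectors of a window before and a
#' window after a suspected fall:
#' `acos(mean(A_b) . mean(A_e) / (|mean(A_b)| |mean(A_e)|))`, degrees.
#'
#' @param A_before,A_after matrices of acceleration vectors.
#' @return angle in degrees in `[0, 180]`.
#' @export
orientation_change <- function(A_before, A_after) {
  if (!nrow(A_before) || !nrow(A_after))
    ff_contract_error("both windows must be nonempty")
  mb <- colMeans(A_before); me <- colMeans(A_after)
  nb <- sqrt(sum(mb^2)); ne <- sqrt(sum(me^2))
  if (nb < 1e-12 || ne < 1e-12)
    ff_data_error("orientation change undefined for zero mean vector")
  acos(pmin(1, pmax(-1, sum(mb * me) / (nb * ne)))) * 180 / pi
}

#' Angular acceleration by forward differences
#'
#' `GA_n = (G_{n+1} - G_n) / dt`, componentwise; length `N - 1`.
#'
#' @param G_window `N x 3` matrix of angular velocity vectors (rad/s).
#' @param dt sample interval in seconds.
#' @return `(N-1) x 3` matrix in rad/s^2.
#' @export
angular_acceleration <- function(G_window, dt) {
  if (nrow(G_window) < 2) ff_contract_error("need at least two samples")
  diff(G_window) / dt
}

#' Threshold set for the feature cascade
#'
#' @param sv SV threshold in g; `av` angle variation in degrees; `ca`
#'   orientation change in degrees; `sv_g` in rad/s; `sv_ga` in rad/s^2.
#' @return a named list of class `alg2_thresholds`.
#' @export
alg2_thresholds <- function(sv, av, ca, sv_g, sv_ga) {
  structure(list(sv = sv, av = av, ca = ca, sv_g = sv_g, sv_ga = sv_ga),
            class = "alg2_thresholds")
}

## Per-window feature table, threshold-independent.  One row per sliding
## window that admits the CA after-window; columns: i_sv (1-based sample of
## the window SV max), t_sv, sv_max, av, ca, sv_g, sv_ga.
alg2_featurize <- function(rec, cutoff = 5, window_s = 2, stride_s = 0.5) {
  fs <- rec$fs; n <- nrow(rec$A); dt <- 1 / fs
  Af <- apply(rec$A, 2, lowpass, fs = fs, cutoff = cutoff)
  Gf <- apply(rec$G, 2, lowpass, fs = fs, cutoff = cutoff)
  sv <- rowSums(abs(Af))
  svg <- rowSums(abs(Gf))
  svga <- c(rowSums(abs(diff(Gf) / dt)), 0)  # value at i = |G[i+1]-G[i]|/dt
  t <- rec$t
  win <- sliding_windows(n, window_s, stride_s, fs)
  rows <- lapply(seq_len(nrow(win)), function(k) {
    idx <- window_slice(win$start[k], win$end[k])
    i_sv <- idx[which.max(sv[idx])]
    t_sv <- t[i_sv]
    if (t_sv + 2 > t[n] + 1e-9) return(NULL)  # CA after-window must fit
    sub <- which(t >= t_sv - 1 & t <= t_sv + 1)
    before <- which(t >= t_sv - 2 & t < t_sv + 1)
    after  <- which(t >= t_sv + 1 & t < t_sv + 2)
    data.frame(
      i_sv = i_sv, t_sv = t_sv, sv_max = sv[i_sv],
      av = max(successive_angles(Af[sub, , drop = FALSE])),
      ca = orientation_change(Af[before, , drop = FALSE],
                              Af[after, , drop = FALSE]),
      sv_g = max(svg[sub]),
      sv_ga = max(svga[sub[-length(sub)]]))
  })
  do.call(rbind, c(rows, list(data.frame(i_sv = integer(0), t_sv = numeric(0),
                                         sv_max = numeric(0), av = numeric(0),
                                         ca = numeric(0), sv_g = numeric(0),
                                         sv_ga = numeric(0)))))
}

alg2_decide <- function(feat, th) {
  hit <- feat$sv_max > th$sv & feat$av > th$av & feat$ca > th$ca &
    feat$sv_g > th$sv_g & feat$sv_ga > th$sv_ga
  merge_detections(sort(unique(feat$t_sv[hit])), refractory_s = 1)
}

#' Algorithm 2 fall detector (five-feature threshold cascade)
#'
#' Low-pass filters acceleration and angular velocity, slides a 2 s
#' window, and in each window compares the SV maximum with its threshold;
#' only if it is exceeded are the remaining four features computed from
#' sub-windows around the SV peak time `t_SV` -- angle variation, SV_G and
#' SV_GA over `(t_SV - 1, t_SV + 1)` s, and orientation change between
#' `(t_SV - 2, t_SV + 1)` and `(t_SV + 1, t_SV + 2)` s.  A fall is
#' detected at `t_SV` when all five exceed their thresholds; detections
#' within 1 s are merged.  Windows whose CA after-window would extend past
#' the recording end are skipped.
#'
#' The returned vector carries an attribute `n_feature_evals`: the number
#' of windows for which the sub-window features were evaluated (the
#' cascade short-circuits when the SV gate fails).
#'
#' @param rec a preprocessed [imu_recording].
#' @param th an [alg2_thresholds].
#' @param cutoff low-pass cutoff in Hz (zero-phase Butterworth, order 4).
#' @param window_s,stride_s sliding-window width and stride in seconds.
#' @return numeric vector of detection times (s), with attribute
#'   `n_feature_evals`.
#' @export
detect_alg2 <- function(rec, th, cutoff = 5, window_s = 2, stride_s = 0.5) {
  fs <- rec$fs; n <- nrow(rec$A); dt <- 1 / fs
  Af <- apply(rec$A, 2, lowpass, fs = fs, cutoff = cutoff)
  Gf <- apply(rec$G, 2, lowpass, fs = fs, cutoff = cutoff)
  sv <- rowSums(abs(Af))
  t <- rec$t
  win <- sliding_windows(n, window_s, stride_s, fs)
  times <- numeric(0); n_evals <- 0L
  for (k in seq_len(nrow(win))) {
    idx <- window_slice(win$start[k], win$end[k])
    i_sv <- idx[which.max(sv[idx])]
    if (sv[i_sv] <= th$sv) next          # SV gate: short-circuit
    t_sv <- t[i_sv]
    if (t_sv + 2 > t[n] + 1e-9) next     # CA after-window must fit
    n_evals <- n_evals + 1L
    sub <- which(t >= t_sv - 1 & t <= t_sv + 1)
    av <- max(successive_angles(Af[sub, , drop = FALSE]))
    if (av <= th$av) next
    before <- which(t >= t_sv - 2 & t < t_sv + 1)
    after  <- which(t >= t_sv + 1 & t < t_sv + 2)
    ca <- orientation_change(Af[before, , drop = FALSE],
                             Af[after, , drop = FALSE])
    if (ca <= th$ca) next
    svg <- max(rowSums(abs(Gf[sub, , drop = FALSE])))
    if (svg <= th$sv_g) next
    ga <- angular_acceleration(Gf[sub, , drop = FALSE], dt)
    if (max(rowSums(abs(ga))) <= th$sv_ga) next
    times <- c(times, t_sv)
  }
  out <- merge_detections(sort(unique(times)), refractory_s = 1)
  attr(out, "n_feature_evals") <- n_evals
  out
}
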