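## Seeded synthetic IMU generator.
##
## Fall kinematics are scripted piecewise (smoothstep-blended phases), not
## physics-simulated: the detectors consume signal shape, and scripted
## shapes give controllable ground truth.  The gravity direction rotates
## in a single body plane per recording, which keeps the vertical
## projection and orientation-change geometry analytically checkable, and
## the gyroscope output is the exact analytic derivative of the scripted
## rotation, so integrating it recovers the gravity tilt (what makes the
## complementary-filter fusion testable).

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

## Rotation profile: angle phi(t) (rad) ramping 0 -> delta over
## [t0, t0 + T] with a smoothstep.  The rate is the exact discrete
## difference of phi at the sampling grid, so the discrete integral of
## the emitted gyro signal reproduces the scripted tilt sample by sample
## (which is what makes complementary-filter fusion exactly testable).
rotation_profile <- function(t, t0, T, delta) {
  u <- (t - t0) / T
  phi <- delta * smoothstep(u)
  fs <- 1 / (t[2] - t[1])
  dphi <- c(phi[1], diff(phi)) * fs
  list(phi = phi, dphi = dphi)
}

## Frame vectors for a single-plane rotation of the gravity direction.
## axis "pitch": gravity tilts in the y-z plane and the gyro y-axis sees
## the rate; "roll": x-z plane, gyro z-axis.
rotation_frame <- function(phi, axis = c("pitch", "roll")) {
  axis <- match.arg(axis)
  n <- length(phi); z <- numeric(n)
  if (axis == "pitch") {
    u <- cbind(z, -sin(phi), cos(phi))   # gravity direction in body frame
    v <- cbind(z, cos(phi), sin(phi))    # transverse, in the rotation plane
    g_col <- 2L
  } else {
    u <- cbind(sin(phi), z, cos(phi))
    v <- cbind(cos(phi), z, -sin(phi))
    g_col <- 3L
  }
  list(u = u, v = v, g_col = g_col)
}

#' Fall scenario
#'
#' Parameters of the canonical fall waveform: roughly 1 g while upright, a
#' free-fall dip of the acceleration magnitude, a sharp impact spike with
#' a short damped bounce, post-impact inactivity at 1 g, and a net change
#' of the gravity direction (the subject ends up lying).  Defaults are
#' chosen to look like a waist-worn sensor in a hard forward fall: a
#' 3.2 g impact whose vertical component is about 2.4 g, a dip to 0.2 g,
#' a 90 degree orientation change at a peak angular rate of 6 rad/s, and
#' 3.5 s of lying still afterwards.
#'
#' @param pre_fall_s upright duration before the fall (s).
#' @param freefall_depth_g minimum SMV during the dip (g).
#' @param freefall_dur_s dip duration (s).
#' @param impact_peak_g maximum SMV at impact (g).
#' @param impact_vertical_g vertical (along-gravity) component of the
#'   impact peak (g); the transverse remainder is what makes the
#'   acceleration direction jump at impact.
#' @param impact_dur_s impact pulse width (s).
#' @param rebound_s duration after the impact pulse during which the
#'   vertical component stays near the free-fall depth while the body
#'   bounces transversally (s); this low-magnitude, direction-flipping
#'   interval is what produces the large per-sample direction jumps seen
#'   at real impacts.
#' @param inactivity_s post-impact quiet duration (s).
#' @param orientation_change_deg net rotation of the gravity direction.
#' @param gyro_burst_rads peak angular rate of the scripted rotation
#'   (rad/s); the rotation duration is derived from it.
#' @param bounce_amp_g,bounce_freq_hz,bounce_decay_s damped transverse
#'   oscillation right after the impact (body/mattress bounce); this is
#'   what gives real-looking per-sample direction jumps.
#' @param noise_sd_g accelerometer white-noise sd per axis (g).
#' @param gyro_noise_sd gyroscope white-noise sd per axis (rad/s).
#' @param gyro_drift_rads constant gyroscope bias per axis (rad/s).
#' @param axis rotation plane: `"pitch"` (gyro y) or `"roll"` (gyro z).
#' @return a named list of class `fall_scenario`.
#' @export
fall_scenario <- function(pre_fall_s = 3, freefall_depth_g = 0.2,
                          freefall_dur_s = 0.35, impact_peak_g = 3.2,
                          impact_vertical_g = 2.4, impact_dur_s = 0.25,
                          rebound_s = 0.35, inactivity_s = 3.5,
                          orientation_change_deg = 90,
                          gyro_burst_rads = 6.5, bounce_amp_g = 1.4,
                          bounce_freq_hz = 4.5, bounce_decay_s = 0.18,
                          noise_sd_g = 0.03, gyro_noise_sd = 0.02,
                          gyro_drift_rads = 0, axis = "pitch") {
  sc <- as.list(environment())
  if (sc$impact_peak_g <= 1) ff_config_error("impact_peak_g must exceed 1 g")
  if (sc$freefall_depth_g >= 1) ff_config_error("freefall_depth_g must be below 1 g")
  if (sc$impact_vertical_g >= sc$impact_peak_g)
    ff_config_error("impact_vertical_g must be below impact_peak_g")
  if (any(c(sc$pre_fall_s, sc$freefall_dur_s, sc$impact_dur_s,
            sc$inactivity_s) <= 0))
    ff_config_error("durations must be positive")
  structure(sc, class = "fall_scenario")
}

#' Generate a synthetic fall recording
#'
#' Builds the scripted fall waveform of a [fall_scenario]: SMV passes
#' ~1 g, dips to `freefall_depth_g`, peaks at `impact_peak_g`, and settles
#' to 1 g during the inactivity phase; the gravity direction rotates by
#' `orientation_change_deg` in a single plane, and the gyroscope is the
#' exact derivative of that rotation (plus optional bias and noise).
#' The ground-truth impact time is attached as attribute `impact_time`,
#' the scripted tilt-angle series as attribute `phi`.
#'
#' @param sc a [fall_scenario].
#' @param fs sampling rate in Hz (default 50).
#' @param seed optional integer seed for the additive noise.
#' @param label recording label (must start with `"fall"`).
#' @param subject_id subject identifier.
#' @return an [imu_recording] with attributes `impact_time` and `phi`.
#' @export
generate_fall <- function(sc = fall_scenario(), fs = 50, seed = NULL,
                          label = "fall_forward", subject_id = "sim") {
  if (!is.null(seed)) return(with_seed(seed, generate_fall(
    sc, fs, NULL, label, subject_id)))
  ff_onset <- 0.1                      # free-fall dip onset (s)
  settle <- 0.3                        # base recovery after impact (s)
  t_ff <- sc$pre_fall_s                # free-fall start
  t_imp <- t_ff + sc$freefall_dur_s    # impact pulse start
  t_rec <- t_imp + sc$impact_dur_s + sc$rebound_s   # base recovery start
  total <- sc$pre_fall_s + sc$freefall_dur_s + sc$impact_dur_s +
    sc$rebound_s + sc$inactivity_s
  n <- as.integer(round(total * fs))
  t <- (seq_len(n) - 1) / fs

  ## base: magnitude of the along-gravity component; stays at the
  ## free-fall depth through the rebound interval, then recovers to 1 g
  base <- rep(1, n)
  base <- base - (1 - sc$freefall_depth_g) * smoothstep((t - t_ff) / ff_onset)
  base <- base + (1 - sc$freefall_depth_g) * smoothstep((t - t_rec) / settle)

  ## impact pulse: vertical and transverse half-sine components
  inpulse <- t >= t_imp & t <= t_imp + sc$impact_dur_s
  shape <- numeric(n)
  shape[inpulse] <- sin(pi * (t[inpulse] - t_imp) / sc$impact_dur_s)
  i_peak <- which.max(shape)
  pu_amp <- sc$impact_vertical_g - base[i_peak]
  pv_amp <- sqrt(sc$impact_peak_g^2 - sc$impact_vertical_g^2)
  vert <- base + pu_amp * shape
  ## post-impact damped transverse bounce
  t_b <- t_imp + sc$impact_dur_s
  after <- t >= t_b
  bounce <- numeric(n)
  bounce[after] <- sc$bounce_amp_g * exp(-(t[after] - t_b) / sc$bounce_decay_s) *
    sin(2 * pi * sc$bounce_freq_hz * (t[after] - t_b))
  trans <- pv_amp * shape + bounce

  ## scripted rotation of the gravity direction
  delta <- sc$orientation_change_deg * pi / 180
  T_rot <- 1.5 * abs(delta) / sc$gyro_burst_rads
  rot <- rotation_profile(t, t_ff, T_rot, delta)
  fr <- rotation_frame(rot$phi, sc$axis)

  A <- fr$u * vert + fr$v * trans
  G <- matrix(0, n, 3)
  G[, fr$g_col] <- rot$dphi
  A <- A + matrix(stats::rnorm(3 * n, sd = sc$noise_sd_g), n, 3)
  G <- G + sc$gyro_drift_rads +
    matrix(stats::rnorm(3 * n, sd = sc$gyro_noise_sd), n, 3)

  rec <- imu_recording(A, G, fs = fs, label = label, is_fall = TRUE,
                       subject_id = subject_id)
  attr(rec, "impact_time") <- t[i_peak]
  attr(rec, "phi") <- rot$phi
  attr(rec, "scenario") <- sc
  rec
}

#' ADL scenario
#'
#' Parameters of a scripted activity of daily living.  Kinds and their
#' signatures: `walking` / `jogging` -- periodic SMV oscillation around
#' 1 g (fundamental 1--3 Hz) with a small transverse sway; `jumping` --
#' repeated landing spikes that may exceed 2 g separated by flight-phase
#' dips, with no post-spike inactivity; `sitting` -- one moderate
#' transient with a small tilt; `lying` -- a slow large orientation change
#' with the SMV never leaving the vicinity of 1 g; `standing` -- 1 g plus
#' noise.
#'
#' @param kind one of `"walking"`, `"jogging"`, `"jumping"`, `"sitting"`,
#'   `"lying"`, `"standing"`.
#' @param freq_hz fundamental frequency for periodic kinds (Hz).
#' @param amp_g SMV oscillation amplitude for periodic kinds (g).
#' @param peak_g landing-spike peak for `jumping` (g).
#' @param period_s jump period (s).
#' @param tilt_deg orientation change for `sitting` / `lying` (degrees).
#' @param tilt_dur_s duration of that orientation change (s).
#' @param noise_sd_g,gyro_noise_sd,gyro_drift_rads noise model, as in
#'   [fall_scenario].
#' @param axis rotation plane for the tilting kinds.
#' @return a named list of class `adl_scenario`.
#' @export
adl_scenario <- function(kind = c("walking", "jogging", "jumping", "sitting",
                                  "lying", "standing"),
                         freq_hz = NULL, amp_g = NULL, peak_g = 3,
                         period_s = 0.6, tilt_deg = NULL, tilt_dur_s = NULL,
                         noise_sd_g = 0.03, gyro_noise_sd = 0.02,
                         gyro_drift_rads = 0, axis = "pitch") {
  kind <- match.arg(kind)
  freq_hz <- freq_hz %||% switch(kind, walking = 2, jogging = 2.8, 1)
  amp_g <- amp_g %||% switch(kind, walking = 0.35, jogging = 0.45, 0)
  tilt_deg <- tilt_deg %||% switch(kind, sitting = 15, lying = 90, 0)
  tilt_dur_s <- tilt_dur_s %||% switch(kind, sitting = 1.5, lying = 4, 1)
  if (kind %in% c("walking", "jogging") && (freq_hz < 1 || freq_hz > 3))
    ff_config_error("walking/jogging fundamental must lie in 1-3 Hz")
  structure(list(kind = kind, freq_hz = freq_hz, amp_g = amp_g,
                 peak_g = peak_g, period_s = period_s, tilt_deg = tilt_deg,
                 tilt_dur_s = tilt_dur_s, noise_sd_g = noise_sd_g,
                 gyro_noise_sd = gyro_noise_sd,
                 gyro_drift_rads = gyro_drift_rads, axis = axis),
            class = "adl_scenario")
}

#' Generate a synthetic ADL recording
#'
#' @param sc an [adl_scenario].
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds (>= 2).
#' @param seed optional integer seed.
#' @param subject_id subject identifier.
#' @return an [imu_recording] (with attribute `phi` for tilting kinds).
#' @export
generate_adl <- function(sc = adl_scenario("walking"), fs = 50,
                         duration_s = 8, seed = NULL, subject_id = "sim") {
  if (!is.null(seed)) return(with_seed(seed, generate_adl(
    sc, fs, duration_s, NULL, subject_id)))
  if (duration_s < 2) ff_contract_error("duration must be at least 2 s")
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  vert <- rep(1, n); trans <- numeric(n)
  phi <- numeric(n); dphi <- numeric(n); axis <- sc$axis

  if (sc$kind %in% c("walking", "jogging")) {
    vert <- 1 + sc$amp_g * sin(2 * pi * sc$freq_hz * t)
    trans <- 0.08 * sin(2 * pi * sc$freq_hz * t + pi / 3)
  } else if (sc$kind == "jumping") {
    ## per period: flight dip then landing spike
    ph <- (t %% sc$period_s) / sc$period_s
    dip <- ph < 0.4
    vert[dip] <- 1 - 0.55 * sin(pi * ph[dip] / 0.4)
    spike <- ph >= 0.4 & ph < 0.7
    vert[spike] <- 1 + (sc$peak_g - 1) * sin(pi * (ph[spike] - 0.4) / 0.3)
  } else if (sc$kind == "sitting") {
    mid <- duration_s / 2
    vert <- 1 - 0.2 * exp(-((t - mid) / 0.25)^2) +
      0.35 * exp(-((t - mid - 0.45) / 0.25)^2)
    rot <- rotation_profile(t, mid - sc$tilt_dur_s / 2, sc$tilt_dur_s,
                            sc$tilt_deg * pi / 180)
    phi <- rot$phi; dphi <- rot$dphi
  } else if (sc$kind == "lying") {
    rot <- rotation_profile(t, duration_s / 2 - sc$tilt_dur_s / 2,
                            sc$tilt_dur_s, sc$tilt_deg * pi / 180)
    phi <- rot$phi; dphi <- rot$dphi
    vert <- 1 + 0.08 * sin(2 * pi * 0.8 * t) * (dphi > 0)
  }                                          # standing: 1 g + noise

  fr <- rotation_frame(phi, axis)
  A <- fr$u * vert + fr$v * trans
  G <- matrix(0, n, 3); G[, fr$g_col] <- dphi
  A <- A + matrix(stats::rnorm(3 * n, sd = sc$noise_sd_g), n, 3)
  G <- G + sc$gyro_drift_rads +
    matrix(stats::rnorm(3 * n, sd = sc$gyro_noise_sd), n, 3)
  rec <- imu_recording(A, G, fs = fs, label = sc$kind, is_fall = FALSE,
                       subject_id = subject_id)
  attr(rec, "phi") <- phi
  attr(rec, "scenario") <- sc
  rec
}

## Default class mixes for generated corpora.
FALL_MIX <- c(fall_forward = 0.4, fall_backward = 0.3, fall_lateral = 0.3)
ADL_MIX <- c(walking = 0.25, jogging = 0.15, jumping = 0.15, sitting = 0.15,
             lying = 0.15, standing = 0.15)

## Per-recording jittered fall scenario, drawn from the current RNG.
jitter_fall_scenario <- function(subtype) {
  peak <- stats::runif(1, 3.0, 3.5)
  fall_scenario(
    pre_fall_s = stats::runif(1, 2.8, 3.5),
    freefall_depth_g = stats::runif(1, 0.15, 0.28),
    freefall_dur_s = stats::runif(1, 0.3, 0.45),
    impact_peak_g = peak,
    impact_vertical_g = 0.75 * peak,
    inactivity_s = stats::runif(1, 3.3, 4.0),
    orientation_change_deg =
      (if (subtype == "fall_backward") -1 else 1) * stats::runif(1, 80, 100),
    gyro_burst_rads = stats::runif(1, 6.5, 8),
    axis = if (subtype == "fall_lateral") "roll" else "pitch")
}

jitter_adl_scenario <- function(kind) {
  switch(kind,
    walking = adl_scenario("walking", freq_hz = stats::runif(1, 1.8, 2.2),
                           amp_g = stats::runif(1, 0.3, 0.4)),
    jogging = adl_scenario("jogging", freq_hz = stats::runif(1, 2.6, 3.0),
                           amp_g = stats::runif(1, 0.4, 0.5)),
    jumping = adl_scenario("jumping", peak_g = stats::runif(1, 2.8, 3.3),
                           period_s = stats::runif(1, 0.55, 0.7)),
    sitting = adl_scenario("sitting", tilt_deg = stats::runif(1, 10, 20)),
    lying = adl_scenario("lying", tilt_deg = stats::runif(1, 75, 110)),
    adl_scenario(kind))
}

#' Generate a labelled synthetic corpus
#'
#' Emits `n_falls` fall recordings and `n_adls` ADL recordings with
#' per-recording parameter jitter.  Every recording gets its own seed
#' derived from the master seed, so the corpus is reproducible and
#' changing one recording's seed changes only that recording.
#'
#' @param n_falls,n_adls class counts.
#' @param fall_mix,adl_mix named probability vectors over subtypes.
#' @param fs sampling rate in Hz.
#' @param adl_duration_s ADL recording length (s).
#' @param seed master seed.
#' @return list with `recordings` (list of [imu_recording]) and
#'   `manifest` (data.frame: index, label, is_fall, seed, n_samples).
#' @export
generate_dataset <- function(n_falls, n_adls, fall_mix = FALL_MIX,
                             adl_mix = ADL_MIX, fs = 50,
                             adl_duration_s = 8, seed = 1) {
  stopifnot(n_falls >= 0, n_adls >= 0)
  counts <- function(n, mix) {
    if (n == 0) return(integer(0))
    k <- floor(n * mix / sum(mix))
    rem <- n - sum(k)
    if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1L
    rep(names(mix), k)
  }
  fall_types <- counts(n_falls, fall_mix)
  adl_types <- counts(n_adls, adl_mix)
  labels <- c(fall_types, adl_types)
  n_tot <- length(labels)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_tot))
  recordings <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    recordings[[i]] <- with_seed(seeds[i], {
      if (i <= n_falls) {
        generate_fall(jitter_fall_scenario(labels[i]), fs = fs,
                      label = labels[i],
                      subject_id = sprintf("sim%03d", i))
      } else {
        generate_adl(jitter_adl_scenario(labels[i]), fs = fs,
                     duration_s = adl_duration_s,
                     subject_id = sprintf("sim%03d", i))
      }
    })
  }
  manifest <- data.frame(
    index = seq_len(n_tot), label = labels,
    is_fall = seq_len(n_tot) <= n_falls, seed = seeds,
    n_samples = vapply(recordings, function(r) nrow(r$A), integer(1)))
  list(recordings = recordings, manifest = manifest)
}

#' Write a corpus to a directory of generic-dialect CSV files
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the manifest with a `file` column, invisibly; also written as
#'   `manifest.csv`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$file <- sprintf("%s_%03d.csv",
                      ifelse(man$is_fall, "FALL", "ADL"), man$index)
  for (i in seq_len(nrow(man)))
    write_recording(dataset$recordings[[i]], file.path(dir, man$file[i]))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Load a corpus written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return list with `recordings` and `manifest`.
#' @export
load_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(man$file, function(f)
    load_recording(file.path(dir, f), dialect("generic")))
  list(recordings = recs, manifest = man)
}
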