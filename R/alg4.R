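## Algorithm 4: single-accelerometer detection.  A finite state machine
## over the acceleration magnitude models the canonical fall phases
## (impact peak above a threshold, post-impact inactivity near 1 g); each
## candidate's surrounding segment yields time/frequency features that a
## kNN classifier accepts or rejects.

#' Parameters of the FSM + kNN detector
#'
#' @param smv_peak impact peak threshold in g.
#' @param at_low,at_high inactivity-check interval in ms after the peak
#'   (`at_low < at_high`).
#' @param fs_low,fs_high feature-extraction segment in ms relative to the
#'   peak (`fs_low < 0 < fs_high`, so the segment includes the pre-impact
#'   free-fall dip).
#' @param k number of nearest neighbours; odd, so binary votes cannot tie.
#' @param inactivity_band inactivity tolerance in g: the mean of
#'   `|SMV - 1|` over the check window must stay below this half-width
#'   around the 1 g rest value (default 0.15 g).
#' @return a named list of class `alg4_params`.
#' @export
alg4_params <- function(smv_peak, at_low, at_high, fs_low, fs_high, k,
                        inactivity_band = 0.15) {
  if (at_low >= at_high) ff_config_error("at_low must be below at_high")
  if (!(fs_low < 0 && fs_high > 0))
    ff_config_error("fs_low must be negative and fs_high positive")
  if (k < 1 || k %% 2 == 0) ff_config_error("k must be odd and >= 1")
  structure(list(smv_peak = smv_peak, at_low = at_low, at_high = at_high,
                 fs_low = fs_low, fs_high = fs_high, k = as.integer(k),
                 inactivity_band = inactivity_band),
            class = "alg4_params")
}

#' FSM candidate detection
#'
#' States: IDLE until SMV exceeds `smv_peak`; the local maximum of the
#' exceedance run is the impact peak; the machine then waits `at_low` ms
#' and checks inactivity over `[peak + at_low, peak + at_high]` -- the
#' mean of `|SMV - 1 g|` must stay below `inactivity_band` (rest gravity
#' is 1 g).  A passing peak is emitted as a candidate.  Whether the check
#' passes or not, the machine stays busy until `peak + at_high` before
#' re-arming, so consecutive candidate peaks are separated by more than
#' the check horizon.  Peaks whose check window or feature segment leaves
#' the recording are dropped.
#'
#' @param smv nonnegative acceleration magnitude sequence (g).
#' @param fs sampling rate in Hz.
#' @param p an [alg4_params].
#' @return data.frame of candidates: `peak_index` (1-based), `peak_time`
#'   (s), `peak_value` (g), `seg_start`, `seg_end` (0-based half-open
#'   feature segment).
#' @export
fsm_candidates <- function(smv, fs, p) {
  n <- length(smv)
  at_lo <- as.integer(round(p$at_low / 1000 * fs))
  at_hi <- as.integer(round(p$at_high / 1000 * fs))
  fs_lo <- as.integer(round(p$fs_low / 1000 * fs))
  fs_hi <- as.integer(round(p$fs_high / 1000 * fs))
  out <- data.frame(peak_index = integer(0), peak_time = numeric(0),
                    peak_value = numeric(0), seg_start = integer(0),
                    seg_end = integer(0))
  above <- smv > p$smv_peak
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  busy_until <- -Inf    # sample index until which the FSM is occupied
  for (j in which(r$values)) {
    run <- starts[j]:ends[j]
    peak <- run[which.max(smv[run])]
    if (peak <= busy_until) next
    busy_until <- peak + at_hi
    w_from <- peak + at_lo; w_to <- peak + at_hi
    if (w_to > n) next                       # check window leaves recording
    if (mean(abs(smv[w_from:w_to] - 1)) >= p$inactivity_band) next
    seg_start <- peak + fs_lo; seg_end <- peak + fs_hi
    if (seg_start < 1L || seg_end > n) next  # feature segment leaves recording
    out <- rbind(out, data.frame(
      peak_index = peak, peak_time = (peak - 1) / fs, peak_value = smv[peak],
      seg_start = seg_start - 1L, seg_end = seg_end))
  }
  out
}

#' Time/frequency features of an SMV segment
#'
#' Fixed-order 11-feature vector computed from the acceleration magnitude
#' alone: mean, standard deviation, min, max, range, skewness, excess
#' kurtosis, signal magnitude area (mean of `|SMV - 1|`), count of samples
#' above `smv_peak`, dominant frequency of the linearly detrended
#' periodogram (Hz), and the fraction of spectral energy below 5 Hz.
#' The exact feature set behind the published detector is not public;
#' this list is a stated stand-in covering the same time- and
#' frequency-domain aspects and computable from a single accelerometer.
#'
#' @param smv_segment SMV segment (g), at least 8 samples.
#' @param fs sampling rate in Hz.
#' @param smv_peak threshold used by the exceedance-count feature.
#' @return named numeric vector of length 11.
#' @export
extract_features <- function(smv_segment, fs, smv_peak = 1.8) {
  x <- smv_segment
  n <- length(x)
  if (n < 8) ff_contract_error("feature segment must have >= 8 samples")
  m <- mean(x); s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 < 1e-24) 0 else mean((x - m)^3) / m2^1.5
  kurt <- if (m2 < 1e-24) 0 else mean((x - m)^4) / m2^2 - 3
  ## periodogram of the linearly detrended segment, DC excluded
  tt <- seq_len(n)
  y <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  P <- Mod(stats::fft(y))^2
  nh <- floor(n / 2)
  P <- P[2:(nh + 1)]
  freqs <- (1:nh) * fs / n
  tot <- sum(P)
  domfreq <- if (tot < 1e-18) 0 else freqs[which.max(P)]
  lowfrac <- if (tot < 1e-18) 1 else sum(P[freqs < 5]) / tot
  c(mean = m, sd = s, min = min(x), max = max(x), range = max(x) - min(x),
    skewness = skew, kurtosis = kurt, sma = mean(abs(x - 1)),
    n_above = sum(x > smv_peak), domfreq = domfreq, lowfreq_frac = lowfrac)
}

#' Fit a kNN model
#'
#' Stores z-score-standardized training features (constant features get
#' unit scale) and their labels.  Both classes must be present.
#'
#' @param X numeric matrix of feature vectors (rows).
#' @param y logical or factor labels (TRUE / "fall" = fall).
#' @param k default neighbour count used by [knn_classify()].
#' @return an object of class `knn_model`.
#' @export
knn_fit <- function(X, y, k = 7) {
  X <- as.matrix(X)
  y <- if (is.logical(y)) y else y == "fall"
  if (nrow(X) != length(y)) ff_contract_error("X rows and y must match")
  if (length(unique(y)) < 2)
    ff_data_error("training set must contain both classes")
  if (nrow(X) < k) ff_contract_error("need at least k training points")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  structure(list(Z = Z, y = y, center = ctr, scale = scl, k = as.integer(k)),
            class = "knn_model")
}

#' Classify feature vectors with a fitted kNN model
#'
#' Majority label among the `k` nearest training points by Euclidean
#' distance in the standardized feature space.  Odd `k` precludes binary
#' vote ties; distance ties at the k-th position are broken by lower
#' training index.
#'
#' @param model a [knn_fit()] result.
#' @param x a feature vector, or a matrix of rows to classify.
#' @param k neighbour count (default: the model's `k`).
#' @return logical vector: `TRUE` for fall.
#' @export
knn_classify <- function(model, x, k = model$k) {
  if (k > nrow(model$Z)) ff_contract_error("k exceeds the training size")
  if (is.null(dim(x))) x <- matrix(x, 1)
  Z <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  apply(Z, 1, function(z) {
    d <- sqrt(colSums((t(model$Z) - z)^2))
    nn <- order(d)[seq_len(k)]      # stable: ties go to lower index
    sum(model$y[nn]) * 2 > k
  })
}

## Training set for the per-fold kNN refit: one feature vector per
## recording, from the segment around the global SMV maximum (clipped to
## the recording), labelled by the recording's class.  Guarantees both
## classes are represented regardless of which FSM candidates fire.
alg4_training_set <- function(recordings, p) {
  feats <- list(); labels <- logical(0)
  for (rec in recordings) {
    smv <- magnitude(rec$A)
    fv <- alg4_peak_features(smv, rec$fs, p)
    if (is.null(fv)) next
    feats[[length(feats) + 1L]] <- fv
    labels <- c(labels, rec$is_fall)
  }
  list(X = do.call(rbind, feats), y = labels)
}

alg4_peak_features <- function(smv, fs, p) {
  n <- length(smv)
  peak <- which.max(smv)
  lo <- max(1L, peak + as.integer(round(p$fs_low / 1000 * fs)))
  hi <- min(n, peak + as.integer(round(p$fs_high / 1000 * fs)))
  if (hi - lo + 1L < 8L) return(NULL)
  extract_features(smv[lo:hi], fs, p$smv_peak)
}

#' Fit the Algorithm 4 classifier on labelled recordings
#'
#' @param recordings list of labelled [imu_recording]s (both classes).
#' @param p an [alg4_params].
#' @return a `knn_model` with `k = p$k`.
#' @export
alg4_fit <- function(recordings, p) {
  tr <- alg4_training_set(recordings, p)
  if (is.null(tr$X) || nrow(tr$X) < p$k)
    ff_data_error("not enough usable training recordings")
  knn_fit(tr$X, tr$y, k = p$k)
}

#' Algorithm 4 fall detector (FSM + kNN)
#'
#' Runs [fsm_candidates()] on the acceleration magnitude, extracts the
#' 11-feature vector from each candidate's segment
#' `[peak + fs_low, peak + fs_high]`, and keeps the candidates the kNN
#' classifier labels as falls.
#'
#' @param rec a preprocessed [imu_recording].
#' @param p an [alg4_params].
#' @param model a fitted `knn_model` (see [alg4_fit()]).
#' @return numeric vector of detection times (s).
#' @export
detect_alg4 <- function(rec, p, model) {
  smv <- magnitude(rec$A)
  cand <- fsm_candidates(smv, rec$fs, p)
  if (!nrow(cand)) return(numeric(0))
  X <- t(vapply(seq_len(nrow(cand)), function(i) {
    idx <- window_slice(cand$seg_start[i], cand$seg_end[i])
    extract_features(smv[idx], rec$fs, p$smv_peak)
  }, numeric(11)))
  cand$peak_time[knn_classify(model, X, k = min(model$k, nrow(model$Z)))]
}
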