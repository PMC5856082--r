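## Shared fixture builders.  Everything is generated in code; no stored
## binary data.

## Minimal recording: constant 1 g on z, zero gyro.
const_rec <- function(n = 200, fs = 50, label = "standing") {
  imu_recording(cbind(0, 0, rep(1, n)), matrix(0, n, 3), fs = fs,
                label = label, is_fall = FALSE)
}

## Deterministic default fall / ADL at a given seed.
fixture_fall <- function(seed = 1, sc = fall_scenario()) {
  generate_fall(sc, fs = 50, seed = seed)
}
fixture_adl <- function(kind, seed = 1, duration_s = 8) {
  generate_adl(adl_scenario(kind), fs = 50, duration_s = duration_s,
               seed = seed)
}

## Small mixed corpus (deterministic): n_falls + n_adls recordings.
fixture_corpus <- function(n_falls = 10, n_adls = 20, seed = 42) {
  generate_dataset(n_falls, n_adls, seed = seed)$recordings
}

## Independent brute-force Friedman oracle (r = 1): explicit per-row
## ranking and the textbook tie-corrected chi-square formula
##   T = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A1 - C1),
## with A1 = sum of squared ranks and C1 = n k (k+1)^2 / 4.
friedman_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- t(apply(x, 1, rank))
  Rj <- colSums(R)
  A1 <- sum(R^2)
  C1 <- n * k * (k + 1)^2 / 4
  if (abs(A1 - C1) < 1e-12) return(0)
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A1 - C1)
}

## Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
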