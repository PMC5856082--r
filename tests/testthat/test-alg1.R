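test_that("accel_angles matches its closed forms", {
  expect_equal(unname(accel_angles(c(0, 0, 1))), c(0, 0))
  expect_equal(unname(accel_angles(c(1, 0, 0))), c(pi / 2, 0))
  expect_equal(unname(accel_angles(c(0, -1, 0))), c(0, pi / 2))
  expect_error(accel_angles(c(0, 0, 0)), class = "ff_data_error")
})

test_that("complementary_update reproduces its analytic limits", {
  ## alpha = 0: memoryless accelerometer estimate
  expect_equal(unname(complementary_update(c(0.7, -0.3), c(0, 0, 1),
                                           c(1, 2, 3), alpha = 0, dt = 0.02)),
               c(0, 0))
  ## alpha = 1: pure gyro integration
  st <- complementary_update(c(0.1, 0), c(0, 0, 1), c(0, 0, 0.5),
                             alpha = 1, dt = 0.02)
  expect_equal(unname(st), c(0.11, 0))
  ## fixed point at rest
  st2 <- complementary_update(c(0, 0), c(0, 0, 1), c(0, 0, 0),
                              alpha = 0.95, dt = 0.02)
  expect_equal(unname(st2), c(0, 0))
  expect_error(complementary_update(c(0, 0), c(0, 0, 1), c(0, 0, 0),
                                    alpha = 2, dt = 0.02),
               class = "ff_config_error")
})

test_that("filter limits hold over whole streams", {
  n <- 500
  A <- with_seed(1, matrix(rnorm(3 * n, sd = 0.3), n) + rep(c(0, 0, 1), each = n))
  G0 <- matrix(0, n, 3)
  ## alpha = 1, zero gyro: orientation constant whatever the accelerometer does
  th <- complementary_filter(A, G0, alpha = 1, dt = 0.02, init = c(0.2, -0.1))
  expect_equal(th[, 1], rep(0.2, n))
  expect_equal(th[, 2], rep(-0.1, n))
  ## alpha = 0: memoryless, equals accel_angles of the current sample
  th0 <- complementary_filter(A, G0, alpha = 0, dt = 0.02)
  ref <- t(apply(A, 1, accel_angles))
  expect_equal(unname(th0), unname(ref), tolerance = 1e-12)
})

test_that("constant gyro bias drift stays bounded by the analytic limit", {
  fs <- 50; n <- 60 * fs; bias <- 0.01; alpha <- 0.95
  A <- matrix(rep(c(0, 0, 1), each = n), n)   # stationary, flat
  G <- matrix(bias, n, 3)
  th <- complementary_filter(A, G, alpha = alpha, dt = 1 / fs)
  bound <- bias * (1 / fs) * alpha / (1 - alpha)
  expect_lt(max(abs(th[(n / 2):n, ])), bound + 1e-12)
  ## and the steady state actually approaches the bound, it is not just tiny
  expect_gt(max(abs(th[(n / 2):n, ])), 0.5 * bound)
})

test_that("vertical_acceleration projects onto the gravity axis", {
  expect_equal(vertical_acceleration(c(0, 0, 1), c(0, 0)), 1)
  expect_equal(vertical_acceleration(c(0.5, 0.5, 0.7), c(0, 0)), 0.7)
  expect_equal(vertical_acceleration(c(1, 0, 0), c(0, pi / 2)), 0,
               tolerance = 1e-12)
})

test_that("detect_two_phase needs both channels and both phases", {
  fs <- 50
  th <- default_thresholds("alg1")
  ## constant signals: zero swing, no detections
  expect_length(detect_two_phase(rep(1, 400), rep(1, 400), fs, th), 0)

  ## a generated fall is detected once, at the scripted impact
  rec <- fixture_fall(seed = 2)
  det <- detect_alg1(rec, th)
  expect_length(det, 1)
  expect_lt(abs(det - attr(rec, "impact_time")), 0.2)

  ## SMV shows both phases but AV is flat: the conjunction fails
  smv <- magnitude(rec$A)
  expect_length(detect_two_phase(smv, rep(1, length(smv)), fs, th), 0)

  expect_error(detect_two_phase(rep(1, 10), rep(1, 9), fs, th),
               class = "ff_contract_error")
})

test_that("detect_two_phase is translation-equivariant", {
  rec <- fixture_fall(seed = 4)
  th <- default_thresholds("alg1")
  smv <- magnitude(rec$A)
  theta <- complementary_filter(rec$A, rec$G, 0.95, dt = 1 / rec$fs)
  av <- vertical_acceleration(rec$A, theta)
  d0 <- detect_two_phase(smv, av, rec$fs, th)
  m <- 73
  d1 <- detect_two_phase(c(rep(1, m), smv), c(rep(av[1], m), av), rec$fs, th)
  expect_equal(d1, d0 + m / rec$fs, tolerance = 1e-9)
})

test_that("raising any alg1 threshold never increases detections", {
  recs <- lapply(1:6, fixture_fall)
  base <- list(smv_ff = 0.7, smv_ip = 1.5, av_ff = 0.3, av_ip = 0.7)
  count <- function(vals) {
    th <- do.call(alg1_thresholds, vals)
    sum(vapply(recs, function(r) length(detect_alg1(r, th)), numeric(1)))
  }
  for (nm in names(base)) {
    hi <- c(0, 0.15, 0.4)
    counts <- vapply(hi, function(h) {
      v <- base; v[[nm]] <- v[[nm]] + h; count(v)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), info = nm)
  }
})
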