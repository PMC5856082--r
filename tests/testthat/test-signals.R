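test_that("imu_recording validates its invariants", {
  A <- matrix(rnorm(30), 10); G <- matrix(rnorm(30), 10)
  rec <- imu_recording(A, G, fs = 50)
  expect_s3_class(rec, "imu_recording")
  expect_equal(rec$t, (0:9) / 50)
  expect_error(imu_recording(A, G[1:5, ], fs = 50), class = "ff_contract_error")
  expect_error(imu_recording(A, G, fs = -1), class = "ff_contract_error")
  expect_error(imu_recording(A, G, fs = 50, t = rev((0:9) / 50)),
               class = "ff_data_error")
  A[3, 2] <- NA
  expect_error(imu_recording(A, G, fs = 50), class = "ff_data_error")
})

test_that("load_recording round-trips the generic dialect", {
  dir <- withr::local_tempdir()
  rec <- fixture_fall(seed = 3)
  path <- file.path(dir, "FALL_001.csv")
  write_recording(rec, path)
  back <- load_recording(path)
  expect_equal(back$A, rec$A, tolerance = 1e-9)
  expect_equal(back$G, rec$G, tolerance = 1e-9)
  expect_equal(back$fs, rec$fs)
  expect_true(back$is_fall)
  expect_identical(back$label, rec$label)
})

test_that("load_recording applies dialect column maps and unit conversion", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.csv")
  t <- (0:6) / 100
  df <- data.frame(rel_time = t,
                   acc_x = rep(0, 7), acc_y = rep(0, 7),
                   acc_z = rep(9.80665, 7),
                   gyro_x = 0, gyro_y = 0, gyro_z = 0)
  write.csv(df, path, row.names = FALSE)
  rec <- load_recording(path, dialect("mobiact"), label = "walking")
  expect_equal(nrow(rec$A), 7L)
  expect_equal(rec$A[, 3], rep(1, 7))    # m/s^2 divided by standard gravity

  ## missing column names the column
  df2 <- df; names(df2)[4] <- "acc_zz"
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_recording(path, dialect("mobiact")), "acc_z",
               class = "ff_format_error")

  ## shuffled timestamps violate monotonicity
  df3 <- df; df3$rel_time <- sample(df3$rel_time)
  write.csv(df3, path, row.names = FALSE)
  expect_error(load_recording(path, dialect("mobiact")),
               class = "ff_data_error")
})

test_that("resample decimates as specified", {
  rec <- imu_recording(matrix(rnorm(3000), 1000), matrix(rnorm(3000), 1000),
                       fs = 100)
  out <- resample(rec, 50)
  expect_equal(out$fs, 50)
  expect_equal(nrow(out$A), 500L)

  ## constant signals are invariant at any rate
  n <- 803
  recc <- imu_recording(cbind(0.3, -0.2, 0.9)[rep(1, n), ],
                        matrix(0.1, n, 3), fs = 200)
  out200 <- resample(recc, 50)
  expect_equal(nrow(out200$A), ceiling(n / 4))
  expect_equal(unname(out200$A[, 1]), rep(0.3, ceiling(n / 4)),
               tolerance = 1e-6)

  expect_error(resample(rec, 200), class = "ff_config_error")
  expect_equal(resample(rec, 200, upsample = TRUE)$fs, 200)
})

test_that("resample and magnitude commute for pure subsampling", {
  rec <- fixture_fall(seed = 5)
  sub <- resample(rec, 25, antialias = FALSE)
  expect_equal(magnitude(sub$A),
               magnitude(rec$A)[seq(1, nrow(rec$A), by = 2)],
               tolerance = 1e-12)
})

test_that("median_filter3 matches its stated examples and reaches a binary root", {
  expect_equal(median_filter3(c(1, 10, 1)), c(1, 1, 1))
  expect_equal(median_filter3(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(median_filter3(rep(2.5, 9)), rep(2.5, 9))
  ## one pass is not idempotent on arbitrary binary signals (a pass can
  ## create a new isolated extremum), but iterating reaches a fixed point
  ## ("root" signal) in finitely many passes, on which the filter is
  ## idempotent
  for (i in 1:20) {
    x <- with_seed(i, sample(0:1, 40, replace = TRUE))
    root <- x
    for (pass in 1:40) {
      nxt <- median_filter3(root)
      if (identical(nxt, root)) break
      root <- nxt
    }
    expect_identical(median_filter3(root), root)
  }
})

test_that("magnitude is the Euclidean norm, invariant to axis permutation and sign", {
  expect_equal(magnitude(rbind(c(0, 0, 1))), 1)
  expect_equal(magnitude(rbind(c(0.6, 0.8, 0))), 1)
  expect_equal(magnitude(rbind(c(1, 1, 1))), sqrt(3))
  V <- with_seed(99, matrix(rnorm(3000), 1000))
  m0 <- magnitude(V)
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  for (p in perms) expect_equal(magnitude(V[, p]), m0)
  S <- with_seed(100, matrix(sample(c(-1, 1), 3000, TRUE), 1000))
  expect_equal(magnitude(V * S), m0)
})

test_that("sliding_windows enumerates half-open 0-based windows", {
  w1 <- sliding_windows(100, width_s = 1, stride_s = 1, fs = 50)
  expect_equal(nrow(w1), 2L)   # starts 0 and 50 both fit in 100 samples
  expect_equal(w1$start[1], 0L); expect_equal(w1$end[1], 50L)

  w2 <- sliding_windows(200, width_s = 2, stride_s = 0.5, fs = 50)
  expect_equal(w2$start, c(0L, 25L, 50L, 75L, 100L))
  expect_equal(nrow(w2), 5L)

  expect_equal(nrow(sliding_windows(10, 2, 0.5, 50)), 0L)
})

test_that("lowpass matches an independent reference implementation", {
  ## input/output pair frozen from scipy.signal.butter(4, 0.2) +
  ## filtfilt (odd padding), the de facto reference for this design
  x <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
         0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
         0.066031, 1.127241, 0.467509, -0.859292, 0.368751, -0.958883,
         0.87845, -0.049926, -0.184862, -0.68093, 1.222541, -0.154529)
  expected <- c(0.2988300564, 0.0329027755, -0.2150576434, -0.4233618201,
                -0.5641026407, -0.6107159949, -0.549798401, -0.3898483646,
                -0.1622396042, 0.0851730558, 0.2993054936, 0.4355516293,
                0.4705992242, 0.4096168659, 0.2839651996, 0.1392273137,
                0.0180012688, -0.0549860408, -0.0787969213, -0.071605495,
                -0.0593450021, -0.0636883537, -0.0938197433, -0.1442401208)
  expect_equal(lowpass(x, fs = 50, cutoff = 5), expected, tolerance = 1e-8)
})

test_that("lowpass has unit DC gain and attenuates above cutoff", {
  expect_equal(lowpass(rep(2.5, 100), 50, 5), rep(2.5, 100), tolerance = 1e-9)
  t <- (0:499) / 50
  hi <- sin(2 * pi * 20 * t)
  out <- lowpass(hi, 50, 5)
  expect_lt(sqrt(mean(out^2)), 0.1 * sqrt(mean(hi^2)))
  lo <- sin(2 * pi * 1 * t)
  mix <- lo + hi
  out2 <- lowpass(mix, 50, 5)
  expect_lt(abs(sqrt(mean(out2^2)) - sqrt(mean(lo^2))),
            0.05 * sqrt(mean(lo^2)))
  expect_error(lowpass(lo, 50, 25), class = "ff_config_error")
})

test_that("preprocess warns instead of upsampling slow native rates", {
  n <- 200
  rec <- imu_recording(matrix(rnorm(3 * n), n), matrix(rnorm(3 * n), n),
                       fs = 20)
  expect_warning(out <- preprocess(rec, target_fs = 50), "native rate")
  expect_equal(out$fs, 20)
})
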