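test_that("metrics match direct substitution and undefined rules", {
  m <- metrics(confusion_matrix(tp = 9, tn = 90, fp = 10, fn = 1))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 9 / 19)
  expect_equal(m$f1, 2 * (9 / 19) * 0.9 / (9 / 19 + 0.9))

  perfect <- metrics(confusion_matrix(tp = 5, tn = 7))
  expect_equal(unlist(unclass(perfect)), c(sensitivity = 1, specificity = 1,
                                           precision = 1, f1 = 1))

  z <- metrics(confusion_matrix(tp = 0, fp = 0, fn = 3, tn = 2))
  expect_true(is.na(z$precision))
  expect_equal(z$sensitivity, 0)
  allz <- metrics(confusion_matrix())
  expect_true(all(is.na(unlist(unclass(allz)))))
})

test_that("F1 is the harmonic mean of precision and recall", {
  for (i in 1:200) {
    cm <- with_seed(i, confusion_matrix(sample(0:30, 1), sample(0:30, 1),
                                        sample(0:30, 1), sample(0:30, 1)))
    m <- metrics(cm)
    if (!is.na(m$f1) && !is.na(m$precision) && !is.na(m$sensitivity) &&
        m$precision + m$sensitivity > 0)
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity), tolerance = 1e-12)
  }
})

test_that("friedman_test equals the brute-force oracle on random matrices", {
  for (i in 1:200) {
    dims <- with_seed(i, c(sample(3:8, 1), sample(2:5, 1)))
    x <- with_seed(i + 1000, matrix(rnorm(prod(dims)), dims[1], dims[2]))
    if (i %% 3 == 0) x[sample(length(x), 3)] <- x[1]   # inject ties
    ours <- attr(friedman_test(x, n_groups = nrow(x), n_reps = 1), "chisq")
    expect_equal(ours, friedman_oracle(x), tolerance = 1e-9, info = i)
  }
})

test_that("friedman_test df structure follows the two-way layout", {
  for (prm in list(c(4, 3, 10), c(3, 2, 4), c(5, 4, 2), c(2, 6, 3))) {
    k <- prm[1]; d <- prm[2]; r <- prm[3]
    x <- with_seed(k * 100 + d, matrix(rnorm(d * r * k), d * r, k))
    ft <- friedman_test(x, n_groups = d, n_reps = r)
    expect_equal(ft$df, c(d - 1, k - 1, (k - 1) * (d - 1), d * k * (r - 1),
                          d * r * k - 1))
    expect_equal(sum(ft$SS[1:4]), ft$SS[5], tolerance = 1e-9)
    expect_equal(ft$SS[1], 0)   # joint within-group ranking zeroes Groups
  }
})

test_that("friedman degenerate and permutation behaviour", {
  z <- matrix(rep(with_seed(3, runif(12)), 4), 12, 4)
  ftz <- friedman_test(z, 12, 1)
  expect_equal(attr(ftz, "chisq"), 0)
  expect_equal(attr(ftz, "p_value"), 1)

  x <- with_seed(4, matrix(rnorm(40), 10, 4))
  f0 <- friedman_test(x, 10, 1)
  perm <- c(3, 1, 4, 2)
  f1 <- friedman_test(x[, perm], 10, 1)
  expect_equal(attr(f1, "chisq"), attr(f0, "chisq"), tolerance = 1e-12)
  expect_equal(attr(f1, "avg_ranks"), attr(f0, "avg_ranks")[perm],
               tolerance = 1e-12)
  expect_error(friedman_test(x[, 1, drop = FALSE], 10, 1),
               class = "ff_contract_error")
  xna <- x; xna[2, 2] <- NA
  expect_error(friedman_test(xna, 10, 1), class = "ff_contract_error")
})

test_that("nemenyi critical distance follows the embedded q table", {
  nm <- nemenyi(c(a = 1.2, b = 2.1, c = 3.0, d = 3.7), n_blocks = 30)
  expect_equal(nm$cd, 2.569032 * sqrt(20 / 180), tolerance = 1e-6)
  ## monotone: decreasing in n_blocks, increasing in k
  cds_n <- vapply(c(10, 30, 90), function(n)
    nemenyi(rep(1, 4), n)$cd, numeric(1))
  expect_true(all(diff(cds_n) < 0))
  cds_k <- vapply(2:10, function(k)
    nemenyi(rep(1, k), 30)$cd, numeric(1))
  expect_true(all(diff(cds_k) > 0))
  ## equal ranks never significant; wide gaps are
  expect_false(nemenyi(c(2, 2), 30)$significant[1, 2])
  expect_true(nemenyi(c(1, 4), 30)$significant[1, 2])
  expect_error(nemenyi(rep(1, 4), 30, alpha = 0.01),
               class = "ff_config_error")
})

test_that("compare_algorithms ranks a dominating algorithm first", {
  mk_cv <- function(tp, fn, fp, tn, r = 5) {
    structure(list(fold_results = data.frame(
      fold = 1:r, train_sensitivity = 1, train_specificity = 1,
      tp = tp, tn = tn, fp = fp, fn = fn)), class = "cv_result")
  }
  good <- mk_cv(10, 0, 0, 10); mid <- mk_cv(8, 2, 2, 8); bad <- mk_cv(5, 5, 5, 5)
  cvs <- list(d1 = list(A = good, B = mid, C = bad),
              d2 = list(A = good, B = mid, C = bad),
              d3 = list(A = good, B = mid, C = bad))
  cp <- compare_algorithms(cvs, metric = "f1", alpha = 0.05)
  expect_equal(names(which.min(cp$avg_ranks)), "A")
  expect_lt(attr(cp$friedman, "p_value"), 0.05)
  expect_true(cp$nemenyi$significant["A", "C"])
  expect_match(cp$table[1, 1], "^\\d\\.\\d{4} \\(\\d\\.\\d{4}\\)$")

  ## identical detections: chi-square 0, p = 1, post-hoc skipped
  same <- list(d1 = list(A = mid, B = mid), d2 = list(A = mid, B = mid))
  cp2 <- compare_algorithms(same, metric = "sensitivity")
  expect_equal(attr(cp2$friedman, "p_value"), 1)
  expect_null(cp2$nemenyi)
})
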