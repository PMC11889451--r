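test_that("EM on complete data equals the closed-form Gaussian MLE", {
  set.seed(21)
  X <- MASS::mvrnorm(80, c(1, -2, 0.5), diag(0.6, 3) + 0.4)
  est <- em_fit(data_matrix(X))
  expect_equal(unname(est$mu), unname(colMeans(X)), tolerance = 1e-8)
  expect_equal(unname(est$sigma), unname(stats::cov(X) * 79 / 80),
               tolerance = 1e-8)
  expect_true(est$converged)
})

test_that("EM recovers the generating parameters under MCAR", {
  set.seed(22)
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  X <- MASS::mvrnorm(5000, c(0, 0), S)
  X[runif(1e4) < 0.2] <- NA
  X[1, ] <- c(0, 0)                      # keep at least one complete row
  est <- em_fit(data_matrix(X))
  expect_true(all(abs(est$mu) < 0.05))
  expect_true(all(abs(est$sigma - S) < 0.08))
  expect_true(est$converged)
})

test_that("the observed-data log-likelihood is non-decreasing across EM iterations", {
  for (seed in c(31, 32, 33)) {
    dm <- random_masked_dm(60, 4, 0.3, seed = seed)
    est <- em_fit(dm)
    expect_true(all(diff(est$loglik_trace) > -1e-8))
  }
  # heavily missing column: still runs, flag honest, loglik monotone
  set.seed(34)
  X <- MASS::mvrnorm(200, c(0, 0), diag(0.4, 2) + 0.6)
  X[sample(200, 198), 2] <- NA
  est <- em_fit(data_matrix(X), max_iter = 50L)
  expect_true(all(diff(est$loglik_trace) > -1e-8))
  expect_type(est$converged, "logical")
})

test_that("EM rejects features with no observations", {
  X <- matrix(rnorm(20), 10, 2)
  X[, 2] <- NA
  expect_error(em_fit(data_matrix(X)), "zero observed")
})

test_that("Little's d2 matches explicit matrix algebra on a small instance", {
  X <- matrix(c(2.1, 0.4, -1.3, 0.8, 1.7,
                0.3, 1.9, -0.2, -1.1, 0.6,
                1.2, -0.7, 0.9, 0.1, NA), 5, 3)
  dm <- data_matrix(X)
  r <- suppressWarnings(little_mcar(dm))
  mu <- r$em$mu; sigma <- r$em$sigma
  # brute force: two patterns, quadratic forms written out by hand
  ybar1 <- colMeans(X[1:4, ])                         # complete pattern
  d1 <- 4 * drop(t(ybar1 - mu) %*% solve(sigma) %*% (ybar1 - mu))
  ybar2 <- X[5, 1:2]                                  # third value missing
  d2 <- 1 * drop(t(ybar2 - mu[1:2]) %*% solve(sigma[1:2, 1:2]) %*%
                   (ybar2 - mu[1:2]))
  expect_equal(r$chi2, d1 + d2, tolerance = 1e-8)
  expect_equal(r$chi2, sum(r$pattern_contributions$contribution),
               tolerance = 1e-10)
  expect_equal(r$df, (3L + 2L) - 3L)
  expect_equal(r$p_value, stats::pchisq(r$chi2, 2, lower.tail = FALSE))
})

test_that("pattern means equal to the EM means give a zero statistic", {
  X <- rbind(c(-1, -1), c(1, 1), c(1, -1), c(-1, 1), c(-2, NA), c(2, NA))
  r <- suppressWarnings(little_mcar(data_matrix(X)))
  expect_lt(r$chi2, 1e-8)
  expect_gt(r$p_value, 0.999)
})

test_that("Little's test refuses degenerate inputs", {
  expect_error(little_mcar(data_matrix(matrix(rnorm(20), 5, 4))),
               "no missing cells")
  X <- matrix(rnorm(20), 5, 4); X[, 2] <- NA   # one shared pattern
  expect_error(little_mcar(data_matrix(X)), "at least 2 distinct")
})

test_that("Little's test keeps MCAR data and rejects covariate-driven missingness", {
  keep <- logical(40)
  for (s in 1:40) {
    sd_ <- generate_synthetic(synthetic_spec("mcar", n = 300L, p = 4L,
                                             target_rate = 0.1,
                                             correlation = 0.3, seed = s))
    keep[s] <- suppressWarnings(little_mcar(sd_$data))$conclusion ==
      "mcar_not_rejected"
  }
  expect_gte(mean(keep), 0.85)

  rej <- logical(20)
  for (s in 1:20) {
    set.seed(s + 600)
    X <- MASS::mvrnorm(1000, rep(0, 3), diag(0.7, 3) + 0.3)
    X[runif(1000) < plogis(-1 + 2 * X[, 1]), 2] <- NA   # MAR on feature 1
    rej[s] <- suppressWarnings(little_mcar(data_matrix(X)))$conclusion ==
      "mcar_rejected"
  }
  expect_gte(mean(rej), 0.90)
})

test_that("the normality gate warns but does not block", {
  set.seed(41)
  X <- exp(MASS::mvrnorm(300, rep(0, 3), diag(0.5, 3) + 0.5))  # lognormal
  X[runif(300) < 0.15, 2] <- NA
  r <- little_mcar(data_matrix(X))
  expect_false(is.null(r$normality_warning))
  expect_true(r$conclusion %in% c("mcar_not_rejected", "mcar_rejected"))
})
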