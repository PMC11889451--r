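test_that("simple imputation fills the column statistic", {
  dm <- data_matrix(cbind(a = c(1, NA, 3), b = c(0, 1, 2)))
  expect_equal(impute_simple(dm, "mean")$completed[2, 1], 2.0)

  dm2 <- data_matrix(cbind(a = c(1, 1, 2, NA), b = 1:4))
  expect_equal(impute_simple(dm2, "most_frequent")$completed[4, 1], 1.0)

  dm3 <- data_matrix(cbind(a = c(1, 2, NA, 100), b = 1:4))
  expect_equal(impute_simple(dm3, "median")$completed[3, 1], 2.0)

  X <- cbind(a = rep(NA_real_, 3), b = 1:3)
  expect_error(impute_simple(data_matrix(X), "mean"), "zero observed")
})

test_that("KNN copies a zero-distance donor and matches the brute-force oracle", {
  X <- rbind(c(1, 2, 3), c(1, 2, NA), c(9, 9, 9), c(0, 5, 7))
  r <- impute_knn(data_matrix(X), k = 1)
  expect_equal(r$completed[2, 3], 3)         # identical donor row

  for (seed in 91:95) {
    dm <- random_masked_dm(8, 3, 0.25, seed = seed)
    for (w in c("uniform", "distance")) {
      got <- impute_knn(dm, k = 2, weighting = w)$completed
      want <- oracle_knn(dm$values, k = 2, weighting = w)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("KNN saturates to the donor mean and falls back when no donor shares coordinates", {
  X <- rbind(c(1, 10), c(2, 20), c(3, 30), c(4, NA))
  r <- impute_knn(data_matrix(X), k = 50)
  expect_equal(r$completed[4, 2], 20)        # mean of all donors

  # row 1 observed only in column 1; donors for column 2 lack column 1
  Xf <- rbind(c(5, NA, NA), c(NA, 2, 7), c(NA, 3, 8))
  rf <- impute_knn(data_matrix(Xf), k = 2)
  expect_equal(rf$completed[1, 2], 2.5)      # column-mean fallback
  expect_false(is.null(rf$fallback_cells))
})

test_that("iterative imputation reproduces an exact linear relation", {
  set.seed(101)
  x1 <- rnorm(30)
  X <- cbind(a = x1, b = 2 * x1)
  X[c(3, 11, 25), 2] <- NA
  r <- impute_iterative(data_matrix(X), "linear")
  expect_equal(unname(r$completed[c(3, 11, 25), 2]), 2 * x1[c(3, 11, 25)],
               tolerance = 1e-6)
})

test_that("iterative-linear beats mean imputation on correlated data", {
  set.seed(102)
  S <- diag(0.1, 4) + 0.9
  truth <- MASS::mvrnorm(300, rep(0, 4), S)
  mask <- matrix(runif(1200) < 0.2, 300, 4)
  X <- truth; X[mask] <- NA
  dm <- data_matrix(X)
  r_lin <- impute_iterative(dm, "linear", seed = 1)
  r_mean <- impute_simple(dm, "mean")
  expect_lt(rmse(truth[mask], r_lin$completed[mask]),
            rmse(truth[mask], r_mean$completed[mask]))
})

test_that("a loose tolerance stops after one round", {
  dm <- random_masked_dm(40, 3, 0.2, seed = 103)
  r <- impute_iterative(dm, "linear", tol = 1e6)
  expect_equal(r$n_iterations, 1L)
  expect_true(r$converged)
})

test_that("all imputers preserve observed cells, complete the matrix, and are deterministic", {
  dm <- random_masked_dm(50, 4, 0.25, seed = 104)
  obs <- !missing_mask(dm)
  methods <- list(
    function() impute_simple(dm, "median"),
    function() impute_knn(dm, k = 3),
    function() impute_iterative(dm, "linear", seed = 9),
    function() impute_iterative(dm, "lasso_cv", seed = 9),
    function() impute_iterative(dm, "random_forest", seed = 9),
    function() impute_iterative(dm, "gradient_boosting", seed = 9))
  for (m in methods) {
    r1 <- m(); r2 <- m()
    expect_false(anyNA(r1$completed))
    expect_identical(r1$completed[obs], dm$values[obs])
    expect_identical(r1$completed, r2$completed)
    expect_identical(r1$imputed_mask, missing_mask(dm))
  }
})

test_that("simple and KNN fills stay inside the observed range", {
  for (seed in 111:113) {
    dm <- random_masked_dm(40, 3, 0.3, seed = seed)
    for (r in list(impute_simple(dm, "mean"), impute_knn(dm, k = 3))) {
      for (j in 1:3) {
        obs <- dm$values[!missing_mask(dm)[, j], j]
        imp <- r$completed[missing_mask(dm)[, j], j]
        expect_true(all(imp >= min(obs) - 1e-12 & imp <= max(obs) + 1e-12))
      }
    }
  }
})

test_that("multiple imputation pools by Rubin's rules", {
  # complete data: all draws identical, zero between-imputation variance
  dmc <- data_matrix(matrix(rnorm(60), 20, 3))
  mic <- impute_mice(dmc, m = 3)
  expect_identical(mic$draws[[1]]$completed, mic$draws[[2]]$completed)
  expect_equal(mic$pooled$between, rep(0, 3))

  set.seed(120)
  truth <- MASS::mvrnorm(400, rep(0, 3), diag(0.5, 3) + 0.5)
  X <- truth; X[runif(1200) < 0.2] <- NA
  mi <- impute_mice(data_matrix(X), m = 5, seed = 7)
  se <- apply(truth, 2, sd) / sqrt(400)
  expect_true(all(abs(mi$pooled$pooled_mean) < 3 * se + 0.05))
  expect_true(all(mi$pooled$total_var >= mi$pooled$within - 1e-15))
  # reproducible given the seed
  mi2 <- impute_mice(data_matrix(X), m = 5, seed = 7)
  expect_identical(mi$draws[[5]]$completed, mi2$draws[[5]]$completed)
})
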