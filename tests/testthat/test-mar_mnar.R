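make_mar_dm <- function(n, seed, outcome = FALSE, beta_y = 0) {
  set.seed(seed)
  X <- MASS::mvrnorm(n, rep(0, 3), diag(0.7, 3) + 0.3)
  Y <- rnorm(n)
  miss <- runif(n) < plogis(-1.5 + 1.2 * X[, 2] + beta_y * Y)
  X[miss, 1] <- NA
  data_matrix(X, outcome = if (outcome) Y else NULL)
}

test_that("the LRT agrees with an unpenalized glm fit", {
  dm <- make_mar_dm(500, seed = 51)
  r <- feature_lrt(dm, 1)
  D <- as.numeric(!is.na(dm$values[, 1]))
  Z <- missdiag:::mean_fill(dm$values[, -1])
  added <- dm$values[, 1]
  added[is.na(added)] <- mean(added, na.rm = TRUE)
  m0 <- stats::glm(D ~ Z, family = binomial)
  m1 <- stats::glm(D ~ Z + added, family = binomial)
  lrt_glm <- 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0)))
  expect_equal(r$lrt_stat, lrt_glm, tolerance = 0.01)
  expect_equal(r$df_added, 1L)
})

test_that("nested fits keep the statistic nonnegative across random data", {
  for (seed in 61:70) {
    dm <- random_masked_dm(80, 4, 0.25, seed = seed)
    r <- feature_lrt(dm, 1 + seed %% 4)
    if (r$conclusion == "skipped") next
    expect_gte(r$lrt_stat, 0)
    expect_gte(r$l_mnar, r$l_mar - 1e-6)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("edge cases are skipped, never errors", {
  X <- matrix(rnorm(100), 25, 4)
  X[1:5, 2] <- NA
  dm <- data_matrix(X)
  expect_identical(feature_lrt(dm, 1)$conclusion, "skipped")      # fully observed
  expect_match(feature_lrt(dm, 1)$skip_reason, "fully observed")
  dm_small <- data_matrix(X[1:10, ])
  expect_match(feature_lrt(dm_small, 2)$skip_reason, "small sample")
  X1 <- matrix(rnorm(30), 30, 1); X1[1:6] <- NA
  expect_match(feature_lrt(data_matrix(X1), 1)$skip_reason, "single variable")
})

test_that("an outcome variable takes precedence as the added regressor", {
  dm <- make_mar_dm(300, seed = 52, outcome = TRUE)
  r <- feature_lrt(dm, 1)
  expect_identical(r$added_regressor, "outcome_Y")
  r2 <- feature_lrt(data_matrix(dm$values), 1)
  expect_identical(r2$added_regressor, "self_feature_imputed")
})

test_that("the LRT statistic follows chi-square(1) when the added regressor is irrelevant", {
  lrt <- vapply(1:400, function(s)
    feature_lrt(make_mar_dm(400, seed = s + 9000, outcome = TRUE), 1)$lrt_stat,
    numeric(1))
  u <- sort(stats::pchisq(lrt, 1))
  ks <- max(abs(u - seq_along(u) / length(u)))
  expect_lt(ks, 0.07)
  expect_lt(abs(mean(lrt > stats::qchisq(0.95, 1)) - 0.05), 0.03)
})

test_that("self-masked features are flagged MNAR, MCAR features are not over-flagged", {
  fx <- generate_synthetic(synthetic_spec("mnar", n = 2000L, p = 10L,
                                          target_rate = 0.30, coeffs = 2,
                                          correlation = 0.3, seed = 71))
  concl <- vapply(1:10, function(j) feature_lrt(fx$data, j)$conclusion,
                  character(1))
  expect_gte(sum(concl == "mnar"), 9L)

  rej <- vapply(1:60, function(s) {
    sm <- generate_synthetic(synthetic_spec("mcar", n = 400L, p = 4L,
                                            target_rate = 0.2,
                                            correlation = 0.3, seed = s + 300))
    r <- feature_lrt(sm$data, 1)
    r$conclusion == "mnar"
  }, logical(1))
  expect_lte(mean(rej), 0.07)     # conservative under MCAR
})

test_that("the combined workflow gates feature-wise tests on Little's verdict", {
  fx <- table_fixtures(seed = 81L)
  rep_mcar <- combined_test(fx$mcar$data)
  expect_identical(rep_mcar$little$conclusion, "mcar_not_rejected")
  expect_length(rep_mcar$per_feature, 0L)

  rep_forced <- combined_test(fx$mcar$data, force_featurewise = TRUE)
  expect_gt(length(rep_forced$per_feature), 0L)
  expect_true(all(c("p", "p_adj", "conclusion") %in%
                    names(rep_forced$feature_table)))
  expect_true(all(rep_forced$feature_table$p_adj >=
                    rep_forced$feature_table$p - 1e-12))

  rep_mnar <- combined_test(fx$mnar$data)
  expect_identical(rep_mnar$little$conclusion, "mcar_rejected")
  expect_equal(nrow(rep_mnar$feature_table), 10L)
  expect_match(rep_mnar$overall_comment, "MNAR")

  expect_error(combined_test(data_matrix(matrix(rnorm(40), 10, 4))),
               "not applicable")
})
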