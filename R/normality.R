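new_normality_result <- function(test_name, statistic, p_value, n_used, alpha,
                                 extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, n_used = n_used, alpha = alpha,
                   normal_at_alpha = p_value > alpha), extra),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g, n = %d -> %s at alpha = %g\n",
              x$test_name, x$statistic, x$p_value, x$n_used,
              if (x$normal_at_alpha) "consistent with normality" else "non-normal",
              x$alpha))
  invisible(x)
}

check_univariate <- function(x, min_n = 3L) {
  x <- x[!is.na(x)]
  if (length(x) < min_n)
    stop(sprintf("insufficient data: need at least %d observed values, got %d",
                 min_n, length(x)), call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate input: all observed values identical", call. = FALSE)
  x
}

#' Shapiro-Wilk normality test
#'
#' Tests whether the observed (non-missing) values of `x` are consistent with
#' a normal distribution. The W statistic is the squared ratio of the best
#' linear unbiased estimate of scale (a weighted sum of the order statistics,
#' with weights from the expected normal order statistics) to the sample sum
#' of squares; W near 1 indicates normality and smaller W stronger departure.
#'
#' @param x numeric vector; missing values are dropped.
#' @param alpha significance level for the verdict (default 0.05).
#' @return a `normality_result` with `statistic` = W.
#' @export
shapiro_wilk <- function(x, alpha = 0.05) {
  x <- check_univariate(x)
  if (length(x) > 5000) {
    warning("Shapiro-Wilk approximation degrades beyond n = 5000; ",
            "using the first 5000 values")
    x <- x[seq_len(5000)]
  }
  sw <- stats::shapiro.test(x)
  new_normality_result("shapiro_wilk", unname(sw$statistic), sw$p.value,
                       length(x), alpha)
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS test of the observed values against the normal distribution.
#' D = sup |F_n(x) - Phi(x)| is compared to the Kolmogorov distribution. When
#' `mean` and `sd` are not supplied the sample is standardised by its own mean
#' and standard deviation; the nominal p-value is then conservative (the
#' Lilliefors situation, since the null parameters were estimated from the
#' same data) and the result carries a `lilliefors_caveat` flag to make this
#' explicit rather than silently switching critical values. Supplying known
#' `mean` and `sd` gives the exactly calibrated fixed-null test.
#'
#' @inheritParams shapiro_wilk
#' @param mean,sd optional known null parameters; both NULL (default) means
#'   they are estimated from the sample.
#' @return a `normality_result` with `statistic` = D and the
#'   `lilliefors_caveat` flag.
#' @export
ks_normal <- function(x, alpha = 0.05, mean = NULL, sd = NULL) {
  x <- check_univariate(x)
  estimated <- is.null(mean) || is.null(sd)
  if (estimated) {
    z <- (x - base::mean(x)) / stats::sd(x)
  } else {
    z <- (x - mean) / sd
  }
  ks <- suppressWarnings(stats::ks.test(z, "pnorm", exact = FALSE))
  new_normality_result("kolmogorov_smirnov", unname(ks$statistic), ks$p.value,
                       length(x), alpha,
                       extra = list(lilliefors_caveat = estimated))
}

# sup-norm distance between the ecdf of x and a reference cdf, evaluated at
# the jump points with both one-sided gaps (internal helper; ks_normal uses
# stats::ks.test, this exists for direct reference-cdf checks)
ks_statistic <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)
}

#' Henze-Zirkler multivariate normality test
#'
#' Computes the Henze-Zirkler statistic on the complete rows of `data`: a
#' weighted L2 distance between the empirical characteristic function of the
#' standardised data and that of the multivariate normal, with the standard
#' data-size-dependent smoothing parameter. The p-value uses the usual
#' lognormal approximation to the null distribution. The test serves as an
#' advisory gate for Little's MCAR test, which assumes multivariate normality.
#'
#' @param data a [data_matrix()] or numeric matrix.
#' @param alpha significance level for the verdict (default 0.05).
#' @return a `normality_result` with `statistic` = HZ and `n_used` = number of
#'   complete rows.
#' @export
henze_zirkler <- function(data, alpha = 0.05) {
  X <- if (inherits(data, "data_matrix")) data$values else as.matrix(data)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2)
    stop(sprintf(paste("insufficient data: Henze-Zirkler needs at least p + 2 =",
                       "%d complete rows, got %d; warn and proceed without the",
                       "normality gate"), p + 2, n), call. = FALSE)
  S <- stats::cov(X) * (n - 1) / n
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv))
    stop("degenerate input: covariance of complete rows is singular",
         call. = FALSE)
  ctr <- sweep(X, 2L, colMeans(X))
  Dj <- rowSums((ctr %*% Sinv) * ctr)          # squared Mahalanobis to mean
  Y <- X %*% Sinv %*% t(X)
  d <- diag(Y)
  Djk <- outer(d, d, "+") - 2 * Y              # pairwise squared Mahalanobis
  b <- (1 / sqrt(2)) * ((2 * p + 1) * n / 4)^(1 / (p + 4))
  hz <- n * (sum(exp(-(b^2) / 2 * Djk)) / n^2 -
               2 * (1 + b^2)^(-p / 2) * mean(exp(-(b^2) / (2 * (1 + b^2)) * Dj)) +
               (1 + 2 * b^2)^(-p / 2))
  a <- 1 + 2 * b^2
  wb <- (1 + b^2) * (1 + 3 * b^2)
  mu <- 1 - a^(-p / 2) * (1 + p * b^2 / a + p * (p + 2) * b^4 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b^2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b^4 / a^2 + 3 * p * (p + 2) * b^8 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b^4 / (2 * wb) + p * (p + 2) * b^8 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
  psi <- sqrt(log((si2 + mu^2) / mu^2))
  pval <- stats::plnorm(hz, meanlog = pmu, sdlog = psi, lower.tail = FALSE)
  new_normality_result("henze_zirkler", hz, pval, n, alpha)
}

#' Per-feature normality table
#'
#' Runs Shapiro-Wilk and KS tests on each feature's observed values.
#'
#' @param data a [data_matrix()].
#' @param alpha significance level.
#' @return data.frame with one row per feature: W, its p-value, D, its
#'   p-value, and the verdicts at `alpha`. Features with fewer than 3 observed
#'   values or zero variance get `NA` entries.
#' @export
normality_table <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "data_matrix"))
  rows <- lapply(seq_along(data$feature_names), function(j) {
    x <- data$values[, j]
    sw <- tryCatch(shapiro_wilk(x, alpha), error = function(e) NULL)
    ks <- tryCatch(ks_normal(x, alpha), error = function(e) NULL)
    data.frame(feature = data$feature_names[j],
               shapiro_W = if (is.null(sw)) NA_real_ else sw$statistic,
               shapiro_p = if (is.null(sw)) NA_real_ else sw$p_value,
               ks_D = if (is.null(ks)) NA_real_ else ks$statistic,
               ks_p = if (is.null(ks)) NA_real_ else ks$p_value,
               normal_shapiro = if (is.null(sw)) NA else sw$normal_at_alpha,
               normal_ks = if (is.null(ks)) NA else ks$normal_at_alpha)
  })
  do.call(rbind, rows)
}

#' Ordered-quantile pairs for a Q-Q plot
#'
#' Returns the plain table (theoretical normal quantile, ordered sample value)
#' that a Q-Q plot would draw, for export.
#'
#' @inheritParams shapiro_wilk
#' @return data.frame with columns `theoretical` and `sample`.
#' @export
qq_table <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  data.frame(theoretical = stats::qnorm(stats::ppoints(n)), sample = x)
}
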