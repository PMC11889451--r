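# Ridge-penalized logistic regression by iteratively reweighted least squares.
# The intercept is unpenalized; slopes carry a quadratic penalty lambda/2 * ||b||^2.
# Both models of the LRT are fitted with the same lambda so their penalized
# log-likelihoods stay comparable (and nested: the larger model can always
# reproduce the smaller one's fit with the extra coefficient at 0).
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, X)
  d <- ncol(X)
  pen <- diag(c(0, rep(lambda, d - 1L)), d)
  beta <- numeric(d)
  pll_old <- -Inf
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, d), g))
    beta_new <- beta + step
    eta_new <- pmin(pmax(drop(X %*% beta_new), -30), 30)
    pll <- sum(y * eta_new - log1p(exp(eta_new))) -
      0.5 * lambda * sum(beta_new[-1L]^2)
    # halve the step if the penalized log-likelihood would decrease
    h <- 0
    while (pll < pll_old && h < 20) {
      step <- step / 2
      beta_new <- beta + step
      eta_new <- pmin(pmax(drop(X %*% beta_new), -30), 30)
      pll <- sum(y * eta_new - log1p(exp(eta_new))) -
        0.5 * lambda * sum(beta_new[-1L]^2)
      h <- h + 1
    }
    beta <- beta_new
    if (abs(pll - pll_old) < tol * (abs(pll_old) + 1)) break
    pll_old <- pll
  }
  if (any(abs(drop(X %*% beta)) >= 30)) separation <- TRUE
  list(beta = drop(beta), loglik = pll, separation = separation)
}

# mean-fill a matrix's NA cells column-wise (fitting-only; callers' data stay
# unchanged); drops nothing
mean_fill <- function(X) {
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (anyNA(x)) X[is.na(x), j] <- mean(x, na.rm = TRUE)
  }
  X
}

#' Feature-wise MAR-versus-MNAR likelihood-ratio test
#'
#' For one feature, models its missingness indicator D (1 = observed,
#' 0 = missing) with two nested logistic regressions: the MAR model uses all
#' other features as predictors, and the MNAR model adds one regressor — the
#' outcome Y when one is present, otherwise the feature itself with its
#' missing cells filled at its observed column mean (a deterministic,
#' mean-anchored fill). The statistic 2 (l_MNAR - l_MAR) is referred to
#' chi-square(1); a significant result says the probability of missingness
#' depends on the feature's own value beyond what the other features explain,
#' i.e. MNAR.
#'
#' The mean-anchored fill matters: under self-masking, the conditional
#' location of the feature given the other features shifts between the
#' observed and missing classes, and anchoring the missing rows at a constant
#' preserves that shift as signal. A fill from a regression trained on the
#' observed rows would absorb it -- training residuals are mean-zero on the
#' observed class by construction -- leaving the test powerless against
#' self-masking. Under MCAR the added regressor carries no class information
#' and the test is conservative.
#'
#' Other features' own missing cells are mean-filled for the fits only, so D
#' keeps its full length. Both fits carry the same small ridge penalty
#' (`lambda`) so the compared likelihoods are identically penalized; the
#' statistic is therefore nonnegative by construction. Note the self-feature
#' variant leans on filled values where D = 0 (MNAR is not point-identifiable
#' from observed data alone); the result flags which regressor was used.
#'
#' @param data a [data_matrix()].
#' @param feature feature name or column index.
#' @param alpha significance level (default 0.05).
#' @param lambda ridge penalty on slopes of both logistic fits (default 1e-4).
#' @return a `feature_lrt_result`: `feature`, `l_mar`, `l_mnar`, `lrt_stat`,
#'   `df_added`, `p_value`, `conclusion` ("mar", "mnar" or "skipped"),
#'   `skip_reason`, `added_regressor` ("outcome_Y" or "self_feature_imputed"),
#'   `separation_flag`.
#' @export
feature_lrt <- function(data, feature, alpha = 0.05, lambda = 1e-4) {
  stopifnot(inherits(data, "data_matrix"))
  X <- data$values
  j <- if (is.character(feature)) match(feature, data$feature_names) else as.integer(feature)
  if (is.na(j) || j < 1L || j > ncol(X))
    stop("unknown feature: ", feature, call. = FALSE)
  fname <- data$feature_names[j]
  n <- nrow(X)
  skip <- function(reason) structure(
    list(feature = fname, l_mar = NA_real_, l_mnar = NA_real_,
         lrt_stat = NA_real_, df_added = NA_integer_, p_value = NA_real_,
         conclusion = "skipped", skip_reason = reason,
         added_regressor = NA_character_, separation_flag = NA),
    class = "feature_lrt_result")

  D <- as.numeric(!is.na(X[, j]))
  if (all(D == 1)) return(skip("feature fully observed"))
  if (all(D == 0)) return(skip("feature fully missing"))
  if (n < 20L) return(skip("small sample"))
  if (ncol(X) < 2L && is.null(data$outcome))
    return(skip("single variable and no outcome"))

  others <- setdiff(seq_len(ncol(X)), j)
  usable <- others[colSums(!is.na(X[, others, drop = FALSE])) > 0L]
  Z <- if (length(usable)) mean_fill(X[, usable, drop = FALSE]) else
    matrix(numeric(0), n, 0)
  if (ncol(Z)) {
    sds <- apply(Z, 2L, stats::sd)
    Z <- Z[, sds > 0, drop = FALSE]
  }

  if (!is.null(data$outcome)) {
    added <- data$outcome
    added_regressor <- "outcome_Y"
  } else {
    if (ncol(Z) == 0L) return(skip("no other usable predictors"))
    added <- X[, j]
    added[is.na(added)] <- mean(added, na.rm = TRUE)
    added_regressor <- "self_feature_imputed"
  }
  if (stats::sd(added) == 0) return(skip("added regressor is constant"))

  fit_mar <- ridge_logistic(Z, D, lambda = lambda)
  fit_mnar <- ridge_logistic(cbind(Z, added = added), D, lambda = lambda)
  lrt <- max(0, 2 * (fit_mnar$loglik - fit_mar$loglik))
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  structure(list(feature = fname, l_mar = fit_mar$loglik,
                 l_mnar = fit_mnar$loglik, lrt_stat = lrt, df_added = 1L,
                 p_value = p,
                 conclusion = if (p <= alpha) "mnar" else "mar",
                 skip_reason = NULL, added_regressor = added_regressor,
                 separation_flag = fit_mar$separation || fit_mnar$separation),
            class = "feature_lrt_result")
}

#' @export
print.feature_lrt_result <- function(x, ...) {
  if (x$conclusion == "skipped") {
    cat(sprintf("%s: skipped (%s)\n", x$feature, x$skip_reason))
  } else {
    cat(sprintf("%s: LRT = %.3f, p = %.4g -> %s (added regressor: %s)\n",
                x$feature, x$lrt_stat, x$p_value, x$conclusion,
                x$added_regressor))
  }
  invisible(x)
}

#' Combined MCAR then MAR/MNAR mechanism test
#'
#' The full diagnosis workflow: run Little's MCAR test first; if MCAR is
#' rejected (or `force_featurewise = TRUE`), run the feature-wise MAR/MNAR
#' likelihood-ratio test for every feature with at least one missing cell.
#' Per-feature p-values are reported raw and Benjamini-Hochberg adjusted;
#' conclusions use the raw p-value at `alpha` by default (set
#' `use_adjusted = TRUE` to conclude on the adjusted values).
#'
#' @param data a [data_matrix()] with at least one missing cell.
#' @param alpha significance level (default 0.05).
#' @param force_featurewise run the feature-wise tests even when MCAR is not
#'   rejected (default FALSE).
#' @param use_adjusted base the MAR/MNAR conclusions on BH-adjusted p-values.
#' @param ... passed to [little_mcar()].
#' @return a `mechanism_report`: `little` (the [little_mcar()] result),
#'   `per_feature` (list of [feature_lrt()] results; empty when MCAR stands),
#'   `feature_table` (data.frame with lrt_stat, p, p_adj, conclusion),
#'   `overall_comment`, `alpha`.
#' @export
combined_test <- function(data, alpha = 0.05, force_featurewise = FALSE,
                          use_adjusted = FALSE, ...) {
  stopifnot(inherits(data, "data_matrix"))
  if (!anyNA(data$values))
    stop("not applicable: dataset is complete, nothing to diagnose",
         call. = FALSE)
  little <- little_mcar(data, alpha = alpha, ...)
  per_feature <- list()
  feature_table <- NULL
  if (identical(little$conclusion, "mcar_rejected") || force_featurewise) {
    miss_feats <- data$feature_names[colSums(is.na(data$values)) > 0L]
    per_feature <- lapply(miss_feats, function(f)
      feature_lrt(data, f, alpha = alpha))
    names(per_feature) <- miss_feats
    p_raw <- vapply(per_feature, `[[`, numeric(1), "p_value")
    p_adj <- stats::p.adjust(p_raw, method = "BH")
    concl <- vapply(seq_along(per_feature), function(i) {
      r <- per_feature[[i]]
      if (r$conclusion == "skipped") return("skipped")
      pv <- if (use_adjusted) p_adj[i] else p_raw[i]
      if (!is.na(pv) && pv <= alpha) "mnar" else "mar"
    }, character(1))
    feature_table <- data.frame(
      feature = miss_feats,
      lrt_stat = vapply(per_feature, `[[`, numeric(1), "lrt_stat"),
      p = p_raw, p_adj = p_adj, conclusion = concl, row.names = NULL)
  }
  n_mar <- sum(feature_table$conclusion == "mar")
  n_mnar <- sum(feature_table$conclusion == "mnar")
  n_skip <- sum(feature_table$conclusion == "skipped")
  overall_comment <- if (is.null(feature_table)) {
    sprintf("Little's MCAR test %s (p = %.4g); feature-wise MAR/MNAR tests not performed.",
            gsub("_", " ", little$conclusion), little$p_value)
  } else {
    sprintf("Little's MCAR test %s (p = %.4g); feature-wise LRTs: %d MAR, %d MNAR, %d skipped.",
            gsub("_", " ", little$conclusion), little$p_value,
            n_mar, n_mnar, n_skip)
  }
  structure(list(little = little, per_feature = per_feature,
                 feature_table = feature_table,
                 overall_comment = overall_comment, alpha = alpha),
            class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("mechanism_report\n")
  print(x$little)
  if (!is.null(x$feature_table)) {
    cat("\nper-feature MAR/MNAR likelihood-ratio tests:\n")
    print(x$feature_table, digits = 4)
  }
  cat("\n", x$overall_comment, "\n", sep = "")
  invisible(x)
}
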