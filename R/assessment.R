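#' Root-mean-square error
#'
#' @param true_vals numeric vector of reference values.
#' @param imputed_vals numeric vector of the same length.
#' @return `sqrt(mean((true_vals - imputed_vals)^2))`.
#' @export
rmse <- function(true_vals, imputed_vals) {
  if (length(true_vals) != length(imputed_vals) || length(true_vals) == 0L)
    stop("rmse: vectors must have equal nonzero length", call. = FALSE)
  sqrt(mean((true_vals - imputed_vals)^2))
}

seven_num <- function(x) {
  if (length(x) == 0L)
    return(c(n = 0, mean = NA, sd = NA, min = NA, q1 = NA, median = NA,
             q3 = NA, max = NA))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(x), mean = mean(x), sd = stats::sd(x), min = min(x),
    q1 = q[1], median = q[2], q3 = q[3], max = max(x))
}

#' Plausibility checks for an imputation
#'
#' Feature-wise comparison of observed values against the values placed in the
#' originally missing cells: summary statistics of both groups, a count of
#' imputed values falling outside the observed range, and a two-sample
#' Kolmogorov-Smirnov test of whether the imputed values could come from the
#' observed distribution (not applicable below 3 imputed cells). The report
#' passes overall when no feature has a significant distribution shift and no
#' range violations occur.
#'
#' @param original the [data_matrix()] the imputation was run on.
#' @param result the `imputation_result` produced from it.
#' @param alpha significance level for the distribution test (default 0.05).
#' @return a `quality_report`: `per_feature` (data.frame), `cell_table`
#'   (long-format source table for density/box plots), `overall_pass`,
#'   `notes`.
#' @export
assess_quality <- function(original, result, alpha = 0.05) {
  stopifnot(inherits(original, "data_matrix"),
            inherits(result, "imputation_result"))
  mask <- is.na(original$values)
  if (!identical(unname(mask), unname(result$imputed_mask)))
    stop("contract error: result's imputed mask does not match the original's missingness",
         call. = FALSE)
  p <- ncol(original$values)
  rows <- vector("list", p)
  cells <- vector("list", p)
  for (j in seq_len(p)) {
    obs <- original$values[!mask[, j], j]
    imp <- result$completed[mask[, j], j]
    so <- seven_num(obs); si <- seven_num(imp)
    viol <- if (length(imp) && length(obs))
      sum(imp < min(obs) | imp > max(obs)) else 0L
    ksp <- if (length(imp) >= 3L && length(obs) >= 3L)
      suppressWarnings(stats::ks.test(obs, imp)$p.value) else NA_real_
    rows[[j]] <- data.frame(feature = original$feature_names[j],
                            n_observed = so["n"], n_imputed = si["n"],
                            obs_mean = so["mean"], obs_sd = so["sd"],
                            obs_min = so["min"], obs_q1 = so["q1"],
                            obs_median = so["median"], obs_q3 = so["q3"],
                            obs_max = so["max"],
                            imp_mean = si["mean"], imp_sd = si["sd"],
                            imp_min = si["min"], imp_max = si["max"],
                            range_violation_count = viol,
                            distribution_test_p = ksp, row.names = NULL)
    cells[[j]] <- data.frame(
      feature = original$feature_names[j],
      value = c(obs, imp),
      source = rep(c("observed", "imputed"), c(length(obs), length(imp))))
  }
  per_feature <- do.call(rbind, rows)
  fail <- with(per_feature, range_violation_count > 0 |
                 (!is.na(distribution_test_p) & distribution_test_p <= alpha))
  structure(list(per_feature = per_feature,
                 cell_table = do.call(rbind, cells),
                 overall_pass = !any(fail),
                 alpha = alpha,
                 notes = if (any(fail))
                   paste("features failing plausibility:",
                         paste(per_feature$feature[fail], collapse = ", "))
                 else "all features pass plausibility checks"),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: overall %s (alpha = %g)\n",
              if (x$overall_pass) "PASS" else "FAIL", x$alpha))
  print(x$per_feature[, c("feature", "n_imputed", "obs_mean", "imp_mean",
                          "range_violation_count", "distribution_test_p")],
        digits = 4)
  cat(x$notes, "\n")
  invisible(x)
}

# resolve a method descriptor into a completed-matrix producer
run_imputation_method <- function(data, desc, seed) {
  if (is.function(desc)) return(desc(data))
  if (is.character(desc)) desc <- list(name = desc)
  name <- desc$name
  args <- desc[setdiff(names(desc), "name")]
  res <- switch(name,
    mean = , median = , most_frequent = impute_simple(data, statistic = name),
    knn = do.call(impute_knn, c(list(data = data), args)),
    iterative = do.call(impute_iterative,
                        c(list(data = data, seed = seed), args)),
    rf = do.call(impute_iterative,
                 c(list(data = data, learner = "random_forest", seed = seed),
                   args)),
    lasso = do.call(impute_iterative,
                    c(list(data = data, learner = "lasso_cv", seed = seed),
                      args)),
    gboost = do.call(impute_iterative,
                     c(list(data = data, learner = "gradient_boosting",
                            seed = seed), args)),
    mice = {
      mi <- do.call(impute_mice, c(list(data = data, seed = seed), args))
      comp <- Reduce(`+`, lapply(mi$draws, `[[`, "completed")) / mi$m
      new_imputation_result(data, comp, mi$method)
    },
    stop("unknown imputation method: ", name, call. = FALSE))
  res
}

method_label <- function(desc) {
  if (is.function(desc)) return("custom")
  if (is.character(desc)) return(desc)
  desc$name
}

#' Mask-and-score comparison of imputation methods
#'
#' Hides a random 10-20% of the originally observed cells, runs each candidate
#' method on the masked dataset, and scores every method on the identical
#' hidden-cell set: RMSE between the true and imputed values, and a p-value
#' for systematic bias. Pre-existing missing cells stay missing, so each
#' method faces the original missingness plus the probe mask. Masking respects
#' a per-column floor of 2 remaining observed values.
#'
#' @param data a [data_matrix()].
#' @param methods list of method descriptors: a name ("mean", "median",
#'   "most_frequent", "knn", "iterative", "rf", "lasso", "gboost", "mice"), a
#'   list with `name` plus arguments, or a function `data -> imputation_result`.
#' @param mask_fraction fraction of observed cells to hide; must lie in
#'   \[0.10, 0.20\] (default 0.15).
#' @param seed integer seed for the probe mask and seeded methods.
#' @param alpha significance level reported alongside.
#' @param bias_test "t" (two-sided paired t-test on true - imputed, the
#'   default) or "ks" (two-sample KS between true and imputed values).
#' @return a `compare_report`: `masked_cells` (row/column data.frame),
#'   `mask_fraction` (realized), `per_method` (data.frame: method, rmse,
#'   bias_p_value, error), `ranking`, `seed`.
#' @export
compare_methods <- function(data, methods, mask_fraction = 0.15, seed = 42L,
                            alpha = 0.05, bias_test = c("t", "ks")) {
  stopifnot(inherits(data, "data_matrix"))
  bias_test <- match.arg(bias_test)
  if (!is.numeric(mask_fraction) || mask_fraction < 0.10 || mask_fraction > 0.20)
    stop("mask_fraction must lie in [0.10, 0.20], got ", mask_fraction,
         call. = FALSE)
  X <- data$values
  obs_cells <- which(!is.na(X), arr.ind = TRUE)
  n_obs <- nrow(obs_cells)
  target <- round(mask_fraction * n_obs)
  per_col_obs <- colSums(!is.na(X))
  if (any(per_col_obs - 2L <= 0L))
    stop("every column must keep at least 2 observed values after masking",
         call. = FALSE)
  set.seed(seed)
  ord <- sample.int(n_obs)
  cap <- per_col_obs - 2L          # max maskable per column
  taken <- integer(ncol(X))
  sel <- integer(0)
  for (idx in ord) {
    j <- obs_cells[idx, 2L]
    if (taken[j] < cap[j]) {
      taken[j] <- taken[j] + 1L
      sel <- c(sel, idx)
      if (length(sel) >= target) break
    }
  }
  masked <- obs_cells[sel, , drop = FALSE]
  realized <- nrow(masked) / n_obs
  Xm <- X
  Xm[masked] <- NA_real_
  masked_data <- data_matrix(Xm, feature_names = data$feature_names,
                             sample_ids = data$sample_ids,
                             outcome = data$outcome)
  truth <- X[masked]

  rows <- lapply(methods, function(desc) {
    label <- method_label(desc)
    res <- tryCatch(run_imputation_method(masked_data, desc, seed = seed),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(method = label, rmse = NA_real_,
                        bias_p_value = NA_real_,
                        error = conditionMessage(res)))
    imp <- res$completed[masked]
    pv <- if (bias_test == "t") {
      d <- truth - imp
      if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
    } else {
      suppressWarnings(stats::ks.test(truth, imp)$p.value)
    }
    data.frame(method = label, rmse = rmse(truth, imp), bias_p_value = pv,
               error = NA_character_)
  })
  per_method <- do.call(rbind, rows)
  ranking <- per_method$method[order(per_method$rmse)]
  structure(list(masked_cells = as.data.frame(masked),
                 mask_fraction = realized, per_method = per_method,
                 ranking = ranking, seed = seed, alpha = alpha,
                 bias_test = bias_test),
            class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  cat(sprintf("compare_report: %d cells masked (%.1f%% of observed), seed %d\n",
              nrow(x$masked_cells), 100 * x$mask_fraction, x$seed))
  tab <- x$per_method[order(x$per_method$rmse), ]
  tab$rank <- seq_len(nrow(tab))
  print(tab[, c("rank", "method", "rmse", "bias_p_value")], digits = 4,
        row.names = FALSE)
  invisible(x)
}
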