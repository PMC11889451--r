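new_imputation_result <- function(data, completed, method,
                                  n_iterations = NULL, converged = NULL,
                                  fallback_cells = NULL) {
  mask <- is.na(data$values)
  stopifnot(!anyNA(completed))
  # observed cells are never altered
  completed[!mask] <- data$values[!mask]
  dimnames(completed) <- dimnames(data$values)
  structure(list(completed = completed, imputed_mask = mask, method = method,
                 n_iterations = n_iterations, converged = converged,
                 fallback_cells = fallback_cells),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: method = %s, %d cells filled%s\n",
              x$method$name, sum(x$imputed_mask),
              if (!is.null(x$n_iterations))
                sprintf(", %d iterations (%s)", x$n_iterations,
                        if (isTRUE(x$converged)) "converged" else "not converged")
              else ""))
  invisible(x)
}

check_imputable <- function(data) {
  stopifnot(inherits(data, "data_matrix"))
  nobs <- colSums(!is.na(data$values))
  if (any(nobs == 0L))
    stop("unusable feature with zero observed values: ",
         paste(data$feature_names[nobs == 0L], collapse = ", "), call. = FALSE)
  invisible(data)
}

#' Simple statistic imputation
#'
#' Fills each missing cell with the mean, median or mode (most frequent value,
#' ties broken by the smallest value) of its column's observed values.
#'
#' @param data a [data_matrix()]; every feature needs at least one observed
#'   value.
#' @param statistic one of "mean", "median", "most_frequent".
#' @return an `imputation_result`.
#' @export
impute_simple <- function(data, statistic = c("mean", "median", "most_frequent")) {
  statistic <- match.arg(statistic)
  check_imputable(data)
  X <- data$values
  fill_fun <- switch(statistic,
    mean = function(x) mean(x),
    median = function(x) stats::median(x),
    most_frequent = function(x) {
      tab <- table(x)
      vals <- as.numeric(names(tab))
      min(vals[tab == max(tab)])
    })
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- fill_fun(X[!miss, j])
  }
  new_imputation_result(data, X, list(name = statistic))
}

# pairwise nan-Euclidean distances: squared distance over mutually observed
# coordinates, scaled up by p / (number of coordinates used); NA when two rows
# share no observed coordinate
nan_euclidean <- function(X) {
  p <- ncol(X)
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  Mn <- matrix(as.numeric(M), nrow(X))
  shared <- Mn %*% t(Mn)                         # counts of shared coords
  sq <- X0^2
  # sum over shared coords of (xi - xr)^2, expanded so masked terms vanish
  d2 <- (sq %*% t(Mn)) + (Mn %*% t(sq)) - 2 * (X0 %*% t(X0))
  d2 <- d2 * p / shared
  d2[shared == 0] <- NA_real_
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' k-nearest-neighbour imputation
#'
#' Fills each missing cell with the (optionally distance-weighted) mean of the
#' target column's values among the k nearest donor rows. Row-to-row distance
#' is Euclidean over mutually observed coordinates, scaled by the proportion
#' of coordinates used (the nan-Euclidean convention). Donors must have the
#' target value observed; if none exists the cell falls back to the column
#' mean and is flagged.
#'
#' @param data a [data_matrix()].
#' @param k number of donors (default 5).
#' @param weighting "uniform" (plain mean) or "distance" (weights 1/d, a
#'   zero-distance donor dominating).
#' @return an `imputation_result`; `fallback_cells` lists any cells filled by
#'   the column-mean fallback.
#' @export
impute_knn <- function(data, k = 5L, weighting = c("uniform", "distance")) {
  weighting <- match.arg(weighting)
  check_imputable(data)
  stopifnot(k >= 1L)
  X <- data$values
  n <- nrow(X)
  D <- nan_euclidean(X)
  diag(D) <- NA_real_
  out <- X
  fallback <- NULL
  for (j in seq_len(ncol(X))) {
    targets <- which(is.na(X[, j]))
    donors_j <- which(!is.na(X[, j]))
    for (i in targets) {
      d <- D[i, donors_j]
      ok <- !is.na(d)
      if (!any(ok)) {
        out[i, j] <- mean(X[donors_j, j])
        fallback <- rbind(fallback, c(i, j))
        next
      }
      cand <- donors_j[ok]
      dd <- d[ok]
      ord <- order(dd, cand)
      sel <- ord[seq_len(min(k, length(ord)))]
      vals <- X[cand[sel], j]
      if (weighting == "uniform") {
        out[i, j] <- mean(vals)
      } else {
        w <- 1 / pmax(dd[sel], .Machine$double.eps)
        out[i, j] <- sum(w * vals) / sum(w)
      }
    }
  }
  new_imputation_result(data, out,
                        list(name = "knn", k = k, weighting = weighting),
                        fallback_cells = fallback)
}

# learner plug-ins for the round-robin engine; each fits y ~ X on training
# rows and predicts on new rows, returning predictions and the training
# residual standard deviation (used for stochastic draws)
fit_predict_learner <- function(learner, Xtr, ytr, Xpred, seed) {
  lin <- function() {
    fit <- stats::lm.fit(cbind(1, Xtr), ytr)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    list(pred = drop(cbind(1, Xpred) %*% cf),
         sd = stats::sd(fit$residuals))
  }
  res <- switch(learner,
    linear = lin(),
    lasso_cv = {
      if (ncol(Xtr) < 2L || nrow(Xtr) < 10L) lin() else {
        if (!requireNamespace("glmnet", quietly = TRUE))
          stop("learner 'lasso_cv' needs the glmnet package", call. = FALSE)
        set.seed(seed)
        foldid <- sample(rep_len(seq_len(5L), nrow(Xtr)))
        cv <- glmnet::cv.glmnet(Xtr, ytr, nfolds = 5L, foldid = foldid)
        pr <- drop(stats::predict(cv, newx = Xpred, s = "lambda.min"))
        tr <- drop(stats::predict(cv, newx = Xtr, s = "lambda.min"))
        list(pred = pr, sd = stats::sd(ytr - tr))
      }
    },
    random_forest = {
      if (!requireNamespace("ranger", quietly = TRUE))
        stop("learner 'random_forest' needs the ranger package", call. = FALSE)
      df <- as.data.frame(Xtr); df$.y <- ytr
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 100L,
                            seed = seed, num.threads = 1L)
      pr <- stats::predict(fit, data = as.data.frame(Xpred),
                           num.threads = 1L)$predictions
      list(pred = pr, sd = sqrt(max(fit$prediction.error, 0)))
    },
    gradient_boosting = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("learner 'gradient_boosting' needs the xgboost package",
             call. = FALSE)
      dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = 3L,
                      eta = 0.3, nthread = 1L, seed = seed),
        data = dtr, nrounds = 50L, verbose = 0L)
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(Xpred))
      tr <- stats::predict(fit, dtr)
      list(pred = pr, sd = stats::sd(ytr - tr))
    },
    stop("unknown learner: ", learner, call. = FALSE))
  if (!is.finite(res$sd)) res$sd <- 0
  res
}

#' Iterative round-robin imputation
#'
#' Initialises missing cells with column means, then repeatedly regresses each
#' incomplete feature on all other features (using the rows where it is
#' observed) and replaces its missing cells with the predictions. Features are
#' visited in ascending missing-count order (most complete first). Stops when
#' the largest absolute change of any imputed cell falls below `tol` times its
#' column's standard deviation, or after `max_iter` rounds.
#'
#' @param data a [data_matrix()] with at least 2 features.
#' @param learner one of "linear", "lasso_cv", "random_forest",
#'   "gradient_boosting".
#' @param max_iter maximum rounds (default 10).
#' @param tol relative convergence tolerance (default 1e-3).
#' @param seed integer seed; seeded learners are deterministic given it.
#' @param stochastic add Gaussian noise (training residual sd) to each
#'   prediction — the proper-imputation mode used by [impute_mice()].
#' @param visit_order optional explicit column visitation order (indices).
#' @return an `imputation_result` with `n_iterations` and `converged`.
#' @export
impute_iterative <- function(data,
                             learner = c("linear", "lasso_cv", "random_forest",
                                         "gradient_boosting"),
                             max_iter = 10L, tol = 1e-3, seed = 42L,
                             stochastic = FALSE, visit_order = NULL) {
  learner <- match.arg(learner)
  check_imputable(data)
  X <- data$values
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("iterative imputation needs at least 2 features", call. = FALSE)
  mask <- is.na(X)
  incomplete <- which(colSums(mask) > 0L)
  if (is.null(visit_order)) {
    visit_order <- incomplete[order(colSums(mask)[incomplete], incomplete)]
  } else {
    visit_order <- intersect(as.integer(visit_order), incomplete)
  }
  cur <- mean_fill(X)
  if (length(incomplete) == 0L)
    return(new_imputation_result(data, cur, list(name = paste0("iterative_", learner),
                                                 seed = seed),
                                 n_iterations = 0L, converged = TRUE))
  col_sd <- apply(cur, 2L, stats::sd)
  col_sd[col_sd == 0] <- 1
  set.seed(seed)
  converged <- FALSE
  iter <- 0L
  for (round in seq_len(max_iter)) {
    iter <- round
    prev <- cur
    for (j in visit_order) {
      obs <- !mask[, j]
      Xo <- cur[, -j, drop = FALSE]
      pred <- tryCatch(
        fit_predict_learner(learner, Xo[obs, , drop = FALSE], X[obs, j],
                            Xo[!obs, , drop = FALSE],
                            seed = seed + round * 131L + j),
        error = function(e) {
          warning(sprintf("learner failed for feature '%s' (%s); keeping current fill",
                          colnames(X)[j], conditionMessage(e)))
          NULL
        })
      if (is.null(pred)) next
      vals <- pred$pred
      if (stochastic && pred$sd > 0)
        vals <- vals + stats::rnorm(length(vals), 0, pred$sd)
      cur[!obs, j] <- vals
    }
    delta <- abs(cur - prev) / matrix(col_sd, n, p, byrow = TRUE)
    if (max(delta[mask]) < tol) { converged <- TRUE; break }
  }
  new_imputation_result(data, cur,
                        list(name = paste0("iterative_", learner),
                             learner = learner, seed = seed,
                             stochastic = stochastic),
                        n_iterations = iter, converged = converged)
}

#' Multiple imputation by chained equations with Rubin pooling
#'
#' Runs `m` independent stochastic round-robin imputations (predictions
#' perturbed by Gaussian draws with the learner's training-residual standard
#' deviation, each run on its own sub-seed) and pools per-feature mean
#' estimates by Rubin's rules: with per-draw estimates Q_i and their
#' within-imputation variances U_i, the pooled estimate is the mean of the
#' Q_i, and its total variance is W + (1 + 1/m) B where W = mean(U_i) and
#' B = var(Q_i).
#'
#' @param data a [data_matrix()].
#' @param m number of imputations (default 5, must be >= 2).
#' @param learner passed to [impute_iterative()].
#' @param seed master seed; sub-seeds for the draws are derived from it.
#' @param ... further arguments for [impute_iterative()].
#' @return a `multiple_imputation_result`: `draws` (list of m
#'   `imputation_result`s), `pooled` (data.frame: feature, pooled_mean,
#'   within, between, total_var), `m`, `seed`.
#' @export
impute_mice <- function(data, m = 5L, learner = "linear", seed = 42L, ...) {
  stopifnot(m >= 2L)
  check_imputable(data)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, m)
  draws <- lapply(seq_len(m), function(i)
    impute_iterative(data, learner = learner, seed = sub_seeds[i],
                     stochastic = TRUE, ...))
  n <- nrow(data$values)
  Q <- vapply(draws, function(d) colMeans(d$completed),
              numeric(ncol(data$values)))          # p x m
  U <- vapply(draws, function(d) apply(d$completed, 2L, stats::var) / n,
              numeric(ncol(data$values)))
  Q <- matrix(Q, ncol = m); U <- matrix(U, ncol = m)
  W <- rowMeans(U)
  B <- apply(Q, 1L, stats::var)
  pooled <- data.frame(feature = data$feature_names,
                       pooled_mean = rowMeans(Q),
                       within = W, between = B,
                       total_var = W + (1 + 1 / m) * B)
  structure(list(draws = draws, pooled = pooled, m = m, seed = seed,
                 method = list(name = "mice", learner = learner, m = m,
                               seed = seed)),
            class = "multiple_imputation_result")
}

#' @export
print.multiple_imputation_result <- function(x, ...) {
  cat(sprintf("multiple_imputation_result: m = %d draws (%s learner)\n",
              x$m, x$method$learner))
  print(x$pooled, digits = 4)
  invisible(x)
}
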