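#' EM estimation of mean and covariance for incomplete data
#'
#' Fits the maximum-likelihood mean vector and covariance matrix of an
#' incomplete data matrix under the multivariate-normal model. Rows are
#' grouped by missingness pattern; the E-step fills each pattern's missing
#' block with its conditional expectation given the observed block under the
#' current parameters (and adds the conditional covariance to the second
#' moments), and the M-step re-estimates `mu` and `sigma` from the completed
#' sufficient statistics. Iterates until the relative change in the
#' observed-data log-likelihood falls below `tol` or `max_iter` is reached;
#' the observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param data a [data_matrix()] or numeric matrix with `NA`s.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 200). Non-convergence is
#'   reported via `converged = FALSE`, never an error.
#' @param ridge ridge added to `sigma` when an observed-block inverse fails;
#'   `NULL` (default) uses `1e-6 * trace(sigma) / p` at the time of failure.
#' @return an `mvn_estimate`: `mu`, `sigma` (ML, divisor n), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `tol_used`.
#' @export
em_fit <- function(data, tol = 1e-6, max_iter = 200L, ridge = NULL) {
  X <- if (inherits(data, "data_matrix")) data$values else as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  nobs <- colSums(!is.na(X))
  if (any(nobs == 0L))
    stop("unusable feature with zero observed values: ",
         paste(colnames(X)[nobs == 0L], collapse = ", "), call. = FALSE)
  if (n <= p)
    warning("n <= p: EM covariance estimate may be unstable")

  pats <- missing_patterns(data_matrix(X))
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2L, stats::var, na.rm = TRUE) * (nobs - 1) / pmax(nobs, 2)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, p)

  safe_solve <- function(S) {
    out <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(out)) {
      r <- if (is.null(ridge)) 1e-6 * sum(diag(S)) / nrow(S) else ridge
      out <- solve(S + diag(r, nrow(S)))
    }
    out
  }

  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  ll_old <- -Inf
  repeat {
    iter <- iter + 1L
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (pat in pats) {
      o <- pat$observed_idx
      m <- setdiff(seq_len(p), o)
      rows <- pat$row_indices
      k <- length(rows)
      if (length(o) == 0L) {
        # nothing observed: conditional on nothing is the marginal
        T1 <- T1 + k * mu
        T2 <- T2 + k * (sigma + tcrossprod(mu))
        next
      }
      Xo <- X[rows, o, drop = FALSE]
      Soo_inv <- safe_solve(sigma[o, o, drop = FALSE])
      dev <- sweep(Xo, 2L, mu[o])
      # observed-data log-likelihood contribution of this pattern
      ld <- determinant(sigma[o, o, drop = FALSE], logarithm = TRUE)$modulus
      q <- rowSums((dev %*% Soo_inv) * dev)
      ll <- ll - 0.5 * (k * (length(o) * log(2 * pi) + ld) + sum(q))
      comp <- matrix(0, k, p)
      comp[, o] <- Xo
      Cm <- matrix(0, p, p)
      if (length(m) > 0L) {
        B <- sigma[m, o, drop = FALSE] %*% Soo_inv        # regression coefs
        comp[, m] <- matrix(mu[m], k, length(m), byrow = TRUE) + dev %*% t(B)
        Cmm <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
        Cm[m, m] <- k * Cmm
      }
      T1 <- T1 + colSums(comp)
      T2 <- T2 + crossprod(comp) + Cm
    }
    mu_new <- T1 / n
    sigma_new <- T2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      mu <- mu_new; sigma <- sigma_new
      break
    }
    mu <- mu_new; sigma <- sigma_new
    ll_old <- ll
    if (iter >= max_iter) break
  }
  names(mu) <- colnames(X)
  dimnames(sigma) <- list(colnames(X), colnames(X))
  structure(list(mu = mu, sigma = sigma,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, tol_used = tol),
            class = "mvn_estimate")
}

#' @export
print.mvn_estimate <- function(x, ...) {
  cat(sprintf("mvn_estimate: p = %d, loglik = %.3f, %d EM iterations (%s)\n",
              length(x$mu), x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
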