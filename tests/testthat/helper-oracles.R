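# deterministic uniform stream shared with external cross-checks
lcg_uniform <- function(n, s = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (1103515245 * s + 12345) %% 2^31
    out[i] <- s / 2^31
  }
  out
}

# brute-force nan-Euclidean KNN fill: plain loops, independent of the
# vectorised implementation
oracle_knn <- function(X, k, weighting = "uniform") {
  n <- nrow(X); p <- ncol(X)
  out <- X
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (!is.na(X[i, j])) next
    cand <- c(); dd <- c()
    for (r in seq_len(n)) {
      if (r == i || is.na(X[r, j])) next
      shared <- which(!is.na(X[i, ]) & !is.na(X[r, ]))
      if (length(shared) == 0L) next
      d <- sqrt(p / length(shared) * sum((X[i, shared] - X[r, shared])^2))
      cand <- c(cand, r); dd <- c(dd, d)
    }
    if (length(cand) == 0L) {
      out[i, j] <- mean(X[, j], na.rm = TRUE)
      next
    }
    ord <- order(dd, cand)[seq_len(min(k, length(cand)))]
    vals <- X[cand[ord], j]
    out[i, j] <- if (weighting == "uniform") mean(vals) else {
      w <- 1 / pmax(dd[ord], .Machine$double.eps)
      sum(w * vals) / sum(w)
    }
  }
  out
}

# random data_matrix with an MCAR mask, every column keeping >= 1 observation
random_masked_dm <- function(n, p, rate, seed) {
  set.seed(seed)
  X <- matrix(round(stats::rnorm(n * p), 4), n, p)
  mask <- matrix(stats::runif(n * p) < rate, n, p)
  for (j in seq_len(p)) if (all(mask[, j])) mask[1, j] <- FALSE
  X[mask] <- NA_real_
  data_matrix(X)
}
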