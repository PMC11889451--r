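#' Construct a data_matrix
#'
#' The central container of the package: an n x p numeric matrix in which
#' missing entries are `NA`, together with unique feature names, unique sample
#' ids, and an optional fully observed outcome vector `Y`. The missingness
#' mask is always recomputed from the values (`is.na`), never stored as
#' separate mutable state.
#'
#' @param values numeric matrix (or data.frame coercible to one); `NA` marks a
#'   missing cell.
#' @param feature_names character vector of length `ncol(values)`; defaults to
#'   existing column names or `V1..Vp`.
#' @param sample_ids character vector of length `nrow(values)`; defaults to
#'   existing row names or 0-based row positions rendered as strings.
#' @param outcome optional numeric vector of length `nrow(values)` with no
#'   missing values.
#' @return an object of class `data_matrix` with elements `values`,
#'   `feature_names`, `sample_ids`, `outcome`.
#' @examples
#' dm <- data_matrix(matrix(c(1, NA, 3, 4), 2, 2))
#' missing_mask(dm)
#' @export
data_matrix <- function(values, feature_names = NULL, sample_ids = NULL,
                        outcome = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !(is.numeric(values) || is.logical(values)))
    stop("`values` must be a numeric matrix", call. = FALSE)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (n < 1L || p < 1L) stop("need n >= 1 and p >= 1", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("V", seq_len(p))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n) - 1L)
  }
  feature_names <- as.character(feature_names)
  sample_ids <- as.character(sample_ids)
  if (length(feature_names) != p) stop("feature_names length != p", call. = FALSE)
  if (length(sample_ids) != n) stop("sample_ids length != n", call. = FALSE)
  if (anyDuplicated(feature_names)) stop("duplicate feature names", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (!is.null(outcome)) {
    outcome <- as.numeric(outcome)
    if (length(outcome) != n) stop("outcome length != n", call. = FALSE)
    if (anyNA(outcome)) stop("outcome must not contain missing values", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values, feature_names = feature_names,
                 sample_ids = sample_ids, outcome = outcome),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  n <- nrow(x$values); p <- ncol(x$values)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("data_matrix: %d samples x %d features, %d missing cells (%.1f%%)%s\n",
              n, p, nmiss, 100 * nmiss / (n * p),
              if (!is.null(x$outcome)) ", with outcome Y" else ""))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Missingness mask of a data_matrix
#'
#' @param data a [data_matrix()].
#' @return logical n x p matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(data) {
  stopifnot(inherits(data, "data_matrix"))
  is.na(data$values)
}

#' Read a numeric CSV into a data_matrix
#'
#' Reads an RFC 4180-style CSV with a header row. Cells equal to one of
#' `missing_tokens` become missing; every other cell must parse as a finite
#' real number. An optional outcome column is split off into `outcome` and
#' must itself be complete.
#'
#' @param path path to the CSV file.
#' @param missing_tokens character vector of cell values treated as missing.
#'   The default covers common CSV dialects ("", "NA", "NaN", "nan", "null").
#' @param outcome_col optional name of the outcome column Y.
#' @param id_col optional name of a sample-id column.
#' @return a [data_matrix()].
#' @export
read_missing_csv <- function(path,
                             missing_tokens = c("", "NA", "NaN", "nan", "null"),
                             outcome_col = NULL, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character())
  if (anyDuplicated(names(df)))
    stop("duplicate column names in ", path, call. = FALSE)
  sample_ids <- NULL
  if (!is.null(id_col)) {
    if (!id_col %in% names(df)) stop("id column not found: ", id_col, call. = FALSE)
    sample_ids <- df[[id_col]]
    df[[id_col]] <- NULL
  }
  parse_col <- function(x, name, allow_missing = TRUE) {
    x <- trimws(x)
    miss <- x %in% missing_tokens
    out <- rep(NA_real_, length(x))
    ok <- !miss
    suppressWarnings(vals <- as.numeric(x[ok]))
    bad <- which(ok)[is.na(vals) | !is.finite(vals)]
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], name, x[bad[1]]), call. = FALSE)
    out[ok] <- vals
    if (!allow_missing && any(miss))
      stop(sprintf("outcome column '%s' contains missing values", name),
           call. = FALSE)
    out
  }
  outcome <- NULL
  if (!is.null(outcome_col)) {
    if (!outcome_col %in% names(df))
      stop("outcome column not found: ", outcome_col, call. = FALSE)
    outcome <- parse_col(df[[outcome_col]], outcome_col, allow_missing = FALSE)
    df[[outcome_col]] <- NULL
  }
  if (ncol(df) < 1L) stop("no feature columns left after splitting", call. = FALSE)
  values <- vapply(names(df), function(nm) parse_col(df[[nm]], nm),
                   numeric(nrow(df)))
  if (nrow(df) == 1L) values <- matrix(values, nrow = 1L,
                                       dimnames = list(NULL, names(df)))
  data_matrix(values, feature_names = names(df), sample_ids = sample_ids,
              outcome = outcome)
}

#' Write a data_matrix to CSV
#'
#' Missing cells are written as empty fields; the outcome, if any, is written
#' as a trailing column. `read_missing_csv()` on the result round-trips the
#' values, mask and names for finite decimal inputs.
#'
#' @param data a [data_matrix()].
#' @param path output path.
#' @param outcome_col name used for the outcome column (default "Y").
#' @export
write_missing_csv <- function(data, path, outcome_col = "Y") {
  stopifnot(inherits(data, "data_matrix"))
  df <- as.data.frame(data$values, check.names = FALSE)
  if (!is.null(data$outcome)) df[[outcome_col]] <- data$outcome
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Enumerate missingness patterns
#'
#' A missingness pattern is a distinct row-wise observed/missing signature.
#' Patterns partition the rows; they are returned sorted by descending member
#' count, ties broken by the signature's lexicographic order.
#'
#' @param data a [data_matrix()].
#' @return a list of patterns; each has `signature` (logical, TRUE = observed),
#'   `row_indices`, `observed_idx` (sorted), and `count`.
#' @export
missing_patterns <- function(data) {
  stopifnot(inherits(data, "data_matrix"))
  obs <- !is.na(data$values)
  keys <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_along(keys), keys)
  pats <- lapply(groups, function(rows) {
    sig <- unname(obs[rows[1L], ])
    list(signature = sig, row_indices = rows,
         observed_idx = which(sig), count = length(rows))
  })
  counts <- vapply(pats, `[[`, integer(1), "count")
  ord <- order(-counts, names(groups), method = "radix", decreasing = FALSE)
  unname(pats[ord])
}

#' Summarise missingness
#'
#' Percentages of missing cells per feature, per sample, and overall, plus the
#' missingness pattern table.
#'
#' @param data a [data_matrix()].
#' @return a `missing_summary` list with `per_feature_pct`, `per_sample_pct`,
#'   `total_pct`, `pattern_table`, and `flags` naming all-missing or
#'   all-observed features (kept in the data, flagged here).
#' @export
missing_summary <- function(data) {
  stopifnot(inherits(data, "data_matrix"))
  m <- is.na(data$values)
  per_feature <- 100 * colMeans(m)
  per_sample <- 100 * rowMeans(m)
  names(per_feature) <- data$feature_names
  names(per_sample) <- data$sample_ids
  all_missing <- data$feature_names[colSums(!m) == 0L]
  structure(list(per_feature_pct = per_feature,
                 per_sample_pct = per_sample,
                 total_pct = 100 * mean(m),
                 pattern_table = missing_patterns(data),
                 flags = list(all_missing_features = all_missing)),
            class = "missing_summary")
}

#' @export
print.missing_summary <- function(x, ...) {
  cat(sprintf("missing_summary: %.2f%% of cells missing, %d patterns\n",
              x$total_pct, length(x$pattern_table)))
  cat("per-feature %:\n")
  print(round(x$per_feature_pct, 2))
  if (length(x$flags$all_missing_features))
    cat("all-missing features:",
        paste(x$flags$all_missing_features, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation between missingness indicators
#'
#' Pearson correlation of the binary missing-indicator columns, useful for
#' spotting features whose values go missing together (a sign of shared
#' causes). Features whose indicator is constant (fully observed or fully
#' missing) get `NA` rows/columns rather than raising an error.
#'
#' @param data a [data_matrix()] with at least 2 features.
#' @return p x p correlation matrix; diagonal 1 where the indicator varies.
#' @export
pattern_correlation <- function(data) {
  stopifnot(inherits(data, "data_matrix"))
  p <- ncol(data$values)
  if (p < 2L) stop("need at least 2 features", call. = FALSE)
  ind <- matrix(as.numeric(is.na(data$values)), nrow = nrow(data$values))
  sds <- apply(ind, 2L, stats::sd)
  out <- suppressWarnings(stats::cor(ind))
  out[sds == 0, ] <- NA_real_
  out[, sds == 0] <- NA_real_
  dimnames(out) <- list(data$feature_names, data$feature_names)
  out
}
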