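#' Construct a feature table
#'
#' A feature table bundles a numeric descriptor matrix `X` (one row per
#' compound or data point, one named column per descriptor) with a
#' continuous response `y` (log BB units in the blood-brain-barrier use
#' case) and unique sample identifiers. It is the container every other
#' function in the package operates on.
#'
#' @param X numeric matrix (or data frame coercible to one) with unique
#'   column names.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param sample_ids character vector of unique identifiers; defaults to
#'   the row names of `X` or `"s1"`, `"s2"`, ...
#' @param target_name name of the response, used in printing and logs.
#' @return An object of class `"feature_table"`: a list with elements
#'   `X`, `y`, `sample_ids`, `target_name`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("f1", "f2"))),
#'                     y = rnorm(10))
#' ft
#' @export
feature_table <- function(X, y, sample_ids = NULL, target_name = "y") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop_validation("X must be a numeric matrix")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    stop_validation("duplicate feature names: ",
                    paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop_validation("length(y) must equal nrow(X)")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X) || anyDuplicated(sample_ids))
    stop_validation("sample_ids must be unique and match nrow(X)")
  rownames(X) <- sample_ids
  structure(list(X = X, y = y, sample_ids = sample_ids,
                 target_name = target_name),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", length(x$sample_ids), " samples x ",
      ncol(x$X), " features; target '", x$target_name, "'\n", sep = "")
  n_miss <- sum(is.na(x$X))
  if (n_miss > 0) cat("  (", n_miss, " missing descriptor values)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Read a feature table from CSV
#'
#' Expects a comma-separated file with a header row. One column holds the
#' continuous target; an optional id column holds sample identifiers;
#' every remaining column is treated as a descriptor. Non-numeric cells in
#' descriptor columns are recorded as missing values (and later removed by
#' [drop_unusable_features()]).
#'
#' @param path path to a CSV file.
#' @param target_column name of the response column.
#' @param id_column optional name of the identifier column; when `NULL`
#'   row numbers are used.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, target_column, id_column = NULL) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!target_column %in% names(df))
    stop_config("target column '", target_column, "' not present in ", path)
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df))
      stop_config("id column '", id_column, "' not present in ", path)
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  y <- suppressWarnings(as.numeric(df[[target_column]]))
  df[[target_column]] <- NULL
  if (anyDuplicated(names(df)))
    stop_validation("duplicate feature names in ", path)
  X <- vapply(df, function(col) suppressWarnings(as.numeric(col)),
              numeric(nrow(df)))
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(df)))
  colnames(X) <- names(df)
  feature_table(X, y, sample_ids = ids, target_name = target_column)
}

#' Remove unusable descriptor columns
#'
#' Drops every feature column that contains a missing value or shows no
#' variation across the data set. Sample rows and the target are never
#' altered. The removals are recorded in the `"removal_log"` attribute of
#' the returned table, a data frame with columns `feature` and `reason`
#' (`"missing"` or `"invariant"`).
#'
#' @param table a [feature_table()].
#' @return The cleaned feature table (with a `"removal_log"` attribute).
#' @export
drop_unusable_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$X
  has_na <- apply(X, 2, anyNA)
  spread <- apply(X, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) > 0 && max(col) > min(col)
  })
  reason <- ifelse(has_na, "missing", ifelse(!spread, "invariant", NA))
  drop <- !is.na(reason)
  if (all(drop)) stop_validation("all feature columns are unusable")
  out <- table
  out$X <- X[, !drop, drop = FALSE]
  attr(out, "removal_log") <- data.frame(
    feature = colnames(X)[drop], reason = reason[drop],
    stringsAsFactors = FALSE)
  out
}

#' Remove near-duplicate descriptor columns
#'
#' Many descriptor sets contain columns that are numerically almost
#' identical (rescaled copies, re-exported duplicates). A single greedy
#' pass over feature pairs in column order removes one member of every
#' pair whose absolute Pearson correlation exceeds `cutoff`; which member
#' is dropped is decided by the seeded RNG, mirroring the convention of
#' discarding a random member rather than privileging column order. The
#' default cutoff is deliberately extreme: highly correlated descriptors
#' can still be complementary, so only effectively identical columns go.
#'
#' @param table a [feature_table()] with no missing or invariant columns
#'   (run [drop_unusable_features()] first).
#' @param cutoff absolute-correlation threshold in (0, 1]; default
#'   0.999999.
#' @param seed integer seed for the member-choice RNG; `NULL` uses the
#'   ambient stream.
#' @return The reduced feature table; attribute `"removal_log"` holds a
#'   data frame with columns `feature`, `reason` (`"duplicate_of:<kept>"`).
#' @export
drop_near_duplicate_features <- function(table, cutoff = 0.999999, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$X) < 2) stop_config("need at least 2 features")
  if (!(cutoff > 0 && cutoff <= 1)) stop_config("cutoff must be in (0, 1]")
  X <- table$X
  if (anyNA(X)) stop_validation("missing values present; clean the table first")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_validation("zero-variance column present; clean the table first")
  cm <- abs(suppressWarnings(stats::cor(X)))
  n <- ncol(X)
  keep <- rep(TRUE, n)
  kept_of <- character(0); removed <- character(0)
  local_seed(seed, {
    for (i in seq_len(n - 1)) {
      if (!keep[i]) next
      for (j in seq((i + 1), n)) {
        if (!keep[j]) next
        if (!is.na(cm[i, j]) && cm[i, j] > cutoff) {
          drop_i <- stats::runif(1) < 0.5
          victim <- if (drop_i) i else j
          survivor <- if (drop_i) j else i
          keep[victim] <- FALSE
          removed <- c(removed, colnames(X)[victim])
          kept_of <- c(kept_of, colnames(X)[survivor])
          if (drop_i) break  # column i is gone; move to next i
        }
      }
    }
  })
  out <- table
  out$X <- X[, keep, drop = FALSE]
  attr(out, "removal_log") <- data.frame(
    feature = removed,
    reason = if (length(kept_of)) paste0("duplicate_of:", kept_of)
             else character(0),
    stringsAsFactors = FALSE)
  out
}

#' Clean a feature table
#'
#' Convenience wrapper applying [drop_unusable_features()] then
#' [drop_near_duplicate_features()], concatenating the two removal logs.
#'
#' @inheritParams drop_near_duplicate_features
#' @return The cleaned feature table with combined `"removal_log"`.
#' @export
clean_features <- function(table, cutoff = 0.999999, seed = NULL) {
  t1 <- drop_unusable_features(table)
  log1 <- attr(t1, "removal_log")
  t2 <- drop_near_duplicate_features(t1, cutoff = cutoff, seed = seed)
  attr(t2, "removal_log") <- rbind(log1, attr(t2, "removal_log"))
  t2
}

#' Kennard-Stone train/test split
#'
#' Deterministic maximin selection of a representative training set. The
#' first training point is the sample closest (Euclidean distance) to the
#' centroid of feature space; each subsequent point is the candidate whose
#' minimum distance to the already-selected set is largest. Ties are broken
#' by the lowest row index, so the split is reproducible and stable under
#' re-runs. Distances are computed on z-scored features by default because
#' raw quantum-chemical descriptors span several orders of magnitude; the
#' response never enters the distance computation.
#'
#' @param table a [feature_table()] without missing values.
#' @param n_train number of training samples, `1 <= n_train < n`.
#' @param standardize z-score the features before computing distances
#'   (default `TRUE`).
#' @return An object of class `"ks_split"`: list with integer vectors
#'   `train_indices` (in selection order) and `test_indices`.
#' @examples
#' ft <- feature_table(matrix(c(0, 1, 2, 10), ncol = 1), y = rep(0, 4))
#' kennard_stone_split(ft, n_train = 3)
#' @export
kennard_stone_split <- function(table, n_train, standardize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$X)
  if (!(n_train >= 1 && n_train < n))
    stop_config("n_train must satisfy 1 <= n_train < ", n)
  X <- table$X
  if (anyNA(X)) stop_validation("missing values present; clean the table first")
  if (standardize) X <- apply_scaler(X, fit_scaler(X))
  centroid <- matrix(colMeans(X), nrow = 1)
  d_centroid <- pairwise_sqdist(X, centroid)[, 1]
  first <- which.min(d_centroid)  # lowest index on ties
  selected <- integer(n_train)
  selected[1] <- first
  if (n_train > 1) {
    D <- pairwise_sqdist(X, X)
    min_d <- D[, first]
    min_d[first] <- -Inf
    for (s in 2:n_train) {
      nxt <- which.max(min_d)  # lowest index on ties
      selected[s] <- nxt
      min_d <- pmin(min_d, D[, nxt])
      min_d[nxt] <- -Inf
    }
  }
  structure(list(train_indices = selected,
                 test_indices = setdiff(seq_len(n), selected)),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat("Kennard-Stone split: ", length(x$train_indices), " train / ",
      length(x$test_indices), " test\n", sep = "")
  invisible(x)
}

# Restrict a feature table to a row subset (used internally for splits).
subset_rows <- function(table, rows) {
  feature_table(table$X[rows, , drop = FALSE], table$y[rows],
                sample_ids = table$sample_ids[rows],
                target_name = table$target_name)
}
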