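# Post-hoc analysis of replicated runs: which features keep being
# selected, and what do they have in common?

# Accept a chromosome, a ga_svr fit, or a bare integer vector.
extract_features <- function(model) {
  if (inherits(model, "ga_svr")) return(model$best$chromosome$features)
  if (inherits(model, "chromosome")) return(model$features)
  as.integer(model)
}

#' Feature occurrence counts across replicate models
#'
#' Counts, for every feature in the universe, how many of the supplied
#' models selected it. With wrapper selection a single run's subset is
#' noisy; features that recur across many independently seeded runs are
#' the robust signal carriers.
#'
#' @param models list of models — `"ga_svr"` fits, [chromosome()]s, or
#'   integer index vectors.
#' @param universe character vector of all candidate feature names (the
#'   columns of the table the models were fit on).
#' @return A data frame of class `"feature_frequency"` with columns
#'   `feature_index`, `feature_name`, `count`, `n_models`, sorted by
#'   descending count, ties by ascending index.
#' @export
feature_frequency <- function(models, universe) {
  N <- length(universe)
  counts <- integer(N)
  for (m in models) {
    f <- extract_features(m)
    if (any(f < 1 | f > N))
      stop_validation("model references a feature outside the universe")
    counts[f] <- counts[f] + 1L
  }
  out <- data.frame(feature_index = seq_len(N), feature_name = universe,
                    count = counts, n_models = length(models),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$feature_index), ]
  rownames(out) <- NULL
  class(out) <- c("feature_frequency", "data.frame")
  out
}

#' Aggregate feature occurrences by property group
#'
#' Descriptor sets contain many near-synonymous columns (e.g. several
#' polar-surface-area variants at different pH); summing occurrence
#' counts within user-defined physicochemical groups exposes which
#' underlying property the models keep reaching for. Features absent
#' from the map are pooled under `"other"`.
#'
#' @param freq a [feature_frequency()] table.
#' @param groups named character vector mapping `feature_name` to a group
#'   label, or a data frame with columns `feature` and `group`.
#' @return Data frame with columns `group`, `count` (sum of member
#'   feature counts), `n_features`, sorted by descending count.
#' @export
group_occurrence <- function(freq, groups = character(0)) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$feature))
  lab <- groups[freq$feature_name]
  lab[is.na(lab)] <- "other"
  agg <- stats::aggregate(
    list(count = freq$count, n_features = rep(1L, nrow(freq))),
    by = list(group = as.character(lab)), FUN = sum)
  agg <- agg[order(-agg$count, agg$group), ]
  rownames(agg) <- NULL
  agg
}

#' Evaluate a chromosome on a train/test split
#'
#' Trains the chromosome's SVR (its parameters, its feature subset) on
#' the training partition only — the feature scaler is also fit there, so
#' nothing about the held-out samples touches training — and reports
#' train r-squared, test r-squared, test RMSE, and the 10-fold CV MSE on
#' the training partition.
#'
#' @param table the full [feature_table()].
#' @param split a [kennard_stone_split()] (or any list with
#'   `train_indices` / `test_indices`).
#' @param chromo a [chromosome()] valid for `table`.
#' @param n_folds CV folds for the training-partition CV MSE.
#' @param seed fold-assignment seed.
#' @return An object of class `"svr_report"`: list with `train_r2`,
#'   `test_r2`, `test_rmse`, `cv_mse`, `predictions` (list with `train`
#'   and `test` prediction vectors), `chromosome`.
#' @export
evaluate_final_model <- function(table, split, chromo, n_folds = 10,
                                 seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  N <- ncol(table$X)
  feats <- extract_features(chromo)
  if (any(feats < 1 | feats > N))
    stop_validation("chromosome references a feature outside the table")
  params <- if (inherits(chromo, "chromosome")) as_svm_params(chromo) else
    stop_validation("chromo must be a chromosome")
  train <- subset_rows(table, split$train_indices)
  model <- train_svr(train$X[, feats, drop = FALSE], train$y, params)
  pred_train <- predict(model, train$X[, feats, drop = FALSE])
  cvm <- cv_mse(train, feats, params, n_folds = n_folds, seed = seed)
  out <- list(train_r2 = r_squared(pred_train, train$y),
              cv_mse = cvm,
              chromosome = chromo,
              predictions = list(train = pred_train))
  if (length(split$test_indices) == 0) {
    warning("empty test partition; test metrics omitted")
    out$test_r2 <- NA_real_; out$test_rmse <- NA_real_
  } else {
    test <- subset_rows(table, split$test_indices)
    pred_test <- predict(model, test$X[, feats, drop = FALSE])
    out$test_r2 <- r_squared(pred_test, test$y)
    out$test_rmse <- sqrt(mse(pred_test, test$y))
    out$predictions$test <- pred_test
  }
  class(out) <- "svr_report"
  out
}

#' @export
print.svr_report <- function(x, ...) {
  cat(sprintf("Final-model report: train r^2 = %.4f, test r^2 = %s, test RMSE = %s, CV MSE = %.6g\n",
              x$train_r2,
              ifelse(is.na(x$test_r2), "NA", sprintf("%.4f", x$test_r2)),
              ifelse(is.na(x$test_rmse), "NA", sprintf("%.4f", x$test_rmse)),
              x$cv_mse))
  invisible(x)
}
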