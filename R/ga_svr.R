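#' Fit an SVR model with genetic-algorithm feature and parameter search
#'
#' The package's core fitting function. A real-coded genetic algorithm
#' evolves mixed chromosomes — three bounded float genes (C, gamma,
#' epsilon) plus a fixed-size set of `k_features` distinct feature
#' indices — to minimize the mean squared error of k-fold
#' cross-validation of an RBF-kernel SVR, so hyperparameters and the
#' feature subset are optimized simultaneously. Fold assignment is drawn
#' once per run, making fitness a deterministic function of the
#' chromosome within the run; identical `(table, config)` give an
#' identical fit. After the search, the best chromosome is refit on the
#' whole supplied table at the solver's default tolerance.
#'
#' @param table a cleaned [feature_table()] (no missing values, no
#'   constant columns).
#' @param config a [ga_config()]; its `seed` controls every source of
#'   randomness in the run.
#' @return An object of class `"ga_svr"` with elements:
#'   \describe{
#'     \item{history}{data frame with per-generation `generation`,
#'       `best_cv_mse`, `mean_cv_mse` (generation 0 is the initial
#'       random population).}
#'     \item{best}{list with the all-time best `chromosome` and its
#'       `cv_mse`.}
#'     \item{model}{the best chromosome refit on the full table
#'       ([train_svr()]).}
#'     \item{cv_predictions}{pooled CV predictions of the best
#'       chromosome (same folds the search used).}
#'     \item{config, feature_names, target_name, n_evaluations, call}{
#'       bookkeeping.}
#'   }
#' @seealso [run_replicates()] for the replicated sweep over `k`,
#'   [grid_search()] for the no-selection baseline.
#' @examples
#' spec <- synthetic_spec(n_samples = 60, n_features = 8,
#'                        informative_indices = c(2, 5),
#'                        effect_sizes = c(1, -1), seed = 7)
#' tab <- generate_table(spec)$table
#' fit <- ga_svr(tab, ga_config(k_features = 2, population_size = 10,
#'                              generations = 3, n_folds = 5, seed = 7))
#' summary(fit)
#' @export
ga_svr <- function(table, config) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "ga_config"))
  if (anyNA(table$X))
    stop_validation("table contains missing values; clean it first")
  n_features <- ncol(table$X)
  if (config$k_features > n_features)
    stop_config("k_features exceeds the number of candidate features")
  cl <- match.call()

  folds <- cv_folds(table$sample_ids, config$n_folds, config$seed)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fitness_fn <- function(chr) {
    key <- paste(sprintf("%.17g", c(chr$C, chr$gamma, chr$epsilon)),
                 paste(sort(chr$features), collapse = ","), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- cv_mse(table, chr$features, as_svm_params(chr), folds = folds,
                  tolerance = config$fit_tolerance)
    n_evals <<- n_evals + 1L
    cache[[key]] <- val
    val
  }

  run <- local_seed(config$seed, {
    population <- lapply(seq_len(config$population_size), function(i) {
      chr <- random_chromosome(config, n_features)
      list(chromosome = chr, fitness = fitness_fn(chr))
    })
    history <- vector("list", config$generations + 1L)
    fits <- vapply(population, `[[`, numeric(1), "fitness")
    history[[1]] <- data.frame(generation = 0L, best_cv_mse = min(fits),
                               mean_cv_mse = mean(fits))
    best <- population[[which.min(fits)]]
    gen <- 0L
    while (gen < config$generations) {
      gen <- gen + 1L
      population <- next_generation(population, config, fitness_fn,
                                    n_features)
      fits <- vapply(population, `[[`, numeric(1), "fitness")
      if (min(fits) < best$fitness) best <- population[[which.min(fits)]]
      history[[gen + 1L]] <- data.frame(generation = gen,
                                        best_cv_mse = min(fits),
                                        mean_cv_mse = mean(fits))
    }
    list(history = do.call(rbind, history), best = best)
  })

  best_chr <- run$best$chromosome
  final_model <- train_svr(table$X[, best_chr$features, drop = FALSE],
                           table$y, as_svm_params(best_chr))
  cv_pred <- cv_predictions(table, best_chr$features, as_svm_params(best_chr),
                            folds = folds)
  structure(list(history = run$history,
                 best = list(chromosome = best_chr,
                             cv_mse = run$best$fitness),
                 model = final_model,
                 fitted_values = predict(final_model,
                                         table$X[, best_chr$features,
                                                 drop = FALSE]),
                 cv_predictions = cv_pred,
                 config = config,
                 feature_names = colnames(table$X),
                 target_name = table$target_name,
                 y = table$y,
                 n_evaluations = n_evals,
                 call = cl),
            class = "ga_svr")
}

#' @export
print.ga_svr <- function(x, ...) {
  chr <- x$best$chromosome
  cat("GA/SVR fit (", x$config$generations, " generations, population ",
      x$config$population_size, ")\n", sep = "")
  cat(sprintf("  best CV MSE: %.6g\n", x$best$cv_mse))
  cat(sprintf("  C = %.6g, gamma = %.6g, epsilon = %.6g\n",
              chr$C, chr$gamma, chr$epsilon))
  cat("  features [", length(chr$features), "]: ",
      paste(x$feature_names[chr$features], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ga_svr <- function(object, ...) {
  chr <- object$best$chromosome
  out <- list(
    k_features = length(chr$features),
    features = stats::setNames(chr$features,
                               object$feature_names[chr$features]),
    params = c(C = chr$C, gamma = chr$gamma, epsilon = chr$epsilon),
    cv_mse = object$best$cv_mse,
    cv_r2 = r_squared(object$cv_predictions, object$y),
    generations = object$config$generations,
    n_evaluations = object$n_evaluations)
  class(out) <- "summary.ga_svr"
  out
}

#' @export
print.summary.ga_svr <- function(x, ...) {
  cat("GA/SVR model summary\n")
  cat(sprintf("  selected features (%d): %s\n", x$k_features,
              paste(names(x$features), collapse = ", ")))
  cat(sprintf("  C = %.6g, gamma = %.6g, epsilon = %.6g\n",
              x$params["C"], x$params["gamma"], x$params["epsilon"]))
  cat(sprintf("  CV MSE = %.6g, CV r^2 = %.4f (%d generations, %d fitness evaluations)\n",
              x$cv_mse, x$cv_r2, x$generations, x$n_evaluations))
  invisible(x)
}

#' @export
coef.ga_svr <- function(object, ...) {
  chr <- object$best$chromosome
  out <- c(C = chr$C, gamma = chr$gamma, epsilon = chr$epsilon)
  attr(out, "features") <- stats::setNames(
    chr$features, object$feature_names[chr$features])
  out
}

#' Predict from a GA/SVR fit
#'
#' @param object a `"ga_svr"` fit.
#' @param newdata numeric matrix or data frame carrying (at least) the
#'   selected feature columns, matched by name when column names are
#'   present, by position in the original table otherwise.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.ga_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sel <- object$best$chromosome$features
  sel_names <- object$feature_names[sel]
  if (!is.null(colnames(newdata))) {
    missing_cols <- setdiff(sel_names, colnames(newdata))
    if (length(missing_cols))
      stop_validation("newdata lacks selected feature columns: ",
                      paste(missing_cols, collapse = ", "))
    newdata <- newdata[, sel_names, drop = FALSE]
  } else {
    newdata <- newdata[, sel, drop = FALSE]
  }
  predict(object$model, newdata)
}

#' @export
fitted.ga_svr <- function(object, ...) object$fitted_values

#' @export
residuals.ga_svr <- function(object, ...) object$y - object$fitted_values

#' Convergence plot of a GA/SVR run
#'
#' Best and mean CV MSE per generation; with elitism the best trace is
#' non-increasing.
#'
#' @param x a `"ga_svr"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ga_svr <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$mean_cv_mse, type = "l", col = "grey60",
                 xlab = "generation", ylab = "CV MSE",
                 main = "GA/SVR convergence", ...)
  graphics::lines(h$generation, h$best_cv_mse, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("population mean", "best"),
                   col = c("grey60", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Replicated GA runs over a range of subset sizes
#'
#' For each `k` in `k_range`, runs `n_runs` independently seeded
#' evolutions and keeps the best (minimum CV MSE) per `k`. When a
#' train/test `split` is supplied the GA searches on the training
#' partition only and the summary reports held-out performance of each
#' per-k best model; without a split the GA sees the whole table and the
#' test columns are `NA`. Per-run seeds are derived as
#' `seed + 1000 * k + run`, so replicate sets with the same base seed are
#' identical.
#'
#' @param table a cleaned [feature_table()].
#' @param config a [ga_config()] template; `k_features` and `seed` are
#'   overridden per run.
#' @param n_runs replicate evolutions per subset size.
#' @param k_range integer vector of subset sizes to sweep.
#' @param split optional [kennard_stone_split()] of `table`.
#' @return An object of class `"ga_svr_replicates"`: `runs` (list of
#'   lists of `"ga_svr"` fits, indexed by `k`), `best` (list of the per-k
#'   best fits), and `summary` (data frame with columns `k`, `cv_mse`,
#'   `cv_r2`, `train_r2`, `test_r2`, `C`, `gamma`, `epsilon`).
#' @export
run_replicates <- function(table, config, n_runs, k_range, split = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "ga_config"))
  if (n_runs < 1) stop_config("n_runs must be >= 1")
  search_table <- if (is.null(split)) table else
    subset_rows(table, split$train_indices)
  runs <- list(); best <- list()
  summary_rows <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    k_runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      cfg <- config
      cfg$k_features <- as.integer(k)
      cfg$seed <- config$seed + 1000 * k + r
      k_runs[[r]] <- ga_svr(search_table, cfg)
    }
    fits <- vapply(k_runs, function(f) f$best$cv_mse, numeric(1))
    best_fit <- k_runs[[which.min(fits)]]
    chr <- best_fit$best$chromosome
    if (!is.null(split)) {
      rep_eval <- evaluate_final_model(table, split, chr,
                                       n_folds = config$n_folds,
                                       seed = config$seed)
      train_r2 <- rep_eval$train_r2; test_r2 <- rep_eval$test_r2
    } else {
      train_r2 <- NA_real_; test_r2 <- NA_real_
    }
    summary_rows[[ki]] <- data.frame(
      k = k, cv_mse = best_fit$best$cv_mse,
      cv_r2 = r_squared(best_fit$cv_predictions, best_fit$y),
      train_r2 = train_r2, test_r2 = test_r2,
      C = chr$C, gamma = chr$gamma, epsilon = chr$epsilon)
    runs[[as.character(k)]] <- k_runs
    best[[as.character(k)]] <- best_fit
  }
  structure(list(runs = runs, best = best,
                 summary = do.call(rbind, summary_rows),
                 n_runs = n_runs, split = split),
            class = "ga_svr_replicates")
}

#' @export
print.ga_svr_replicates <- function(x, ...) {
  cat("GA/SVR replicate sweep: ", x$n_runs, " runs per k\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
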