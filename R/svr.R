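#' SVR hyperparameter set
#'
#' Bundle of the three hyperparameters of epsilon-insensitive support
#' vector regression with an RBF kernel: the regularization weight `C`
#' (trade-off between flatness and training error), the kernel width
#' `gamma`, and the half-width `epsilon` of the insensitive zone
#' (residuals smaller than `epsilon` incur no loss; larger values select
#' fewer support vectors and flatter fits).
#'
#' @param C regularization weight, > 0.
#' @param gamma RBF kernel width, > 0.
#' @param epsilon insensitive-zone half-width, >= 0.
#' @return An object of class `"svm_params"`.
#' @export
svm_params <- function(C, gamma, epsilon) {
  if (!(is.numeric(C) && length(C) == 1 && C > 0))
    stop_validation("C must be a single value > 0")
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma > 0))
    stop_validation("gamma must be a single value > 0")
  if (!(is.numeric(epsilon) && length(epsilon) == 1 && epsilon >= 0))
    stop_validation("epsilon must be a single value >= 0")
  structure(list(C = C, gamma = gamma, epsilon = epsilon),
            class = "svm_params")
}

#' @export
print.svm_params <- function(x, ...) {
  cat(sprintf("SVR parameters: C = %.6g, gamma = %.6g, epsilon = %.6g\n",
              x$C, x$gamma, x$epsilon))
  invisible(x)
}

#' RBF kernel
#'
#' Gaussian radial-basis similarity `exp(-gamma * ||a - b||^2)`, the
#' kernel used throughout the package. Values lie in (0, 1], with 1 iff
#' `a == b`.
#'
#' @param a,b numeric vectors of equal length.
#' @param gamma kernel width, > 0.
#' @return A similarity scalar.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(a, b, gamma) {
  if (length(a) != length(b)) stop_validation("vectors differ in length")
  if (!(gamma > 0)) stop_validation("gamma must be > 0")
  exp(-gamma * sum((a - b)^2))
}

# RBF Gram block between row sets (scaled space), vectorized.
rbf_kernel_matrix <- function(A, B, gamma) {
  exp(-gamma * pairwise_sqdist(A, B))
}

#' Mean squared error
#'
#' `mean((predicted - observed)^2)` — the quantity minimized by the
#' genetic algorithm when pooled over cross-validation folds.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Non-negative scalar in squared target units.
#' @export
mse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_validation("vectors differ in length")
  if (length(predicted) < 1) stop_validation("need at least one value")
  mean((predicted - observed)^2)
}

#' Squared correlation between predictions and observations
#'
#' The r-squared convention of QSAR reporting: the squared Pearson
#' correlation between predicted and observed responses, in \[0, 1\]. Note
#' this is sign-blind (perfectly anti-correlated predictions also score 1)
#' and is not penalized for bias; set `method = "cod"` for the
#' coefficient of determination `1 - SS_res/SS_tot` instead.
#'
#' @param predicted,observed numeric vectors, length >= 2; `observed`
#'   must not be constant.
#' @param method `"pearson"` (default) or `"cod"`.
#' @return A scalar; in \[0, 1\] for `"pearson"`.
#' @export
r_squared <- function(predicted, observed, method = c("pearson", "cod")) {
  method <- match.arg(method)
  if (length(predicted) != length(observed))
    stop_validation("vectors differ in length")
  if (length(observed) < 2) stop_validation("need at least two values")
  if (stats::sd(observed) == 0)
    stop_validation("observed vector is constant; r-squared undefined")
  if (method == "pearson") {
    if (stats::sd(predicted) == 0) return(0)
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Train an RBF support vector regression model
#'
#' Fits epsilon-insensitive SVR with an RBF kernel via the libsvm solver
#' ([e1071::svm()]). Features are z-scored on the training data (the
#' scaler is stored and re-applied at prediction time); the response is
#' left on its original scale. The returned object stores the support
#' vectors, the dual-coefficient differences (alpha_i - alpha_i*), the
#' bias, and the kernel width, so predictions are reproducible from the
#' kernel expansion alone:
#' \deqn{f(x) = \sum_i (\alpha_i - \alpha_i^*) K(x_i, x) + b.}
#'
#' @param X numeric training matrix (rows = samples).
#' @param y numeric response.
#' @param params an [svm_params()] object.
#' @param scale z-score features on the training data (default `TRUE`).
#' @param tolerance libsvm termination tolerance (default 0.001, the
#'   solver default).
#' @return An object of class `"svr_model"` with elements
#'   `support_vectors` (scaled space), `dual_coef`, `bias`, `params`,
#'   `scaler`, `tolerance`, `n_sv`, and `libsvm_fit` (the underlying
#'   [e1071::svm()] object, kept so the expansion can be checked against
#'   the solver's own predictions).
#' @export
train_svr <- function(X, y, params, scale = TRUE, tolerance = 0.001) {
  stopifnot(inherits(params, "svm_params"))
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_validation("need at least 2 training samples")
  scaler <- if (scale) fit_scaler(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- apply_scaler(X, scaler)
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = params$C, gamma = params$gamma,
                    epsilon = params$epsilon, scale = FALSE,
                    fitted = FALSE, tolerance = tolerance)
  structure(list(support_vectors = fit$SV,
                 dual_coef = as.numeric(fit$coefs),
                 bias = -fit$rho,
                 params = params,
                 scaler = scaler,
                 tolerance = tolerance,
                 n_sv = nrow(fit$SV),
                 libsvm_fit = fit),
            class = "svr_model")
}

#' Predict from a trained SVR model
#'
#' Evaluates the stored kernel expansion
#' `sum_i (alpha_i - alpha_i*) K(x_i, x) + b` directly from the model's
#' support vectors, dual coefficients and bias — the model's defining
#' contract, independent of the solver's own predict path (the two agree
#' to solver precision; see the package tests).
#'
#' @param object an `"svr_model"`.
#' @param newdata numeric matrix with the same columns the model was
#'   trained on.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- apply_scaler(newdata, object$scaler)
  K <- rbf_kernel_matrix(Xs, object$support_vectors, object$params$gamma)
  as.numeric(K %*% object$dual_coef + object$bias)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("RBF-SVR model: %d support vectors, C = %.4g, gamma = %.4g, epsilon = %.4g\n",
              x$n_sv, x$params$C, x$params$gamma, x$params$epsilon))
  invisible(x)
}

#' Cross-validation fold assignment keyed to sample identifiers
#'
#' Sample ids are put in canonical (sorted) order, shuffled with the
#' seeded RNG, and cut into `n_folds` contiguous blocks. Because the
#' assignment depends on the ids rather than on row positions, reordering
#' the rows of a table leaves every sample in the same fold.
#'
#' @param sample_ids character vector of unique ids.
#' @param n_folds number of folds, >= 2.
#' @param seed integer seed.
#' @return Integer vector of fold labels (1..n_folds), parallel to
#'   `sample_ids`.
#' @export
cv_folds <- function(sample_ids, n_folds, seed) {
  n <- length(sample_ids)
  if (n_folds < 2) stop_config("n_folds must be >= 2")
  if (n < n_folds) stop_config("need at least n_folds samples")
  canonical <- sort(sample_ids)
  perm <- local_seed(seed, sample.int(n))
  shuffled <- canonical[perm]
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- rep(seq_len(n_folds), times = sizes)
  labels[match(sample_ids, shuffled)]
}

# Pooled k-fold CV predictions for a feature subset + parameter set.
# Scaling is fit on each fold's training portion only. Returns the
# prediction vector aligned with the table's rows.
cv_predictions <- function(table, feature_indices, params, n_folds = 10,
                           seed = 1, folds = NULL, trainer = train_svr,
                           tolerance = 0.001) {
  stopifnot(inherits(table, "feature_table"))
  N <- ncol(table$X)
  if (any(feature_indices < 1 | feature_indices > N))
    stop_validation("feature index out of range [1, ", N, "]")
  if (is.null(folds)) folds <- cv_folds(table$sample_ids, n_folds, seed)
  Xf <- table$X[, feature_indices, drop = FALSE]
  pred <- numeric(nrow(Xf))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    # rows fed to the solver in canonical id order, so the fit (and hence
    # the pooled CV error) is exactly invariant to table row order
    tr <- which(!hold)[order(table$sample_ids[!hold])]
    model <- trainer(Xf[tr, , drop = FALSE], table$y[tr], params,
                     tolerance = tolerance)
    pred[hold] <- predict(model, Xf[hold, , drop = FALSE])
  }
  pred
}

#' Cross-validated mean squared error (the GA fitness)
#'
#' Partitions the samples into seeded folds ([cv_folds()]), trains an SVR
#' on each fold's complement (feature scaling fit on the training portion
#' only, so no information leaks from the held-out fold), predicts the
#' held-out fold, and pools all n held-out predictions into a single mean
#' squared error. Lower is better; this is the fitness the genetic
#' algorithm minimizes.
#'
#' @inheritParams cv_folds
#' @param table a [feature_table()].
#' @param feature_indices integer column indices of the features to use.
#' @param params an [svm_params()] object.
#' @param folds optional precomputed fold labels (fixes the partition
#'   across many calls, as within one GA run).
#' @param trainer training function with the signature of [train_svr()];
#'   injectable for testing.
#' @param tolerance solver tolerance passed to the trainer.
#' @return The pooled CV mean squared error (scalar).
#' @export
cv_mse <- function(table, feature_indices, params, n_folds = 10, seed = 1,
                   folds = NULL, trainer = train_svr, tolerance = 0.001) {
  pred <- cv_predictions(table, feature_indices, params, n_folds = n_folds,
                         seed = seed, folds = folds, trainer = trainer,
                         tolerance = tolerance)
  mse(pred, table$y)
}

#' Default hyperparameter grid for the baseline search
#'
#' Conventional log2-spaced axes: `C` over 2^-5..2^15, `gamma` over
#' 2^-15..2^3, `epsilon` over 2^-8..2^-1.
#'
#' @param c_exp,gamma_exp,epsilon_exp exponent sequences (base 2).
#' @return Named list of axes for [grid_search()].
#' @export
default_grid <- function(c_exp = seq(-5, 15, by = 2),
                         gamma_exp = seq(-15, 3, by = 2),
                         epsilon_exp = seq(-8, -1, by = 1)) {
  list(C = 2^c_exp, gamma = 2^gamma_exp, epsilon = 2^epsilon_exp)
}

#' Exhaustive grid search baseline
#'
#' The conventional alternative to the genetic algorithm: evaluate
#' [cv_mse()] at every point of a discretized (C, gamma, epsilon) grid on
#' a fixed feature set and return the argmin (ties resolved in favor of
#' the first point in iteration order, C varying fastest).
#'
#' @inheritParams cv_mse
#' @param grid named list with non-empty numeric axes `C`, `gamma`,
#'   `epsilon` (see [default_grid()]).
#' @return List of class `"svr_grid"`: `params` (best [svm_params()]),
#'   `cv_mse`, and `evaluations` (data frame of every grid point and its
#'   CV MSE).
#' @export
grid_search <- function(table, feature_indices, grid = default_grid(),
                        n_folds = 10, seed = 1, tolerance = 0.001) {
  for (ax in c("C", "gamma", "epsilon"))
    if (is.null(grid[[ax]]) || length(grid[[ax]]) == 0)
      stop_config("grid axis '", ax, "' is empty")
  pts <- expand.grid(C = grid$C, gamma = grid$gamma, epsilon = grid$epsilon,
                     KEEP.OUT.ATTRS = FALSE)
  folds <- cv_folds(table$sample_ids, n_folds, seed)
  scores <- vapply(seq_len(nrow(pts)), function(i) {
    cv_mse(table, feature_indices,
           svm_params(pts$C[i], pts$gamma[i], pts$epsilon[i]),
           folds = folds, tolerance = tolerance)
  }, numeric(1))
  best <- which.min(scores)  # first minimum on ties
  structure(list(params = svm_params(pts$C[best], pts$gamma[best],
                                     pts$epsilon[best]),
                 cv_mse = scores[best],
                 evaluations = cbind(pts, cv_mse = scores)),
            class = "svr_grid")
}

#' @export
print.svr_grid <- function(x, ...) {
  cat(sprintf("Grid search over %d points: best CV MSE %.6g at C = %.4g, gamma = %.4g, epsilon = %.4g\n",
              nrow(x$evaluations), x$cv_mse, x$params$C, x$params$gamma,
              x$params$epsilon))
  invisible(x)
}
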