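# RBF kernel, SVR training contract, CV fitness, grid search.

test_that("rbf_kernel evaluates the Gaussian similarity", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 3.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1))
  expect_equal(rbf_kernel(0, 1, gamma = 1), 0.367879, tolerance = 1e-5)
  expect_lt(rbf_kernel(0, 1, gamma = 1e6), 1e-12)
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), gamma = 1),
               class = "gasvr_validation_error")
})

test_that("mse and r_squared match hand arithmetic", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 2), c(1, 1)), 1)
  v <- rnorm(10); w <- rnorm(10)
  expect_equal(mse(3 * v, 3 * w), 9 * mse(v, w))
  expect_equal(r_squared(v, v), 1)
  expect_equal(r_squared(-v, v), 1)  # squared correlation is sign-blind
  expect_equal(r_squared(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_error(r_squared(v, rep(1, 10)), class = "gasvr_validation_error")
  # coefficient-of-determination alternative penalizes bias
  expect_lt(r_squared(v + 10, v, method = "cod"), 0)
  expect_equal(r_squared(v, v, method = "cod"), 1)
})

test_that("trained SVR satisfies the kernel-expansion prediction contract", {
  set.seed(3)
  X <- matrix(seq(-2, 2.5, length.out = 10), ncol = 1)
  y <- 0.8 * X[, 1] + 0.1 * sin(X[, 1])
  p <- svm_params(C = 100, gamma = 0.7, epsilon = 0.01)
  m <- train_svr(X, y, p)
  expect_equal(length(m$dual_coef), m$n_sv)
  expect_true(all(abs(m$dual_coef) <= p$C + 1e-9))
  grid <- matrix(seq(-2.5, 3, length.out = 25), ncol = 1)
  # package expansion vs the solver's own predict path
  Xs <- sweep(sweep(grid, 2, m$scaler$center, "-"), 2, m$scaler$scale, "/")
  expect_equal(predict(m, grid), as.numeric(predict(m$libsvm_fit, Xs)),
               tolerance = 1e-6)
  # hand-computed expansion from stored pieces on one point
  x0 <- (grid[7, ] - m$scaler$center) / m$scaler$scale
  k <- apply(m$support_vectors, 1, function(sv) rbf_kernel(sv, x0, p$gamma))
  expect_equal(sum(k * m$dual_coef) + m$bias, predict(m, grid[7, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("independent solver (kernlab) reproduces the fit on a 10-point fixture", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  X <- matrix(seq(-2, 2.5, length.out = 10), ncol = 1)
  y <- 0.8 * X[, 1] + 0.1 * sin(X[, 1])
  p <- svm_params(C = 50, gamma = 0.7, epsilon = 0.01)
  m <- train_svr(X, y, p, tolerance = 1e-8)
  grid <- matrix(seq(-2.5, 3, length.out = 25), ncol = 1)
  Xs_tr <- sweep(sweep(X, 2, m$scaler$center, "-"), 2, m$scaler$scale, "/")
  Xs <- sweep(sweep(grid, 2, m$scaler$center, "-"), 2, m$scaler$scale, "/")
  kfit <- kernlab::ksvm(Xs_tr, y, type = "eps-svr", kernel = "rbfdot",
                        kpar = list(sigma = p$gamma), C = p$C,
                        epsilon = p$epsilon, scaled = FALSE, tol = 1e-8)
  expect_equal(predict(m, grid), as.numeric(kernlab::predict(kfit, Xs)),
               tolerance = 1e-6)
  # large C, tiny epsilon: the fixture is interpolated to within epsilon
  expect_true(all(abs(predict(m, X) - y) <= p$epsilon + 1e-6))
})

test_that("constant targets yield (near-)constant models without crashing", {
  X <- matrix(rnorm(20), 10, 2)
  m <- train_svr(X, rep(2.5, 10), svm_params(10, 0.5, 0.1))
  expect_true(all(abs(predict(m, X) - 2.5) <= 0.1 + 1e-8))
  # degenerate all-identical rows must not crash
  Xd <- matrix(1, 5, 2)
  md <- train_svr(Xd, c(1, 2, 3, 2, 1), svm_params(1, 0.5, 0.1))
  expect_length(predict(md, Xd), 5)
})

test_that("larger epsilon never recruits more support vectors", {
  set.seed(9)
  X <- matrix(rnorm(80), 40, 2)
  y <- X[, 1] - X[, 2] + rnorm(40, 0, 0.3)
  n_sv <- sapply(c(0.01, 0.1, 0.3, 0.6, 1),
                 function(e) train_svr(X, y, svm_params(10, 0.5, e))$n_sv)
  expect_true(all(diff(n_sv) <= 0))
})

test_that("fold assignment is keyed to ids, not row order", {
  ids <- sprintf("s%02d", 1:20)
  f1 <- cv_folds(ids, 4, seed = 5)
  expect_equal(sort(unique(f1)), 1:4)
  expect_equal(as.vector(table(f1)), rep(5L, 4))
  perm <- sample(20)
  f2 <- cv_folds(ids[perm], 4, seed = 5)
  expect_identical(f2, f1[perm])  # same id -> same fold
  expect_identical(cv_folds(ids, 4, seed = 5), f1)  # deterministic
  expect_false(identical(cv_folds(ids, 4, seed = 6), f1))
})

test_that("cv_mse pools held-out errors exactly as hand bookkeeping says", {
  ft <- make_table(matrix(rnorm(8), 4, 2), y = c(1, 3, 5, 7),
                   ids = c("a", "b", "c", "d"))
  folds <- cv_folds(ft$sample_ids, 2, seed = 2)
  got <- cv_mse(ft, 1:2, svm_params(1, 1, 0.1), folds = folds,
                trainer = mock_mean_trainer)
  # hand pooling: each sample predicted by the mean of the opposite fold
  pred <- numeric(4)
  for (f in 1:2) pred[folds == f] <- mean(ft$y[folds != f])
  expect_equal(got, mean((pred - ft$y)^2), tolerance = 1e-12)
  # determinism under a fixed seed
  expect_identical(cv_mse(ft, 1:2, svm_params(1, 1, 0.1), n_folds = 2, seed = 9,
                          trainer = mock_mean_trainer),
                   cv_mse(ft, 1:2, svm_params(1, 1, 0.1), n_folds = 2, seed = 9,
                          trainer = mock_mean_trainer))
  expect_error(cv_mse(ft, c(1, 5), svm_params(1, 1, 0.1), n_folds = 2),
               class = "gasvr_validation_error")
})

test_that("cv_mse is invariant to sample order and near zero on noiseless fits", {
  set.seed(21)
  X <- matrix(rnorm(120), 60, 2)
  y <- X[, 1] * 0.9
  ft <- make_table(X, y)
  p <- svm_params(100, 0.5, 0.001)
  v1 <- cv_mse(ft, 1:2, p, n_folds = 5, seed = 3)
  perm <- sample(60)
  ftp <- make_table(X[perm, ], y[perm], ids = ft$sample_ids[perm])
  expect_equal(cv_mse(ftp, 1:2, p, n_folds = 5, seed = 3), v1, tolerance = 1e-10)
  # a target reproducible by the model family gives near-zero CV error
  expect_lt(cv_mse(ft, 1, p, n_folds = 5, seed = 3), 0.01)
})

test_that("grid search returns the pointwise argmin", {
  set.seed(4)
  X <- matrix(rnorm(100), 50, 2)
  y <- X[, 1] + rnorm(50, 0, 0.1)
  ft <- make_table(X, y)
  # two-point grid with one deliberately terrible C
  g <- list(C = c(1e-4, 10), gamma = 0.5, epsilon = 0.1)
  res <- grid_search(ft, 1:2, grid = g, n_folds = 5, seed = 1)
  expect_equal(res$params$C, 10)
  folds <- cv_folds(ft$sample_ids, 5, seed = 1)
  direct <- sapply(c(1e-4, 10), function(C)
    cv_mse(ft, 1:2, svm_params(C, 0.5, 0.1), folds = folds))
  expect_equal(res$cv_mse, min(direct), tolerance = 1e-12)
  expect_true(all(res$cv_mse <= res$evaluations$cv_mse))
  # single-point grid returns that point
  res1 <- grid_search(ft, 1:2, grid = list(C = 2, gamma = 0.3, epsilon = 0.2),
                      n_folds = 5, seed = 1)
  expect_equal(unclass(res1$params)[c("C", "gamma", "epsilon")],
               list(C = 2, gamma = 0.3, epsilon = 0.2))
  # duplicated grid points change nothing
  resd <- grid_search(ft, 1:2, grid = list(C = c(10, 10), gamma = 0.5,
                                           epsilon = 0.1),
                      n_folds = 5, seed = 1)
  expect_equal(resd$cv_mse, res$cv_mse)
  expect_error(grid_search(ft, 1:2, grid = list(C = numeric(0), gamma = 1,
                                                epsilon = 0.1)),
               class = "gasvr_config_error")
})
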