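# Independent oracles and small fixture builders shared across tests.

# Quick feature-table builder.
make_table <- function(X, y, ids = NULL) {
  feature_table(as.matrix(X), y, sample_ids = ids)
}

# Brute-force Kennard-Stone oracle: naive stepwise maximin with explicit
# loops and its own standardization, independent of the package's
# distance code. Returns the selection order (row indices).
ks_oracle <- function(X, n_train, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) {
    for (j in seq_len(ncol(X))) {
      s <- sd(X[, j]); if (s == 0) s <- 1
      X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  n <- nrow(X)
  centroid <- colMeans(X)
  d_cent <- sapply(seq_len(n), function(i) sqrt(sum((X[i, ] - centroid)^2)))
  selected <- which.min(d_cent)
  while (length(selected) < n_train) {
    rest <- setdiff(seq_len(n), selected)
    min_d <- sapply(rest, function(i)
      min(sapply(selected, function(s) sqrt(sum((X[i, ] - X[s, ])^2)))))
    selected <- c(selected, rest[which.max(min_d)])
  }
  selected
}

# A mock trainer whose model predicts the training mean everywhere:
# lets fold bookkeeping be checked against hand arithmetic.
mock_mean_trainer <- function(X, y, params, tolerance = 0.001, ...) {
  structure(list(support_vectors = matrix(0, 1, ncol(as.matrix(X))),
                 dual_coef = 0, bias = mean(y), params = params,
                 scaler = list(center = rep(0, ncol(as.matrix(X))),
                               scale = rep(1, ncol(as.matrix(X))))),
            class = "svr_model")
}

# Deterministic cheap fitness for GA mechanics tests (no SVR involved):
# prefers small C and low feature indices.
cheap_fitness <- function(chr) chr$C + 0.01 * sum(chr$features)

# Independent re-statement of the chromosome invariants.
chromosome_valid_for_test <- function(chr, b, n_features, k) {
  length(chr$features) == k &&
    anyDuplicated(chr$features) == 0 &&
    all(chr$features >= 1 & chr$features <= n_features) &&
    chr$C >= b$C[1] && chr$C <= b$C[2] &&
    chr$gamma >= b$gamma[1] && chr$gamma <= b$gamma[2] &&
    chr$epsilon >= b$epsilon[1] && chr$epsilon <= b$epsilon[2]
}

# Build an evaluated random population without touching SVR.
cheap_population <- function(config, n_features) {
  lapply(seq_len(config$population_size), function(i) {
    chr <- random_chromosome(config, n_features)
    list(chromosome = chr, fitness = cheap_fitness(chr))
  })
}
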