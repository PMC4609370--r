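#' Bounds for the three float genes
#'
#' The allowed ranges for the C, gamma and epsilon genes. Defaults bracket
#' the hyperparameter values typically fitted on descriptor-table QSAR
#' problems (C of order 1-100, gamma below ~1 on z-scored features,
#' epsilon a fraction of the response spread) while leaving the genetic
#' algorithm room to explore.
#'
#' @param C,gamma,epsilon length-2 numeric vectors `c(min, max)`.
#' @return An object of class `"gene_bounds"`.
#' @export
gene_bounds <- function(C = c(0.01, 100), gamma = c(1e-4, 2),
                        epsilon = c(0.001, 1)) {
  for (nm in c("C", "gamma", "epsilon")) {
    b <- get(nm)
    if (length(b) != 2 || !(b[1] < b[2]))
      stop_config("bounds for ", nm, " must be c(min, max) with min < max")
  }
  if (C[1] <= 0 || gamma[1] <= 0) stop_config("C and gamma bounds must be > 0")
  if (epsilon[1] < 0) stop_config("epsilon lower bound must be >= 0")
  structure(list(C = C, gamma = gamma, epsilon = epsilon),
            class = "gene_bounds")
}

#' Genetic algorithm configuration
#'
#' All evolution parameters in one validated object. The defaults are the
#' run parameters used for descriptor-scale problems: population 100,
#' 1000 generations, crossover rate 0.8, per-gene mutation rate 0.1, 2
#' elites copied unchanged each generation, and 8 fresh random immigrants
#' injected each generation to maintain diversity; parents are picked by
#' best-of-3 tournament.
#'
#' @param k_features number of features each chromosome carries (fixed
#'   per run).
#' @param population_size individuals per generation.
#' @param generations number of generations to evolve.
#' @param cross_rate probability a selected parent pair is mated (else
#'   the fitter parent is cloned).
#' @param mutation_rate per-gene Bernoulli mutation probability (applied
#'   to each float gene and each feature slot).
#' @param elite_size number of best individuals copied unchanged.
#' @param n_immigrants fresh random individuals injected per generation.
#' @param tournament_size candidates per selection tournament.
#' @param bounds a [gene_bounds()] object.
#' @param n_folds cross-validation folds for the fitness.
#' @param seed integer seed controlling the whole run (initial
#'   population, operators, fold assignment).
#' @param fit_tolerance libsvm tolerance used for fitness evaluations
#'   during the search (default 0.01 — coarser than the solver default,
#'   which is reserved for final refits).
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(k_features, population_size = 100, generations = 1000,
                      cross_rate = 0.8, mutation_rate = 0.1, elite_size = 2,
                      n_immigrants = 8, tournament_size = 3,
                      bounds = gene_bounds(), n_folds = 10, seed = 1,
                      fit_tolerance = 0.01) {
  stopifnot(inherits(bounds, "gene_bounds"))
  if (missing(k_features) || k_features < 1)
    stop_config("k_features must be >= 1")
  if (elite_size + n_immigrants > population_size)
    stop_config("elite_size + n_immigrants must not exceed population_size")
  for (p in c(cross_rate, mutation_rate))
    if (p < 0 || p > 1) stop_config("rates must be probabilities in [0, 1]")
  if (tournament_size < 1) stop_config("tournament_size must be >= 1")
  if (generations < 0) stop_config("generations must be >= 0")
  structure(list(k_features = as.integer(k_features),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 cross_rate = cross_rate, mutation_rate = mutation_rate,
                 elite_size = as.integer(elite_size),
                 n_immigrants = as.integer(n_immigrants),
                 tournament_size = as.integer(tournament_size),
                 bounds = bounds, n_folds = as.integer(n_folds),
                 seed = seed, fit_tolerance = fit_tolerance),
            class = "ga_config")
}

#' Mixed-type chromosome
#'
#' One candidate solution: three bounded float genes (the SVR
#' hyperparameters C, gamma, epsilon) concatenated with a feature gene —
#' an ordered array of `k` distinct integer feature indices in
#' `[1, n_features]`.
#'
#' @param C,gamma,epsilon float gene values.
#' @param features integer vector of distinct feature indices.
#' @param bounds optional [gene_bounds()] to validate against.
#' @param n_features optional total feature count to validate against.
#' @return An object of class `"chromosome"`.
#' @export
chromosome <- function(C, gamma, epsilon, features, bounds = NULL,
                       n_features = NULL) {
  features <- as.integer(features)
  if (anyDuplicated(features))
    stop_validation("feature gene contains duplicate indices")
  if (any(features < 1)) stop_validation("feature indices must be >= 1")
  if (!is.null(n_features) && any(features > n_features))
    stop_validation("feature index exceeds n_features = ", n_features)
  if (!is.null(bounds)) {
    stopifnot(inherits(bounds, "gene_bounds"))
    ok <- C >= bounds$C[1] && C <= bounds$C[2] &&
      gamma >= bounds$gamma[1] && gamma <= bounds$gamma[2] &&
      epsilon >= bounds$epsilon[1] && epsilon <= bounds$epsilon[2]
    if (!ok) stop_validation("float gene outside its bounds")
  }
  structure(list(C = C, gamma = gamma, epsilon = epsilon,
                 features = features),
            class = "chromosome")
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("Chromosome: C = %.4g, gamma = %.4g, epsilon = %.4g | features: %s\n",
              x$C, x$gamma, x$epsilon, paste(x$features, collapse = ", ")))
  invisible(x)
}

as_svm_params <- function(chr) svm_params(chr$C, chr$gamma, chr$epsilon)

#' Draw a random chromosome
#'
#' Float genes uniform within their bounds; the feature gene is
#' `k_features` distinct indices drawn uniformly from `[1, n_features]`.
#' Used for the initial population and for immigrants. Draws come from
#' the ambient RNG stream (seed it with `set.seed()` for standalone
#' reproducibility; [ga_svr()] manages the stream itself).
#'
#' @param config a [ga_config()].
#' @param n_features total number of candidate features.
#' @return A [chromosome()].
#' @export
random_chromosome <- function(config, n_features) {
  if (config$k_features > n_features)
    stop_config("k_features exceeds the number of candidate features")
  b <- config$bounds
  chromosome(C = stats::runif(1, b$C[1], b$C[2]),
             gamma = stats::runif(1, b$gamma[1], b$gamma[2]),
             epsilon = stats::runif(1, b$epsilon[1], b$epsilon[2]),
             features = sample.int(n_features, config$k_features))
}

#' Tournament selection
#'
#' Draws `tournament_size` candidates uniformly with replacement and
#' returns the one with the smallest fitness (CV MSE); ties go to the
#' first-drawn candidate.
#'
#' @param population list of individuals, each a list with elements
#'   `chromosome` and `fitness`.
#' @param tournament_size candidates per tournament.
#' @param idx optional injected candidate indices (for testing); when
#'   `NULL` they are drawn from the ambient RNG.
#' @return The selected individual.
#' @export
tournament_select <- function(population, tournament_size = 3, idx = NULL) {
  n <- length(population)
  if (n == 0) stop_validation("population is empty")
  if (is.null(idx)) idx <- sample.int(n, tournament_size, replace = TRUE)
  fits <- vapply(population[idx], function(ind) ind$fitness, numeric(1))
  population[[idx[which.min(fits)]]]
}

#' Blend crossover for float genes
#'
#' Child gene `beta * p1 + (1 - beta) * p2` with `beta` uniform on
#' \[-0.25, 1.25\] — the extended interval lets children fall slightly
#' outside the parental segment, after which the result is clamped to the
#' gene's bounds. Vectorized over genes.
#'
#' @param p1,p2 parent gene values (within bounds).
#' @param lower,upper gene bounds (recycled).
#' @param beta optional injected draw(s); when `NULL`, drawn
#'   independently per gene from uniform(-0.25, 1.25).
#' @return Child gene value(s), always within bounds.
#' @export
blend_crossover_float <- function(p1, p2, lower, upper, beta = NULL) {
  if (is.null(beta)) beta <- stats::runif(length(p1), -0.25, 1.25)
  pmin(pmax(beta * p1 + (1 - beta) * p2, lower), upper)
}

#' Directional float-gene mutation
#'
#' Mutates a gene toward one of its bounds: downward to
#' `v - beta * (v - lower)` when `direction < 0.5`, upward to
#' `v + beta * (upper - v)` otherwise, with `beta` uniform on \[0, 1\].
#' The result never leaves the bounds. Vectorized over genes.
#'
#' @param v gene value(s) within bounds.
#' @param lower,upper gene bounds (recycled).
#' @param beta,direction optional injected uniform(0,1) draws.
#' @return Mutated gene value(s).
#' @export
mutate_float <- function(v, lower, upper, beta = NULL, direction = NULL) {
  if (is.null(beta)) beta <- stats::runif(length(v))
  if (is.null(direction)) direction <- stats::runif(length(v))
  ifelse(direction < 0.5, v - beta * (v - lower), v + beta * (upper - v))
}

#' Uniform crossover for the feature gene
#'
#' Position-wise coin flip between the parents' feature arrays. Because
#' both parents may carry the same index at different positions, the raw
#' child can contain duplicates; each duplicate slot is repaired by a
#' uniform draw from the parents' unused indices (keeping offspring close
#' to parental material), falling back to a uniform draw over all indices
#' not yet present.
#'
#' @param f1,f2 parent feature genes, equal length `k`, each distinct.
#' @param n_features total number of candidate features.
#' @param coin optional injected logical vector (`TRUE` takes from `f1`).
#' @return A valid child feature gene: `k` distinct indices in
#'   `[1, n_features]`.
#' @export
uniform_crossover_features <- function(f1, f2, n_features, coin = NULL) {
  k <- length(f1)
  if (length(f2) != k) stop_validation("parent feature genes differ in length")
  if (is.null(coin)) coin <- stats::runif(k) < 0.5
  child <- ifelse(coin, f1, f2)
  for (p in which(duplicated(child))) {
    pool <- setdiff(c(f1, f2), child)
    if (length(pool) == 0) pool <- setdiff(seq_len(n_features), child)
    child[p] <- pool[sample.int(length(pool), 1)]
  }
  as.integer(child)
}

#' Feature-gene mutation
#'
#' Each slot independently mutates with probability `mutation_rate`; a
#' mutated slot receives a uniform draw from `[1, n_features]` excluding
#' every index currently in the gene, so duplicates are impossible. When
#' `k == n_features` no legal replacement exists and the gene is returned
#' unchanged.
#'
#' @param features a valid feature gene.
#' @param n_features total number of candidate features.
#' @param mutation_rate per-slot mutation probability.
#' @param hits optional injected logical vector marking slots to mutate.
#' @return A valid (possibly mutated) feature gene.
#' @export
mutate_features <- function(features, n_features, mutation_rate, hits = NULL) {
  k <- length(features)
  if (is.null(hits)) hits <- stats::runif(k) < mutation_rate
  for (p in which(hits)) {
    pool <- setdiff(seq_len(n_features), features)
    if (length(pool) == 0) break  # k == n_features: nothing legal to do
    features[p] <- pool[sample.int(length(pool), 1)]
  }
  as.integer(features)
}

# Crossover + mutation of a parent pair under `config`; returns a
# chromosome (not yet evaluated). Uses the ambient RNG stream.
breed <- function(par1, par2, config, n_features) {
  b <- config$bounds
  if (stats::runif(1) < config$cross_rate) {
    child <- chromosome(
      C = blend_crossover_float(par1$chromosome$C, par2$chromosome$C,
                                b$C[1], b$C[2]),
      gamma = blend_crossover_float(par1$chromosome$gamma,
                                    par2$chromosome$gamma,
                                    b$gamma[1], b$gamma[2]),
      epsilon = blend_crossover_float(par1$chromosome$epsilon,
                                      par2$chromosome$epsilon,
                                      b$epsilon[1], b$epsilon[2]),
      features = uniform_crossover_features(par1$chromosome$features,
                                            par2$chromosome$features,
                                            n_features))
  } else {
    better <- if (par1$fitness <= par2$fitness) par1 else par2
    child <- better$chromosome
  }
  # per-gene Bernoulli mutation: each float gene, then the feature slots
  if (stats::runif(1) < config$mutation_rate)
    child$C <- mutate_float(child$C, b$C[1], b$C[2])
  if (stats::runif(1) < config$mutation_rate)
    child$gamma <- mutate_float(child$gamma, b$gamma[1], b$gamma[2])
  if (stats::runif(1) < config$mutation_rate)
    child$epsilon <- mutate_float(child$epsilon, b$epsilon[1], b$epsilon[2])
  child$features <- mutate_features(child$features, n_features,
                                    config$mutation_rate)
  child
}

#' Produce the next generation
#'
#' Assembles a full new population from the current one: the `elite_size`
#' best individuals are copied unchanged, `n_immigrants` fresh random
#' chromosomes are injected, and the remainder are offspring — each bred
#' from two tournament-selected parents, mated with probability
#' `cross_rate` (otherwise the fitter parent is cloned), then subjected
#' to per-gene mutation. Every new individual is evaluated with
#' `fitness_fn`.
#'
#' @param population list of evaluated individuals (`chromosome` +
#'   `fitness`), length `population_size`.
#' @param config a [ga_config()].
#' @param fitness_fn function `chromosome -> numeric` (smaller is
#'   better).
#' @param n_features total number of candidate features.
#' @return The new population (same length, all evaluated).
#' @export
next_generation <- function(population, config, fitness_fn, n_features) {
  if (length(population) != config$population_size)
    stop_validation("population size does not match config")
  fits <- vapply(population, function(ind) ind$fitness, numeric(1))
  elite <- population[order(fits)[seq_len(config$elite_size)]]
  immigrants <- lapply(seq_len(config$n_immigrants), function(i) {
    chr <- random_chromosome(config, n_features)
    list(chromosome = chr, fitness = fitness_fn(chr))
  })
  n_offspring <- config$population_size - config$elite_size -
    config$n_immigrants
  offspring <- lapply(seq_len(n_offspring), function(i) {
    par1 <- tournament_select(population, config$tournament_size)
    par2 <- tournament_select(population, config$tournament_size)
    chr <- breed(par1, par2, config, n_features)
    list(chromosome = chr, fitness = fitness_fn(chr))
  })
  c(elite, immigrants, offspring)
}
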