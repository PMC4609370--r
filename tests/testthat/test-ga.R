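# GA operators, generation assembly, chromosome closure.

test_that("blend crossover hits the endpoints, midpoint, and clamps", {
  expect_equal(blend_crossover_float(10, 20, 0, 100, beta = 1), 10)
  expect_equal(blend_crossover_float(10, 20, 0, 100, beta = 0), 20)
  expect_equal(blend_crossover_float(10, 20, 0, 100, beta = 0.5), 15)
  # beta beyond [0,1] may leave the parental segment; bounds clamp it
  expect_equal(blend_crossover_float(100, 50, 0, 100, beta = 1.25), 100)
  expect_equal(blend_crossover_float(0.01, 5, 0.01, 100, beta = 1.25), 0.01)
})

test_that("float mutation follows the directional formula and stays bounded", {
  expect_equal(mutate_float(5, 0, 10, beta = 0, direction = 0.1), 5)
  expect_equal(mutate_float(5, 0, 10, beta = 0, direction = 0.9), 5)
  expect_equal(mutate_float(5, 1, 10, beta = 1, direction = 0.2), 1)   # down -> v_min
  expect_equal(mutate_float(5, 1, 10, beta = 1, direction = 0.8), 10)  # up -> v_max
  expect_equal(mutate_float(4, 2, 10, beta = 0.5, direction = 0), 3)   # v - b(v-lo)
  expect_equal(mutate_float(4, 2, 10, beta = 0.5, direction = 0.7), 7) # v + b(hi-v)
})

test_that("operator outputs stay within gene bounds over random cases", {
  set.seed(101)
  n <- 1e5
  lo <- runif(n, -5, 0); hi <- lo + runif(n, 0.1, 10)
  p1 <- runif(n, lo, hi); p2 <- runif(n, lo, hi)
  child <- blend_crossover_float(p1, p2, lo, hi,
                                 beta = runif(n, -0.25, 1.25))
  expect_true(all(child >= lo & child <= hi))
  mut <- mutate_float(p1, lo, hi, beta = runif(n), direction = runif(n))
  expect_true(all(mut >= lo & mut <= hi))
})

test_that("uniform feature crossover honors forced draws and repairs duplicates", {
  f1 <- c(1L, 2L, 3L); f2 <- c(7L, 8L, 9L)
  expect_equal(uniform_crossover_features(f1, f1, 10), f1)
  expect_equal(uniform_crossover_features(f1, f2, 10,
                                          coin = c(TRUE, TRUE, TRUE)), f1)
  expect_equal(uniform_crossover_features(f1, f2, 10,
                                          coin = c(FALSE, FALSE, FALSE)), f2)
  # overlapping parents force repair; enumerate every outcome for validity
  set.seed(5)
  for (i in 1:200) {
    child <- uniform_crossover_features(c(1L, 2L), c(2L, 3L), 4)
    expect_length(child, 2)
    expect_false(anyDuplicated(child) > 0)
    expect_true(all(child %in% 1:4))
  }
  expect_error(uniform_crossover_features(c(1L, 2L), c(1L, 2L, 3L), 5),
               class = "gasvr_validation_error")
})

test_that("feature mutation avoids duplicates and respects forced cases", {
  expect_equal(mutate_features(c(4L, 9L), 10, mutation_rate = 0), c(4L, 9L))
  # k = 1, N = 2: the only legal replacement
  expect_equal(mutate_features(1L, 2, 1, hits = TRUE), 2L)
  # k = N: no legal replacement, gene unchanged
  expect_equal(mutate_features(c(1L, 2L, 3L), 3, 1, hits = rep(TRUE, 3)),
               c(1L, 2L, 3L))
  # forced single-position mutations always land outside the current gene
  set.seed(6)
  for (i in 1:300) {
    out <- mutate_features(c(1L, 2L), 5, 0, hits = c(TRUE, FALSE))
    expect_true(out[1] %in% 3:5)
    expect_equal(out[2], 2L)
  }
})

test_that("random chromosomes are valid and uniform over features", {
  cfg <- ga_config(k_features = 1, population_size = 10, generations = 1,
                   seed = 1)
  set.seed(8)
  draws <- replicate(10000, random_chromosome(cfg, 4)$features)
  counts <- tabulate(draws, 4)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) <= 3 * sigma))
  # determinism under a fixed seed
  set.seed(12); c1 <- random_chromosome(cfg, 50)
  set.seed(12); c2 <- random_chromosome(cfg, 50)
  expect_identical(c1, c2)
  # k = N forces the full feature set
  cfgN <- ga_config(k_features = 4, population_size = 10, generations = 1)
  set.seed(3)
  expect_setequal(random_chromosome(cfgN, 4)$features, 1:4)
  expect_error(random_chromosome(cfgN, 3), class = "gasvr_config_error")
})

test_that("tournament selection returns the fittest of the drawn candidates", {
  pop <- lapply(c(0.9, 0.1, 0.5), function(f)
    list(chromosome = chromosome(1, 1, 0.1, 1L), fitness = f))
  expect_equal(tournament_select(pop, 3, idx = c(1, 2, 3))$fitness, 0.1)
  expect_equal(tournament_select(pop[1], 3, idx = c(1, 1, 1))$fitness, 0.9)
  # ties go to the first drawn
  tied <- lapply(1:3, function(i)
    list(chromosome = chromosome(1, 1, 0.1, i), fitness = 0.4))
  expect_equal(tournament_select(tied, 3, idx = c(3, 1, 2))$chromosome$features, 3L)
  expect_error(tournament_select(list(), 3), class = "gasvr_validation_error")
})

test_that("next_generation assembles elites, immigrants and offspring", {
  cfg <- ga_config(k_features = 2, population_size = 12, generations = 1,
                   elite_size = 2, n_immigrants = 2, seed = 1)
  set.seed(31)
  pop <- cheap_population(cfg, 10)
  new_pop <- next_generation(pop, cfg, cheap_fitness, 10)
  expect_length(new_pop, 12)
  # the two best old fitnesses survive verbatim
  old_best <- sort(sapply(pop, `[[`, "fitness"))[1:2]
  new_fits <- sapply(new_pop, `[[`, "fitness")
  expect_true(all(old_best %in% new_fits))
  # identity evolution: full elitism, no immigrants, no variation
  cfg_id <- ga_config(k_features = 2, population_size = 8, generations = 1,
                      cross_rate = 0, mutation_rate = 0, elite_size = 8,
                      n_immigrants = 0)
  set.seed(32)
  pop8 <- cheap_population(cfg_id, 10)
  same <- next_generation(pop8, cfg_id, cheap_fitness, 10)
  expect_setequal(sapply(same, `[[`, "fitness"),
                  sapply(pop8, `[[`, "fitness"))
  expect_error(next_generation(pop8, cfg, cheap_fitness, 10),
               class = "gasvr_validation_error")
})

test_that("every chromosome produced by random operator chains is valid", {
  cfg <- ga_config(k_features = 4, population_size = 20, generations = 1,
                   seed = 1)
  b <- cfg$bounds
  set.seed(77)
  pop <- cheap_population(cfg, 15)
  for (g in 1:8) {
    pop <- next_generation(pop, cfg, cheap_fitness, 15)
    for (ind in pop)
      expect_true(chromosome_valid_for_test(ind$chromosome, b, 15, 4))
  }
})

test_that("all-immigrant populations are fresh independent draws", {
  cfg <- ga_config(k_features = 2, population_size = 40, generations = 1,
                   elite_size = 0, n_immigrants = 40)
  set.seed(55)
  pop <- cheap_population(cfg, 12)
  nxt <- next_generation(pop, cfg, cheap_fitness, 12)
  # no individual is carried over
  old_keys <- sapply(pop, function(i) paste(i$chromosome$C,
                                            paste(i$chromosome$features, collapse = ",")))
  new_keys <- sapply(nxt, function(i) paste(i$chromosome$C,
                                            paste(i$chromosome$features, collapse = ",")))
  expect_length(intersect(old_keys, new_keys), 0)
  # feature usage across several such generations stays uniform-ish
  feats <- integer(0)
  for (g in 1:5) {
    nxt <- next_generation(nxt, cfg, cheap_fitness, 12)
    feats <- c(feats, unlist(lapply(nxt, function(i) i$chromosome$features)))
  }
  counts <- tabulate(feats, 12)
  expected <- length(feats) / 12
  sigma <- sqrt(length(feats) * (1 / 12) * (11 / 12))
  expect_true(all(abs(counts - expected) <= 4 * sigma))
})
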