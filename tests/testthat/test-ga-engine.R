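test_that("configuration defaults match the documented search strategy", {
  cfg <- ga_config()
  expect_equal(cfg$population_size, 100L)
  expect_equal(cfg$crossover_rate, 0.8)
  expect_equal(cfg$mutation_rate, 0.01)
  expect_equal(cfg$alpha, 0.15)
  expect_equal(cfg$max_generations, 100L)
  expect_equal(cfg$stagnation_patience, 50L)
  expect_error(ga_config(crossover_rate = 1.2), "crossover")
  expect_error(ga_config(stagnation_patience = 200), "stagnation")
})

test_that("population initialization seeds the all-ones member", {
  cfg <- ga_config(population_size = 100, seed = 3)
  pop <- initialize_population(50, cfg)
  expect_equal(dim(pop), c(100, 50))
  expect_equal(pop[1, ], rep(1L, 50))
  expect_true(all(pop %in% 0:1))
  expect_true(all(rowSums(pop) >= 1))                 # repair rule
  dens <- mean(pop[-1, ])
  expect_lt(abs(dens - 0.5), 0.05)
  expect_identical(initialize_population(50, cfg), pop)
})

test_that("fitness is performance minus the size penalty", {
  expect_equal(ga_fitness(rep(1, 10), 0.90, alpha = 0.15), 0.75)
  expect_equal(ga_fitness(c(1, 0, 1), 0.64, alpha = 0), 0.64)
  one_of_100 <- c(1, rep(0, 99))
  expect_equal(ga_fitness(one_of_100, 0.80, alpha = 0.15), 0.7985)
  expect_equal(ga_fitness(rep(0, 5), 0.9), -Inf)
  # smaller mask wins at equal performance whenever alpha > 0
  expect_gt(ga_fitness(c(1, 0, 0, 0), 0.7, alpha = 0.15),
            ga_fitness(c(1, 1, 1, 0), 0.7, alpha = 0.15))
})

test_that("binary tournament selects a dominant member at the expected rate", {
  fitness <- c(0.9, 0.1, 0.1, 0.1, 0.1)
  withr::with_seed(8, {
    draws <- replicate(5000, tournament_select(fitness))
  })
  p_hat <- mean(draws == 1)
  p_theory <- 1 - (4 / 5)^2                           # 0.36
  expect_lt(abs(p_hat - p_theory), 0.02)
  # two members: the fitter wins unless both draws hit the weaker
  withr::with_seed(9, {
    two <- replicate(2000, tournament_select(c(0.2, 0.9)))
  })
  expect_equal(mean(two == 2), 0.75, tolerance = 0.03)
  withr::with_seed(10, a <- tournament_select(fitness))
  withr::with_seed(10, b <- tournament_select(fitness))
  expect_identical(a, b)
})

test_that("two-point crossover reproduces the printed worked example", {
  p1 <- c(0, 0, 1, 1, 0, 1, 1, 0, 1)
  p2 <- c(1, 1, 1, 0, 0, 0, 1, 1, 1)
  kids <- two_point_crossover(p1, p2, cuts = c(2, 7))
  expect_equal(kids[[1]], c(0, 0, 1, 0, 0, 0, 1, 0, 1))
  expect_equal(kids[[2]], c(1, 1, 1, 1, 0, 1, 1, 1, 1))
})

test_that("crossover conserves per-locus bits and fixes identical parents", {
  withr::with_seed(12, {
    for (i in 1:20) {
      n <- sample(4:30, 1)
      p1 <- rbinom(n, 1, 0.5); p2 <- rbinom(n, 1, 0.5)
      kids <- two_point_crossover(p1, p2, rate = 1)
      expect_equal(kids[[1]] + kids[[2]], p1 + p2)
    }
    same <- rbinom(15, 1, 0.5)
    kids <- two_point_crossover(same, same, rate = 1)
    expect_equal(kids[[1]], same)
    expect_equal(kids[[2]], same)
  })
})

test_that("mutation flips at the configured rate and repairs empties", {
  c0 <- rep(c(1, 0), 10)
  withr::with_seed(1, expect_equal(mutate_chromosome(c0, 0), c0))
  withr::with_seed(2, {
    flipped <- mutate_chromosome(c0, 1)
    expect_equal(flipped, 1L - c0)
  })
  withr::with_seed(3, {
    repaired <- mutate_chromosome(rep(1L, 4), 1)     # complement all-zero
    expect_equal(sum(repaired), 1)
  })
  withr::with_seed(4, {
    flips <- replicate(100, sum(mutate_chromosome(rep(0L, 1000), 0.01)))
  })
  # E = 10, sd ~ 3.1; repair adds at most 1
  expect_lt(abs(mean(flips) - 10), 5 * sqrt(1000 * 0.01 * 0.99) / 10)
})

test_that("the GA recovers a single perfectly predictive feature", {
  withr::with_seed(60, {
    y <- rep(c("neg", "pos"), 250)
    x <- matrix(rnorm(500 * 9), 500, 9)
    d <- tibble::tibble(signal = ifelse(y == "pos", 3, -3) + 0.1 * rnorm(500))
    d <- dplyr::bind_cols(d, tibble::as_tibble(as.data.frame(x)))
    d$class <- y
  })
  hits <- sapply(1:5, function(s) {
    ga <- run_ga(d, ga_config(population_size = 20, max_generations = 15,
                              stagnation_patience = 10, seed = s))
    1 %in% ga$selected
  })
  expect_true(all(hits))
})

test_that("a constant fitness trips the stagnation stop exactly on time", {
  sim <- make_informative_dataset(n_samples = 40, n_informative = 2,
                                  n_noise = 18, seed = 2)
  ga <- run_ga(
    sim$data,
    ga_config(population_size = 10, max_generations = 50,
              stagnation_patience = 12, alpha = 0, seed = 4),
    performance_fn = function(mask) 0.5
  )
  expect_equal(ga$stop_reason, "stagnation")
  expect_equal(max(ga$history$generation), 12)
  expect_equal(ga$history$stagnation[nrow(ga$history)], 12L)
  expect_equal(ga$best_fitness, 0.5)
})

test_that("results are bit-identical for any worker count", {
  sim <- make_informative_dataset(n_samples = 150, n_informative = 3,
                                  n_noise = 12, seed = 5)
  g1 <- run_ga(sim$data, ga_config(population_size = 16, max_generations = 10,
                                   stagnation_patience = 5, seed = 7,
                                   worker_count = 1))
  g4 <- run_ga(sim$data, ga_config(population_size = 16, max_generations = 10,
                                   stagnation_patience = 5, seed = 7,
                                   worker_count = 4))
  expect_identical(g1$best_chromosome, g4$best_chromosome)
  expect_identical(g1$history, g4$history)
  expect_identical(g1$selected, g4$selected)
})

test_that("elitism keeps the best fitness monotonically non-decreasing", {
  sim <- make_informative_dataset(n_samples = 120, n_informative = 2,
                                  n_noise = 10, seed = 6)
  for (sel in c("best_pair", "tournament")) {
    ga <- run_ga(sim$data, ga_config(population_size = 14, max_generations = 12,
                                     stagnation_patience = 6, seed = 8,
                                     selection = sel))
    expect_true(all(diff(ga$history$best_fitness) >= 0))
  }
})

test_that("candidate restriction and empty-mask handling behave", {
  sim <- make_informative_dataset(n_samples = 80, n_informative = 2,
                                  n_noise = 6, seed = 11)
  ga <- run_ga(sim$data, ga_config(population_size = 8, max_generations = 4,
                                   stagnation_patience = 3, seed = 1),
               candidates = c(2, 4, 6))
  expect_true(all(ga$selected %in% c(2, 4, 6)))
  expect_error(run_ga(sim$data, ga_config(), candidates = integer(0)),
               "non-empty")
  expect_error(run_ga(sim$data, ga_config(), candidates = 99), "range")
})

test_that("the wrapper beats univariate top-2 rankings on XOR interactions", {
  wins <- sapply(1:10, function(s) {
    xor <- make_xor_dataset(n_samples = 240, n_noise = 10, seed = 100 + s)
    sp <- split_train_test(xor$data, 0.3, seed = s)
    ga <- run_ga(sp$train, ga_config(population_size = 20, max_generations = 15,
                                     stagnation_patience = 10, seed = s),
                 classifier = "knn")
    g_ga <- evaluate_performance(sp$train, sp$test, "knn", "gmean",
                                 mask = ga$selected)
    # best univariate top-2: by MI and by |correlation|
    mis <- vapply(seq_len(12), function(j) {
      mutual_information(discretize_equal_frequency(sp$train[[j]], 10),
                         sp$train$class)
    }, numeric(1))
    top_mi <- order(-mis)[1:2]
    top_cor <- correlation_ranking(sp$train)$feature[1:2]
    g_uni <- max(
      evaluate_performance(sp$train, sp$test, "knn", "gmean", mask = top_mi),
      evaluate_performance(sp$train, sp$test, "knn", "gmean", mask = top_cor)
    )
    g_ga > g_uni
  })
  expect_gte(sum(wins), 8)
})
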