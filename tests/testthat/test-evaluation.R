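test_that("nested CV with the identity method reduces to plain k-fold CV", {
  sim <- make_informative_dataset(n_samples = 100, n_informative = 3,
                                  n_noise = 4, class_sep = 1.5, seed = 3)
  cv <- nested_cv(sim$data, method = "all_features", k_outer = 5, seed = 21)
  # manual plain 5-fold CV with the same folds and classifier
  folds <- stratified_kfold(sim$data, k = 5, seed = 21)$fold
  manual <- sapply(1:5, function(f) {
    model <- nbc_fit(sim$data[folds != f, ])
    pred <- nbc_predict(model, sim$data[folds == f, ])
    classification_metrics(sim$data$class[folds == f], pred)$gmean
  })
  expect_equal(cv$folds$gmean, manual)
  expect_equal(cv$folds$n_selected, rep(7L, 5))
  expect_true(is.na(cv$mean_stability))   # full-set subsets: undefined
})

test_that("outer-test samples are never exposed to feature selection", {
  sim <- make_informative_dataset(n_samples = 100, n_informative = 2,
                                  n_noise = 6, seed = 4)
  seen <- list()
  spy <- function(train_data, seed) {
    seen[[length(seen) + 1]] <<- attr(train_data, "row_indices")
    seq_len(ncol(train_data) - 1)
  }
  cv <- nested_cv(sim$data, method = spy, k_outer = 5, seed = 9)
  expect_length(seen, 5)
  for (f in 1:5) {
    expect_length(intersect(seen[[f]], cv$test_indices[[f]]), 0)
    expect_setequal(c(seen[[f]], cv$test_indices[[f]]), 1:100)
  }
})

test_that("a separable fixture scores a perfect mean GMean", {
  d <- make_separable_data(n = 100, n_features = 4, sep = 10, seed = 6)
  cv <- nested_cv(d, method = "correlation", k_outer = 5, seed = 2)
  expect_equal(unname(cv$aggregate$mean[cv$aggregate$metric == "gmean"]), 1.0)
})

test_that("nested CV is reproducible for a fixed seed", {
  sim <- make_informative_dataset(n_samples = 80, n_informative = 2,
                                  n_noise = 6, seed = 5)
  a <- nested_cv(sim$data, method = "mrmr", seed = 33)
  b <- nested_cv(sim$data, method = "mrmr", seed = 33)
  expect_identical(a$folds, b$folds)
  expect_identical(a$mean_stability, b$mean_stability)
})

test_that("hybrid selection restricts the wrapper to the filtered candidates", {
  sim <- make_informative_dataset(n_samples = 150, n_informative = 3,
                                  n_noise = 27, seed = 7)
  cfg <- ga_config(population_size = 12, max_generations = 6,
                   stagnation_patience = 4, seed = 13)
  sel <- hybrid_select(sim$data, criterion = "mrmr", fraction = 0.2,
                       config = cfg)
  ga <- attr(sel, "ga")
  expect_length(ga$candidates, 6)              # ceil(0.2 * 30)
  expect_true(all(sel %in% ga$candidates))

  # fraction 1.0 degenerates to the plain wrapper search space
  sim2 <- make_informative_dataset(n_samples = 80, n_informative = 2,
                                   n_noise = 6, seed = 8)
  cfg2 <- ga_config(population_size = 8, max_generations = 3,
                    stagnation_patience = 2, seed = 5)
  sel_full <- hybrid_select(sim2$data, fraction = 1.0, config = cfg2)
  expect_equal(attr(sel_full, "ga")$candidates, 1:8)
  plain <- run_ga(sim2$data, cfg2)
  expect_equal(as.integer(sel_full), sort(plain$selected))
})

test_that("informative features survive both hybrid phases", {
  recovered <- sapply(1:5, function(s) {
    sim <- make_informative_dataset(n_samples = 250, n_informative = 3,
                                    n_noise = 37, class_sep = 3,
                                    seed = 200 + s)
    cfg <- ga_config(population_size = 16, max_generations = 10,
                     stagnation_patience = 6, seed = s)
    sel <- hybrid_select(sim$data, criterion = "mrmr", fraction = 0.25,
                         config = cfg)
    mean(1:3 %in% sel)
  })
  expect_gte(sum(recovered >= 2 / 3), 4)
})

test_that("reduction percentage and performance-per-feature arithmetic", {
  expect_equal(reduction_percentage(1:10, 30), 100 / 3)
  expect_equal(round(reduction_percentage(1:10, 30), 2), 33.33)
  expect_equal(reduction_percentage(1:30, 30), 100)
  expect_equal(round(reduction_percentage(5, 81), 2), 1.23)
  expect_error(reduction_percentage(99, 30), "indices")

  expect_equal(performance_per_feature(0.90, 9), 0.10)
  expect_equal(performance_per_feature(0.75, 1), 0.75)
  expect_gt(performance_per_feature(0.8, 4), performance_per_feature(0.8, 8))
  expect_error(performance_per_feature(0.8, 0), "at least 1")
})

test_that("ranking points follow best-gets-1 with mean-rank ties", {
  grid <- tidyr::expand_grid(dataset = c("d1", "d2"),
                             metric = c("gmean", "f1"),
                             method = c("A", "B"))
  grid$value <- ifelse(grid$method == "A", 0.9, 0.5)
  rt <- rank_methods(grid)
  expect_equal(rt$summary$total_points[rt$summary$method == "A"], 4)
  expect_equal(rt$summary$total_points[rt$summary$method == "B"], 8)
  expect_equal(rt$summary$final_rank, c(1, 2))

  tied <- grid
  tied$value <- 0.7
  rt2 <- rank_methods(tied)
  expect_equal(unique(rt2$summary$total_points), 6)   # 4 cells x mean rank 1.5
  expect_equal(rt2$summary$final_rank, c(1, 1))

  # hand-built 3-method, 2-dataset, 2-metric grid
  g3 <- tidyr::expand_grid(dataset = c("x", "y"), metric = c("m1", "m2"),
                           method = c("A", "B", "C"))
  g3$value <- c(3, 2, 1,  1, 3, 2,  2, 1, 3,  3, 1, 2) / 10
  rt3 <- rank_methods(g3)
  manual <- c(A = 1 + 3 + 2 + 1, B = 2 + 1 + 3 + 3, C = 3 + 2 + 1 + 2)
  expect_equal(
    rt3$summary$total_points[match(names(manual), rt3$summary$method)],
    unname(manual)
  )

  # order invariance and completeness check
  shuffled <- g3[withr::with_seed(1, sample(nrow(g3))), ]
  expect_equal(rank_methods(shuffled)$summary, rt3$summary)
  expect_error(rank_methods(g3[-1, ]), "missing cell")
})
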