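# Nested cross-validation assessment harness, hybrid pipeline, and
# method-comparison utilities.

#' Feature-selection method constructors
#'
#' Each constructor returns a function `f(train_data, seed)` producing the
#' 1-based indices of the selected features, suitable for [nested_cv()]:
#' `fs_method_all()` keeps every feature, `fs_method_filter()` keeps the top
#' fraction of a greedy information-theoretic ranking,
#' `fs_method_correlation()` the top fraction of the class-correlation
#' baseline, `fs_method_ga()` runs the GA wrapper on all features, and
#' `fs_method_hybrid()` runs the filter-then-wrapper pipeline.
#'
#' @param criterion Filter criterion (see [rank_features()]).
#' @param fraction Retained fraction for filter-based methods (default 0.1).
#' @param n_bins Discretization bins (default 10).
#' @param config A [ga_config()]; its seed is overridden by the per-fold
#'   seed supplied by the caller.
#' @param classifier,metric,inner_k,knn_k,scale,positive Passed to
#'   [run_ga()] for wrapper-based methods.
#' @param label Name of the label column; default: last column.
#' @return A function `f(train_data, seed)` returning feature indices.
#' @name fs_methods
NULL

#' @rdname fs_methods
#' @export
fs_method_all <- function(label = NULL) {
  function(train_data, seed) {
    seq_len(fs_split(train_data, label)$n_features)
  }
}

#' @rdname fs_methods
#' @export
fs_method_filter <- function(criterion = "mrmr", fraction = 0.1, n_bins = 10,
                             label = NULL) {
  force(criterion); force(fraction); force(n_bins)
  function(train_data, seed) {
    n <- fs_split(train_data, label)$n_features
    k <- max(1L, as.integer(ceiling(fraction * n)))
    ranking <- rank_features(train_data, criterion = criterion,
                             n_select = k, n_bins = n_bins, label = label)
    sort(select_top_fraction(ranking, fraction, n))
  }
}

#' @rdname fs_methods
#' @export
fs_method_correlation <- function(fraction = 0.1, label = NULL) {
  force(fraction)
  function(train_data, seed) {
    ranking <- correlation_ranking(train_data, label = label)
    sort(select_top_fraction(ranking, fraction))
  }
}

#' @rdname fs_methods
#' @export
fs_method_ga <- function(config = ga_config(), classifier = "nbc",
                         metric = "gmean", inner_k = 5, knn_k = 5,
                         scale = TRUE, positive = NULL, label = NULL) {
  force(config)
  function(train_data, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    res <- run_ga(train_data, config = cfg, classifier = classifier,
                  metric = metric, label = label, inner_k = inner_k,
                  knn_k = knn_k, scale = scale, positive = positive)
    sort(res$selected)
  }
}

#' @rdname fs_methods
#' @export
fs_method_hybrid <- function(criterion = "mrmr", fraction = 0.1,
                             config = ga_config(), classifier = "nbc",
                             metric = "gmean", n_bins = 10, inner_k = 5,
                             knn_k = 5, scale = TRUE, positive = NULL,
                             label = NULL) {
  force(config)
  function(train_data, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    sort(hybrid_select(train_data, criterion = criterion, fraction = fraction,
                       config = cfg, classifier = classifier, metric = metric,
                       n_bins = n_bins, inner_k = inner_k, knn_k = knn_k,
                       scale = scale, positive = positive, label = label))
  }
}

resolve_method <- function(method, classifier, metric, inner_k, knn_k, scale,
                           positive, label) {
  if (is.function(method)) return(list(fn = method, name = "custom"))
  if (!is.character(method) || length(method) != 1) {
    abort("`method` must be a function or a method name.")
  }
  fn <- switch(method,
    all_features = fs_method_all(label),
    correlation = fs_method_correlation(label = label),
    ga = fs_method_ga(classifier = classifier, metric = metric,
                      inner_k = inner_k, knn_k = knn_k, scale = scale,
                      positive = positive, label = label),
    hybrid = fs_method_hybrid(classifier = classifier, metric = metric,
                              inner_k = inner_k, knn_k = knn_k, scale = scale,
                              positive = positive, label = label),
    mrmr = ,
    jmi = ,
    cmim = ,
    icap = fs_method_filter(criterion = method, label = label),
    abort(sprintf("Unknown method '%s'.", method))
  )
  list(fn = fn, name = method)
}

#' Nested k-fold cross-validation of a feature-selection method
#'
#' The outer folds estimate generalization of the whole select-then-classify
#' procedure: within each outer fold, feature selection sees only the outer
#' training portion (wrapper methods run their own inner cross-validation on
#' it); the classifier is then refit on the full outer-training set with the
#' selected mask and scored on the untouched outer test fold.  Selection
#' stability is computed across the outer folds' selected sets.
#'
#' @param data Data frame of features plus a label column.
#' @param method A method name (`"ga"`, `"hybrid"`, `"mrmr"`, `"jmi"`,
#'   `"cmim"`, `"icap"`, `"correlation"`, `"all_features"`) or a function
#'   `f(train_data, seed)` returning feature indices (see [fs_methods]).
#' @param k_outer,k_inner Outer and inner fold counts (default 5 and 5).
#' @param classifier,metric,knn_k,scale,positive As in
#'   [evaluate_performance()]; `metric` only steers wrapper methods — all
#'   seven metrics are always reported.
#' @param seed Integer seed; fold `f` passes `seed + f` to the method.
#' @param label Name of the label column; default: last column.
#' @return An object of class `fs_cv` with per-fold selections and metrics,
#'   aggregate mean/sd, mean reduction percentage and mean stability.
#' @export
nested_cv <- function(data, method = "ga", k_outer = 5, k_inner = 5,
                      classifier = "nbc", metric = "gmean", seed = 1,
                      knn_k = 5, scale = TRUE, positive = NULL, label = NULL) {
  d <- fs_split(data, label)
  m <- resolve_method(method, classifier, metric, k_inner, knn_k, scale,
                      positive, label)
  folds <- stratified_kfold(data, k = k_outer, seed = seed, label = label)$fold
  data_tb <- as_tibble(data)

  fold_rows <- vector("list", k_outer)
  test_indices <- vector("list", k_outer)
  selections <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    train <- data_tb[train_idx, , drop = FALSE]
    attr(train, "row_indices") <- train_idx
    selected <- sort(unique(as.integer(m$fn(train, seed + f))))
    if (length(selected) == 0) abort("Method selected no features.")
    pred_metrics <- fold_metrics(train, data_tb[test_idx, , drop = FALSE],
                                 selected, classifier, metric, knn_k, scale,
                                 positive, label)
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble(fold = f, n_selected = length(selected)),
      pred_metrics,
      tibble(reduction_pct = reduction_percentage(selected, d$n_features))
    )
    test_indices[[f]] <- test_idx
    selections[[f]] <- selected
  }
  folds_tb <- dplyr::bind_rows(fold_rows)
  folds_tb$selected <- selections

  stab <- tryCatch(mean_stability(selections, d$n_features),
                   error = function(e) NULL)
  metric_cols <- c("sensitivity", "specificity", "ppv", "gmean", "f1",
                   "accuracy", "mcc", "reduction_pct")
  aggregate <- tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols, function(mcol) mean(folds_tb[[mcol]]), numeric(1))),
    sd = unname(vapply(metric_cols, function(mcol) sd(folds_tb[[mcol]]), numeric(1)))
  )
  structure(
    list(
      folds = folds_tb,
      aggregate = aggregate,
      stability = stab,
      mean_stability = if (is.null(stab)) NA_real_ else stab$mean_stability,
      test_indices = test_indices,
      n_features = d$n_features,
      k_outer = k_outer, k_inner = k_inner,
      method = m$name, classifier = classifier, metric = metric,
      seed = seed
    ),
    class = "fs_cv"
  )
}

# Refit the requested classifier(s) on the outer-training set with the
# selected mask and score the outer test fold on all seven metrics.
fold_metrics <- function(train, test, selected, classifier, metric, knn_k,
                         scale, positive, label) {
  truth <- fs_split(test, label)$y
  pred_for <- function(clf) {
    if (clf == "nbc") {
      nbc_predict(nbc_fit(train, selected, label), test, label = label)
    } else {
      knn_predict(train, test, k = knn_k, mask = selected, scale = scale,
                  label = label)
    }
  }
  if (classifier == "both") {
    a <- classification_metrics(truth, pred_for("nbc"), positive)
    b <- classification_metrics(truth, pred_for("knn"), positive)
    as_tibble(as.list((unlist(a) + unlist(b)) / 2))
  } else {
    classification_metrics(truth, pred_for(classifier), positive)
  }
}

#' Hybrid filter-then-wrapper feature selection
#'
#' Phase 1 ranks all features with a greedy information-theoretic filter and
#' keeps the top `fraction`; phase 2 runs the GA wrapper restricted to the
#' retained candidates.  Returned indices refer to the original feature
#' space.
#'
#' @inheritParams nested_cv
#' @param criterion Filter criterion (default `"mrmr"`).
#' @param fraction Retained fraction after phase 1 (default 0.1).
#' @param config A [ga_config()] for phase 2.
#' @param n_bins Discretization bins (default 10).
#' @param inner_k Inner folds for the wrapper's Performance (default 5).
#' @return Integer vector of selected original feature indices, with the
#'   phase-1 `ranking` and the full `ga` result attached as attributes.
#' @export
hybrid_select <- function(data, criterion = "mrmr", fraction = 0.1,
                          config = ga_config(), classifier = "nbc",
                          metric = "gmean", n_bins = 10, inner_k = 5,
                          knn_k = 5, scale = TRUE, positive = NULL,
                          label = NULL) {
  d <- fs_split(data, label)
  keep <- max(1L, as.integer(ceiling(fraction * d$n_features)))
  ranking <- rank_features(data, criterion = criterion, n_select = keep,
                           n_bins = n_bins, label = label)
  candidates <- select_top_fraction(ranking, fraction, d$n_features)
  ga <- run_ga(data, config = config, classifier = classifier, metric = metric,
               candidates = candidates, label = label, inner_k = inner_k,
               knn_k = knn_k, scale = scale, positive = positive)
  structure(sort(ga$selected), ranking = ranking, ga = ga)
}

#' Reduction percentage of a selection
#'
#' `100 * |selected| / n`: the share of the original features retained.
#'
#' @param selected Integer vector of selected feature indices.
#' @param n Total feature count.
#' @return Percentage in `[0, 100]`.
#' @export
reduction_percentage <- function(selected, n) {
  selected <- unique(as.integer(selected))
  if (length(selected) > 0 && (any(selected < 1) || any(selected > n))) {
    abort(sprintf("Selected indices must lie in [1, %d].", n))
  }
  100 * length(selected) / n
}

#' Performance per selected feature
#'
#' The effectiveness ratio `metric_value / selected_count`: how much
#' performance each retained feature buys.
#'
#' @param metric_value Classification performance value.
#' @param selected_count Number of selected features (at least 1).
#' @return The ratio.
#' @export
performance_per_feature <- function(metric_value, selected_count) {
  if (selected_count < 1) abort("`selected_count` must be at least 1.")
  metric_value / selected_count
}

#' Ranking-points comparison of feature-selection methods
#'
#' Within each cell (every combination of the grid's identifier columns),
#' methods are sorted by descending metric value and assigned points 1 for
#' the best, 2 for the second best, and so on; tied values share the mean
#' of their ranks.  Points are summed across cells; the smallest sum wins
#' final rank 1.
#'
#' @param grid A data frame with a `method` column, a numeric `value`
#'   column, and one or more identifier columns (e.g. `dataset`, `metric`)
#'   defining the cells.  Every cell must contain every method exactly once.
#' @return A list of class `fs_rank_table`: `points` (the grid with a
#'   `points` column) and `summary` (per-method total points and
#'   `final_rank`).
#' @export
rank_methods <- function(grid) {
  grid <- as_tibble(grid)
  if (!all(c("method", "value") %in% names(grid))) {
    abort("`grid` must have `method` and `value` columns.")
  }
  id_cols <- setdiff(names(grid), c("method", "value"))
  methods <- sort(unique(grid$method))
  cells <- dplyr::distinct(grid[id_cols])
  if (length(id_cols) == 0) cells <- tibble(.rows = 1)
  check <- dplyr::count(grid, across(all_of(id_cols)), .data$method)
  if (any(check$n != 1) || nrow(check) != nrow(cells) * length(methods)) {
    full <- tidyr::expand_grid(cells, method = methods)
    missing <- dplyr::anti_join(full, grid, by = c(id_cols, "method"))
    if (nrow(missing) > 0) {
      abort(paste0("Incomplete grid; missing cell: ",
                   paste(unlist(missing[1, ]), collapse = " / ")))
    }
    abort("Each (cell, method) combination must appear exactly once.")
  }
  points <- grid %>%
    group_by(across(all_of(id_cols))) %>%
    mutate(points = rank(-.data$value, ties.method = "average")) %>%
    ungroup()
  summary <- points %>%
    group_by(.data$method) %>%
    summarise(total_points = sum(.data$points), .groups = "drop") %>%
    mutate(final_rank = rank(.data$total_points, ties.method = "min")) %>%
    arrange(.data$final_rank)
  structure(list(points = points, summary = summary), class = "fs_rank_table")
}

#' @export
print.fs_rank_table <- function(x, ...) {
  cat("Method comparison (1 point = best per cell; smallest sum wins):\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.fs_cv <- function(x, ...) {
  cat(sprintf(
    "Nested %d-fold cross-validation (method: %s, classifier: %s)\n",
    x$k_outer, x$method, x$classifier
  ))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-13s %6.3f +/- %.3f\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  }
  cat(sprintf("  mean stability %.3f\n", x$mean_stability))
  invisible(x)
}
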