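# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a GA run
#'
#' One row per generation: best fitness (monotone under elitism), mean
#' population fitness, size of the incumbent best mask and the stagnation
#' counter.
#'
#' @param x An `fs_ga` object from [run_ga()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.fs_ga <- function(x, ...) {
  x$history
}

#' One-row summary of a GA run
#'
#' @param x An `fs_ga` object.
#' @param ... Unused.
#' @return A one-row tibble with the best fitness/performance, selection
#'   size, generations run and stop reason.
#' @exportS3Method generics::glance
glance.fs_ga <- function(x, ...) {
  tibble(
    best_fitness = x$best_fitness,
    best_performance = x$best_performance,
    n_selected = length(x$selected),
    n_candidates = length(x$candidates),
    generations = max(x$history$generation),
    stop_reason = x$stop_reason
  )
}

#' Plot a GA fitness trajectory
#'
#' Best and mean fitness per generation; the flat tail visualizes the
#' steady-state stopping rule.
#'
#' @param object An `fs_ga` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fs_ga <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("best_fitness", "mean_fitness"),
                           names_to = "series", values_to = "fitness")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Fitness", colour = NULL,
                  title = "GA wrapper fitness trajectory")
}

#' Tidy a nested cross-validation result
#'
#' Per-outer-fold metrics and selection sizes.
#'
#' @param x An `fs_cv` object from [nested_cv()].
#' @param ... Unused.
#' @return A tibble, one row per outer fold (without the list column of
#'   selected indices; use `x$folds$selected` for those).
#' @exportS3Method generics::tidy
tidy.fs_cv <- function(x, ...) {
  dplyr::select(x$folds, -"selected")
}

#' One-row summary of a nested cross-validation result
#'
#' @param x An `fs_cv` object.
#' @param ... Unused.
#' @return A one-row tibble of metric means, mean stability and mean
#'   reduction percentage.
#' @exportS3Method generics::glance
glance.fs_cv <- function(x, ...) {
  agg <- x$aggregate
  wide <- as_tibble(as.list(stats::setNames(agg$mean, agg$metric)))
  dplyr::bind_cols(
    tibble(method = x$method, classifier = x$classifier, k_outer = x$k_outer),
    wide,
    tibble(mean_stability = x$mean_stability)
  )
}

#' Plot per-fold metrics of a nested cross-validation result
#'
#' @param object An `fs_cv` object.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fs_cv <- function(object, metrics = c("sensitivity", "specificity",
                                               "gmean", "f1", "accuracy"),
                           ...) {
  h <- tidyr::pivot_longer(dplyr::select(object$folds, -"selected"),
                           all_of(metrics),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::labs(x = NULL, y = "Outer-fold value", colour = "Fold",
                  title = sprintf("Nested %d-fold CV (%s)", object$k_outer,
                                  object$method))
}
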