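# Configuration-driven front end: flat key=value configs, artifact writing,
# and the mutation/crossover sweep driver.  A thin command-line script over
# these functions ships in inst/scripts/wrapfs.R.

#' Default run configuration
#'
#' All tool defaults in one flat list: GA parameters (population 100,
#' crossover 0.8, mutation 0.01, alpha 0.15, 100 generations, patience 50),
#' classifier/metric choices, the 0.1 filter retention fraction, 10
#' discretization bins, 5 outer and 5 inner folds.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "select",            # filter | select | evaluate | simulate
    input = NULL,
    output_dir = ".",
    delimiter = "\t",
    classifier = "nbc",         # nbc | knn | both
    metric = "gmean",           # gmean | accuracy | f1 | mcc
    method = "ga",              # evaluate mode: ga | hybrid | filter | correlation | all_features
    filter = "none",            # none | mrmr | jmi | cmim | icap | correlation
    fraction = 0.1,
    bins = 10,
    alpha = 0.15,
    population = 100,
    generations = 100,
    patience = 50,
    crossover = 0.8,
    mutation = 0.01,
    knn_k = 5,
    k_outer = 5,
    k_inner = 5,
    workers = 1,
    seed = 1
  )
}

#' Read a flat key=value (or simple key: value) configuration file
#'
#' Lines of the form `key = value` or `key: value`; blank lines and lines
#' starting with `#` are ignored.  Values are parsed as numbers where
#' possible.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) abort(sprintf("Cannot parse config line: '%s'.", ln))
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  if (!cfg$mode %in% c("filter", "select", "evaluate", "simulate")) {
    abort(sprintf("Unknown mode '%s'.", cfg$mode))
  }
  if (!cfg$classifier %in% c("nbc", "knn", "both")) {
    abort(sprintf("Unknown classifier '%s'.", cfg$classifier))
  }
  if (!cfg$metric %in% c("gmean", "accuracy", "f1", "mcc")) {
    abort(sprintf("Unknown metric '%s'.", cfg$metric))
  }
  if (!cfg$filter %in% c("none", "mrmr", "jmi", "cmim", "icap", "correlation")) {
    abort(sprintf("Unknown filter '%s'.", cfg$filter))
  }
  if (!cfg$method %in% c("ga", "hybrid", "filter", "correlation", "all_features")) {
    abort(sprintf("Unknown method '%s'.", cfg$method))
  }
  for (rate in c("fraction", "crossover", "mutation")) {
    if (cfg[[rate]] < 0 || cfg[[rate]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", rate))
    }
  }
  cfg
}

config_ga <- function(cfg) {
  ga_config(
    population_size = cfg$population, crossover_rate = cfg$crossover,
    mutation_rate = cfg$mutation, alpha = cfg$alpha,
    max_generations = cfg$generations, stagnation_patience = cfg$patience,
    seed = cfg$seed, worker_count = cfg$workers
  )
}

#' Write a selected-feature list as JSON and plain text
#'
#' The JSON carries 1-based indices, names and (where available) scores;
#' the text file lists one feature name per line.
#'
#' @param indices Integer feature indices, best first.
#' @param names Feature names parallel to `indices`.
#' @param json_path,txt_path Output paths (either may be `NULL` to skip).
#' @param scores Optional per-feature scores.
#' @return Invisibly, the written paths.
#' @export
write_selection <- function(indices, names, json_path = NULL, txt_path = NULL,
                            scores = NULL) {
  records <- lapply(seq_along(indices), function(i) {
    rec <- list(rank = i, index = indices[i], name = names[i])
    if (!is.null(scores)) rec$score <- scores[i]
    rec
  })
  if (!is.null(json_path)) {
    jsonlite::write_json(records, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(txt_path)) {
    writeLines(names, txt_path)
  }
  invisible(c(json_path, txt_path))
}

#' Execute a full run from a configuration
#'
#' Dispatches on `mode`: `"filter"` ranks features and writes the retained
#' selection; `"select"` runs the GA wrapper (optionally behind a filter
#' phase); `"evaluate"` wraps the configured method in nested
#' cross-validation and writes a per-fold metric table; `"simulate"` writes
#' a synthetic dataset with ground truth.  Artifacts (selection JSON and
#' text, metrics table, per-generation log) are written to `output_dir`.
#'
#' @param config A named list of configuration values (missing keys take
#'   their defaults from [default_config()]) or the path of a key=value
#'   config file.
#' @return Invisibly, a list with the computed `result` and the written
#'   `artifacts` paths.
#' @export
run_from_config <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(cfg$output_dir, name)
  artifacts <- character(0)
  log_lines <- character(0)

  if (cfg$mode == "simulate") {
    sim <- make_informative_dataset(seed = cfg$seed)
    write_feature_table(sim$data, art("synthetic.tsv"))
    write_ground_truth_json(sim$truth, art("synthetic_truth.json"))
    artifacts <- c(art("synthetic.tsv"), art("synthetic_truth.json"))
    return(invisible(list(result = sim, artifacts = artifacts)))
  }

  if (is.null(cfg$input)) abort("Config key `input` is required for this mode.")
  data <- read_feature_table(cfg$input, cfg$delimiter)
  d <- fs_split(data)

  if (cfg$mode == "filter") {
    criterion <- if (cfg$filter == "none") "mrmr" else cfg$filter
    keep <- max(1L, as.integer(ceiling(cfg$fraction * d$n_features)))
    ranking <- rank_features(data, criterion = criterion, n_select = keep,
                             n_bins = cfg$bins)
    idx <- select_top_fraction(ranking, cfg$fraction)
    write_selection(idx, d$feature_names[idx],
                    art("selection.json"), art("selection.txt"),
                    scores = ranking$score[seq_along(idx)])
    artifacts <- c(art("selection.json"), art("selection.txt"))
    result <- ranking
  } else if (cfg$mode == "select") {
    ga_cfg <- config_ga(cfg)
    if (cfg$filter == "none") {
      res <- run_ga(data, config = ga_cfg, classifier = cfg$classifier,
                    metric = cfg$metric, inner_k = cfg$k_inner,
                    knn_k = cfg$knn_k)
      selected <- sort(res$selected)
    } else {
      selected <- hybrid_select(data, criterion = cfg$filter,
                                fraction = cfg$fraction, config = ga_cfg,
                                classifier = cfg$classifier,
                                metric = cfg$metric, n_bins = cfg$bins,
                                inner_k = cfg$k_inner, knn_k = cfg$knn_k)
      res <- attr(selected, "ga")
      selected <- as.integer(selected)
    }
    h <- res$history
    log_lines <- sprintf(
      "generation=%d best_fitness=%.6f best_size=%d stagnation=%d",
      h$generation, h$best_fitness, h$best_size, h$stagnation
    )
    writeLines(log_lines, art("log.txt"))
    write_selection(selected, d$feature_names[selected],
                    art("selection.json"), art("selection.txt"))
    artifacts <- c(art("selection.json"), art("selection.txt"), art("log.txt"))
    result <- res
  } else { # evaluate
    criterion <- if (cfg$filter == "none") "mrmr" else cfg$filter
    method <- switch(cfg$method,
      ga = fs_method_ga(config = config_ga(cfg), classifier = cfg$classifier,
                        metric = cfg$metric, inner_k = cfg$k_inner,
                        knn_k = cfg$knn_k),
      hybrid = fs_method_hybrid(criterion = criterion, fraction = cfg$fraction,
                                config = config_ga(cfg),
                                classifier = cfg$classifier,
                                metric = cfg$metric, n_bins = cfg$bins,
                                inner_k = cfg$k_inner, knn_k = cfg$knn_k),
      filter = fs_method_filter(criterion = criterion,
                                fraction = cfg$fraction, n_bins = cfg$bins),
      correlation = fs_method_correlation(fraction = cfg$fraction),
      all_features = fs_method_all()
    )
    result <- nested_cv(data, method = method, k_outer = cfg$k_outer,
                        k_inner = cfg$k_inner, classifier = cfg$classifier,
                        metric = cfg$metric, seed = cfg$seed,
                        knn_k = cfg$knn_k)
    writeLines(format_cv_table(result), art("metrics.txt"))
    jsonlite::write_json(
      lapply(seq_len(cfg$k_outer), function(f) list(
        fold = f,
        selected = result$folds$selected[[f]],
        metrics = as.list(result$folds[f, c("sensitivity", "specificity",
                                            "ppv", "gmean", "f1",
                                            "accuracy", "mcc")])
      )),
      art("folds.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    artifacts <- c(art("metrics.txt"), art("folds.json"))
  }
  invisible(list(result = result, artifacts = artifacts))
}

# Mean +/- sd table in the layout of the published comparison tables.
format_cv_table <- function(cv) {
  agg <- cv$aggregate
  c(
    sprintf("%-14s %s", "metric", "mean +/- sd"),
    sprintf("%-14s %.4f +/- %.4f", agg$metric, agg$mean, agg$sd),
    sprintf("%-14s %.4f", "stability", cv$mean_stability)
  )
}

#' Sweep mutation and crossover rates
#'
#' Runs the full nested-cross-validated GA pipeline for every combination of
#' the supplied rates and reports GMean, stability and size reduction per
#' setting — the driver behind rate-sensitivity studies.
#'
#' @param config Base configuration (list or file path), as in
#'   [run_from_config()]; must include `input`.
#' @param mutation_rates,crossover_rates Non-empty numeric vectors of rates
#'   in `[0, 1]`.
#' @return A tibble with one row per rate combination: `mutation_rate`,
#'   `crossover_rate`, `gmean_mean`, `gmean_sd`, `stability`,
#'   `reduction_pct`.
#' @export
sweep_rates <- function(config, mutation_rates, crossover_rates) {
  if (length(mutation_rates) == 0 || length(crossover_rates) == 0) {
    abort("Rate lists must be non-empty.")
  }
  if (any(c(mutation_rates, crossover_rates) < 0) ||
      any(c(mutation_rates, crossover_rates) > 1)) {
    abort("All rates must lie in [0, 1].")
  }
  if (is.character(config)) config <- read_config(config)
  grid <- tidyr::expand_grid(mutation_rate = mutation_rates,
                             crossover_rate = crossover_rates)
  purrr::pmap_dfr(grid, function(mutation_rate, crossover_rate) {
    cfg <- modifyList(config, list(mode = "evaluate",
                                   mutation = mutation_rate,
                                   crossover = crossover_rate))
    res <- run_from_config(cfg)$result
    agg <- res$aggregate
    tibble(
      mutation_rate = mutation_rate,
      crossover_rate = crossover_rate,
      gmean_mean = agg$mean[agg$metric == "gmean"],
      gmean_sd = agg$sd[agg$metric == "gmean"],
      stability = res$mean_stability,
      reduction_pct = agg$mean[agg$metric == "reduction_pct"]
    )
  })
}
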