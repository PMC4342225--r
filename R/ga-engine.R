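# Single-population genetic-algorithm wrapper over binary feature masks.
#
# A chromosome is a 0/1 vector over the candidate features; its fitness is
# classifier performance minus a size penalty.  Selection is binary
# tournament, variation is two-point crossover plus bit-flip mutation,
# replacement is generational with single-member elitism, and the run stops
# at a generation cap or after a fixed number of stagnant generations.
# Fitness evaluation is a pure function of the chromosome, so a worker pool
# of any size produces bit-identical results for a fixed seed.

#' GA configuration
#'
#' Bundles the search-strategy parameters with their standard defaults:
#' population of 100, crossover rate 0.8, mutation rate 0.01, size-penalty
#' weight alpha = 0.15, at most 100 generations, and a steady-state stop
#' after 50 generations without any change in the best fitness.
#'
#' @param population_size Number of chromosomes per generation (default 100).
#' @param crossover_rate Per-pair probability of performing crossover
#'   (default 0.8).
#' @param mutation_rate Per-bit flip probability (default 0.01).
#' @param alpha Weight of the selected-fraction penalty in the fitness
#'   (default 0.15).
#' @param max_generations Generation cap (default 100).
#' @param stagnation_patience Consecutive generations without best-fitness
#'   change before stopping (default 50).
#' @param seed Integer master seed (default 1).
#' @param worker_count Size of the fitness-evaluation worker pool
#'   (default 1); results are independent of this value.
#' @param selection Parent-selection scheme: `"best_pair"` (default) mates
#'   the two fittest chromosomes of the current population for every
#'   offspring pair; `"tournament"` draws each parent as the winner of an
#'   independent binary tournament.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, crossover_rate = 0.8,
                      mutation_rate = 0.01, alpha = 0.15,
                      max_generations = 100, stagnation_patience = 50,
                      seed = 1, worker_count = 1,
                      selection = c("best_pair", "tournament")) {
  selection <- match.arg(selection)
  if (population_size < 2) abort("`population_size` must be at least 2.")
  if (crossover_rate < 0 || crossover_rate > 1) abort("`crossover_rate` must be in [0, 1].")
  if (mutation_rate < 0 || mutation_rate > 1) abort("`mutation_rate` must be in [0, 1].")
  if (alpha < 0) abort("`alpha` must be non-negative.")
  if (max_generations < 1) abort("`max_generations` must be at least 1.")
  if (stagnation_patience < 1 || stagnation_patience > max_generations) {
    abort("`stagnation_patience` must lie in [1, max_generations].")
  }
  if (worker_count < 1) abort("`worker_count` must be at least 1.")
  structure(
    list(
      population_size = as.integer(population_size),
      crossover_rate = crossover_rate,
      mutation_rate = mutation_rate,
      alpha = alpha,
      max_generations = as.integer(max_generations),
      stagnation_patience = as.integer(stagnation_patience),
      seed = as.integer(seed),
      worker_count = as.integer(worker_count),
      selection = selection
    ),
    class = "ga_config"
  )
}

# Set one uniformly random bit in an all-zero chromosome (empty masks make
# Performance undefined).
repair_chromosome <- function(bits) {
  if (!any(bits == 1L)) bits[sample.int(length(bits), 1)] <- 1L
  bits
}

#' Initialize a GA population
#'
#' Member 1 is the all-ones chromosome (the solution containing every
#' feature); the remaining members have i.i.d. Bernoulli(0.5) bits.
#' All-zero chromosomes are repaired by setting one random bit.
#'
#' @param n Chromosome length (number of candidate features).
#' @param config A [ga_config()].
#' @return Integer 0/1 matrix with `population_size` rows and `n` columns.
#' @export
initialize_population <- function(n, config = ga_config()) {
  if (n < 1) abort("`n` must be at least 1.")
  with_seed(config$seed, {
    pop <- matrix(
      as.integer(runif(config$population_size * n) < 0.5),
      nrow = config$population_size, ncol = n
    )
    pop[1, ] <- 1L
    for (i in seq_len(nrow(pop))) pop[i, ] <- repair_chromosome(pop[i, ])
    pop
  })
}

#' Size-penalised fitness of a chromosome
#'
#' `performance - alpha * sum(bits) / n`: classification performance minus a
#' penalty proportional to the selected-feature fraction, so of two equally
#' performing masks the smaller one is fitter.  An all-zero chromosome gets
#' `-Inf` and can never be selected as best.
#'
#' @param chromosome Integer 0/1 vector.
#' @param performance The classifier performance achieved with this mask.
#' @param alpha Penalty weight (default 0.15).
#' @param n Feature-universe size; defaults to the chromosome length.
#' @return The fitness value.
#' @export
ga_fitness <- function(chromosome, performance, alpha = 0.15, n = length(chromosome)) {
  size <- sum(chromosome)
  if (size == 0) return(-Inf)
  if (!is.finite(performance)) abort("`performance` must be finite.")
  performance - alpha * size / n
}

# Rank members best-first: higher fitness, then smaller mask, then lower
# member index.
fitness_order <- function(fitness, sizes) {
  order(-fitness, sizes, seq_along(fitness))
}

#' Binary tournament selection
#'
#' Draws two members uniformly at random and returns the index of the
#' fitter; repeated twice (independently) to produce a parent pair.
#' Fitness ties are broken by the smaller selected-feature count, then by
#' the lower member index.  Consumes the current RNG stream.
#'
#' @param fitness Numeric vector of member fitness values.
#' @param sizes Integer vector of member popcounts (for tie-breaking);
#'   default zeros (index-only tie-break).
#' @return Integer vector of two member indices (the parent pair).
#' @export
tournament_select <- function(fitness, sizes = rep(0L, length(fitness))) {
  pick <- function() {
    cand <- sample.int(length(fitness), 2, replace = TRUE)
    better <- cand[order(-fitness[cand], sizes[cand], cand)][1]
    better
  }
  c(pick(), pick())
}

#' Two-point crossover
#'
#' With probability `rate`, two cut positions `a < b` are drawn uniformly
#' and the segment `(a, b]` is exchanged between the parents; otherwise the
#' children are copies of the parents.  Explicit `cuts = c(a, b)` applies
#' the exchange deterministically.
#'
#' @param p1,p2 Equal-length integer 0/1 vectors.
#' @param rate Per-pair crossover probability (default 0.8).
#' @param cuts Optional fixed cut positions `c(a, b)` with
#'   `0 <= a < b <= n`; bits at positions `a+1 .. b` are swapped.
#' @return List of two children.
#' @export
two_point_crossover <- function(p1, p2, rate = 0.8, cuts = NULL) {
  if (length(p1) != length(p2)) abort("Parents must have equal length.")
  n <- length(p1)
  do_cross <- if (is.null(cuts)) runif(1) < rate else TRUE
  if (do_cross) {
    if (is.null(cuts)) cuts <- sort(sample(0:n, 2))
    a <- cuts[1]; b <- cuts[2]
    if (!(a >= 0 && a < b && b <= n)) abort("Invalid cut positions.")
    seg <- (a + 1):b
    c1 <- p1; c2 <- p2
    c1[seg] <- p2[seg]
    c2[seg] <- p1[seg]
    list(c1, c2)
  } else {
    list(p1, p2)
  }
}

#' Bit-flip mutation
#'
#' Flips each bit independently with probability `rate`; an all-zero result
#' is repaired by setting one random bit.
#'
#' @param chromosome Integer 0/1 vector.
#' @param rate Per-bit flip probability (default 0.01).
#' @return Mutated chromosome.
#' @export
mutate_chromosome <- function(chromosome, rate = 0.01) {
  flip <- runif(length(chromosome)) < rate
  out <- ifelse(flip, 1L - chromosome, chromosome)
  repair_chromosome(as.integer(out))
}

#' Run the GA wrapper feature selection
#'
#' Evolves a population of binary feature masks over `data`.  By default a
#' chromosome's Performance is the mean inner `inner_k`-fold
#' cross-validated metric of the requested classifier on the masked
#' features, and its fitness subtracts `alpha` times the selected fraction.
#' The inner fold assignment is derived once from the master seed, making
#' every fitness evaluation a pure function of the chromosome; evaluations
#' are therefore reproducible for any `worker_count`.
#'
#' The run stops at `max_generations`, or earlier once the best fitness has
#' not changed for `stagnation_patience` consecutive generations.
#'
#' @param data Training data frame of features plus a label column.
#' @param config A [ga_config()].
#' @param classifier,metric,knn_k,scale,positive Passed to
#'   [evaluate_performance()].
#' @param candidates Feature indices the search is restricted to (the
#'   filter's output in hybrid mode); default all features.
#' @param label Name of the label column; default: last column.
#' @param inner_k Inner cross-validation folds for the Performance estimate
#'   (default 5).
#' @param performance_fn Optional override: `function(mask_indices)`
#'   returning a Performance value, replacing the inner-CV classifier
#'   evaluation (used for diagnostics and testing).
#' @return An object of class `fs_ga`: best selection (original feature
#'   indices), best chromosome/fitness/performance, a per-generation
#'   `history` tibble and the stop reason.
#' @export
run_ga <- function(data, config = ga_config(), classifier = "nbc",
                   metric = "gmean", candidates = NULL, label = NULL,
                   inner_k = 5, knn_k = 5, scale = TRUE, positive = NULL,
                   performance_fn = NULL) {
  classifier <- match.arg(classifier, c("nbc", "knn", "both"))
  metric <- match.arg(metric, c("gmean", "accuracy", "f1", "mcc"))
  d <- fs_split(data, label)
  if (is.null(candidates)) candidates <- seq_len(d$n_features)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0) abort("`candidates` must be non-empty.")
  if (any(candidates < 1) || any(candidates > d$n_features)) {
    abort("`candidates` out of range.")
  }
  n <- length(candidates)
  r <- config$population_size

  if (is.null(performance_fn)) {
    folds <- stratified_kfold(data, k = inner_k, seed = config$seed,
                              label = label)$fold
    fold_train <- lapply(seq_len(inner_k), function(f) which(folds != f))
    fold_test <- lapply(seq_len(inner_k), function(f) which(folds == f))
    xsq <- d$x^2
    # sufficient statistics per fold and class: a Gaussian NBC fit for any
    # mask is then a plain column lookup instead of a pass over the data
    fold_stats <- lapply(seq_len(inner_k), function(f) {
      tr <- fold_train[[f]]
      per_class <- lapply(d$classes, function(cl) {
        rows <- tr[d$y[tr] == cl]
        list(n = length(rows),
             s1 = colSums(d$x[rows, , drop = FALSE]),
             s2 = colSums(xsq[rows, , drop = FALSE]))
      })
      list(per_class = per_class, n = length(tr),
           tot1 = colSums(d$x[tr, , drop = FALSE]),
           tot2 = colSums(xsq[tr, , drop = FALSE]))
    })
    nbc_fold <- function(m, f) {
      st <- fold_stats[[f]]
      te <- fold_test[[f]]
      gmu <- st$tot1[m] / st$n
      gvar <- pmax((st$tot2[m] - st$n * gmu^2) / (st$n - 1), 0)
      floor_var <- 1e-9 * (gvar + 1)
      xte <- d$x[te, m, drop = FALSE]
      xte_sq <- xsq[te, m, drop = FALSE]
      logp <- vapply(seq_along(d$classes), function(ci) {
        pc <- st$per_class[[ci]]
        mu <- pc$s1[m] / pc$n
        v <- if (pc$n < 2) rep(0, length(m)) else
          (pc$s2[m] - pc$n * mu^2) / (pc$n - 1)
        v <- pmax(v, floor_var)
        drop(xte %*% (mu / v) - xte_sq %*% (0.5 / v)) -
          sum(mu^2 / (2 * v)) - sum(0.5 * log(2 * pi * v)) +
          log(pc$n / st$n)
      }, numeric(length(te)))
      pred <- d$classes[max.col(matrix(logp, nrow = length(te)),
                                ties.method = "first")]
      metric_core(d$y[te], pred, metric, positive, d$classes)
    }
    # standardization is per-feature, so the scaled fold matrices can be
    # built once and column-subset per mask
    knn_scaled <- if (classifier %in% c("knn", "both")) {
      lapply(seq_len(inner_k), function(f) {
        tr <- fold_train[[f]]
        te <- fold_test[[f]]
        xtr <- d$x[tr, , drop = FALSE]
        xte <- d$x[te, , drop = FALSE]
        if (scale) {
          mu <- colMeans(xtr)
          s <- apply(xtr, 2, sd)
          s[s == 0 | is.na(s)] <- 1
          xtr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
          xte <- sweep(sweep(xte, 2, mu), 2, s, "/")
        }
        list(xtr = xtr, xte = xte)
      })
    }
    knn_fold <- function(m, f) {
      ks <- knn_scaled[[f]]
      pred <- knn_core_predict(ks$xtr[, m, drop = FALSE], d$y[fold_train[[f]]],
                               ks$xte[, m, drop = FALSE], knn_k, FALSE,
                               d$classes)
      metric_core(d$y[fold_test[[f]]], pred, metric, positive, d$classes)
    }
    performance_fn <- function(mask_indices) {
      vals <- vapply(seq_len(inner_k), function(f) {
        switch(classifier,
          nbc = nbc_fold(mask_indices, f),
          knn = knn_fold(mask_indices, f),
          both = (nbc_fold(mask_indices, f) + knn_fold(mask_indices, f)) / 2
        )
      }, numeric(1))
      mean(vals)
    }
  }

  cache <- new.env(parent = emptyenv())
  eval_one <- function(bits) {
    if (sum(bits) == 0) return(c(-Inf, NA_real_))
    perf <- performance_fn(candidates[bits == 1L])
    if (!is.finite(perf)) {
      abort(sprintf("Performance evaluation failed for chromosome '%s'.",
                    paste(bits, collapse = "")))
    }
    c(ga_fitness(bits, perf, config$alpha, n), perf)
  }
  evaluate_all <- function(pop) {
    keys <- apply(pop, 1, paste, collapse = "")
    todo <- !vapply(keys, exists, logical(1), envir = cache)
    if (any(todo)) {
      rows <- which(todo)
      uk <- !duplicated(keys[rows])
      rows <- rows[uk]
      results <- if (config$worker_count > 1 &&
                     .Platform$OS.type == "unix") {
        # evaluations are RNG-free, so forked workers cannot perturb the
        # master stream; mc.set.seed = FALSE keeps the parent state intact
        parallel::mclapply(rows, function(i) eval_one(pop[i, ]),
                           mc.cores = config$worker_count,
                           mc.set.seed = FALSE)
      } else {
        lapply(rows, function(i) eval_one(pop[i, ]))
      }
      for (j in seq_along(rows)) {
        res <- results[[j]]
        if (inherits(res, "try-error") || inherits(res, "condition")) {
          abort(sprintf("Fitness evaluation failed for chromosome '%s': %s",
                        keys[rows[j]], conditionMessage(attr(res, "condition") %||% res)))
        }
        assign(keys[rows[j]], res, envir = cache)
      }
    }
    out <- t(vapply(keys, get, numeric(2), envir = cache))
    dimnames(out) <- NULL
    out
  }

  history <- vector("list", config$max_generations + 1)
  best_bits <- NULL
  best_fitness <- -Inf
  best_performance <- NA_real_
  stagnation <- 0L
  stop_reason <- "max_generations"

  with_seed(config$seed, {
    pop <- matrix(
      as.integer(runif(r * n) < 0.5), nrow = r, ncol = n
    )
    pop[1, ] <- 1L
    for (i in seq_len(r)) pop[i, ] <- repair_chromosome(pop[i, ])

    ev <- evaluate_all(pop)
    fitness <- ev[, 1]
    sizes <- rowSums(pop)
    top <- fitness_order(fitness, sizes)[1]
    best_bits <- pop[top, ]
    best_fitness <- fitness[top]
    best_performance <- ev[top, 2]
    history[[1]] <- tibble(
      generation = 0L, best_fitness = best_fitness,
      mean_fitness = mean(fitness[is.finite(fitness)]),
      best_size = sum(best_bits), stagnation = 0L
    )

    for (gen in seq_len(config$max_generations)) {
      ord <- fitness_order(fitness, sizes)
      elite <- pop[ord[1], ]
      children <- list(elite)
      while (length(children) < r) {
        parents <- if (config$selection == "best_pair") {
          ord[1:2]
        } else {
          tournament_select(fitness, sizes)
        }
        kids <- two_point_crossover(pop[parents[1], ], pop[parents[2], ],
                                    rate = config$crossover_rate)
        kids <- lapply(kids, mutate_chromosome, rate = config$mutation_rate)
        children <- c(children, kids)
      }
      pop <- do.call(rbind, children[seq_len(r)])
      ev <- evaluate_all(pop)
      fitness <- ev[, 1]
      sizes <- rowSums(pop)
      top <- fitness_order(fitness, sizes)[1]
      improved <- fitness[top] > best_fitness
      if (improved) {
        best_bits <- pop[top, ]
        best_fitness <- fitness[top]
        best_performance <- ev[top, 2]
        stagnation <- 0L
      } else {
        if (fitness[top] == best_fitness && sum(pop[top, ]) < sum(best_bits)) {
          # same fitness, strictly smaller mask: keep the smaller solution
          # without resetting the stagnation counter (fitness is unchanged)
          best_bits <- pop[top, ]
          best_performance <- ev[top, 2]
        }
        stagnation <- stagnation + 1L
      }
      history[[gen + 1]] <- tibble(
        generation = gen, best_fitness = best_fitness,
        mean_fitness = mean(fitness[is.finite(fitness)]),
        best_size = sum(best_bits), stagnation = stagnation
      )
      if (stagnation >= config$stagnation_patience) {
        stop_reason <- "stagnation"
        break
      }
    }
  })

  structure(
    list(
      selected = candidates[best_bits == 1L],
      best_chromosome = best_bits,
      best_fitness = best_fitness,
      best_performance = best_performance,
      history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
      stop_reason = stop_reason,
      candidates = candidates,
      feature_names = d$feature_names,
      config = config,
      classifier = classifier,
      metric = metric
    ),
    class = "fs_ga"
  )
}

#' @export
print.fs_ga <- function(x, ...) {
  cat(sprintf(
    "GA wrapper feature selection: %d of %d candidate features selected\n",
    length(x$selected), length(x$candidates)
  ))
  cat(sprintf("  best fitness %.4f (performance %.4f), stopped by %s after %d generations\n",
              x$best_fitness, x$best_performance, x$stop_reason,
              max(x$history$generation)))
  invisible(x)
}
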