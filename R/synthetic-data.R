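# Synthetic benchmark generators with known ground truth.
#
# Real feature-selection benchmarks are external downloads; these generators
# stand in for them so filters, classifiers and the GA wrapper are testable
# offline.  Ground truth records which features are informative, redundant
# (derived from an informative source) or pure noise.

make_ground_truth <- function(informative, redundant_source, noise) {
  redundant <- if (length(redundant_source)) {
    tibble(
      redundant = as.integer(names(redundant_source)),
      source = as.integer(redundant_source)
    )
  } else {
    tibble(redundant = integer(0), source = integer(0))
  }
  structure(
    list(
      informative = as.integer(informative),
      redundant = redundant,
      noise = as.integer(noise)
    ),
    class = "fs_ground_truth"
  )
}

#' Generate a Gaussian-cluster dataset with informative, redundant and noise
#' features
#'
#' Emulates hypercube-cluster benchmarks of the Madelon family: the two
#' classes sit at centres separated by `class_sep` along a random direction
#' of the informative subspace, each informative coordinate carrying unit
#' Gaussian noise.  Redundant features are noisy random linear combinations
#' of the informative block; noise features are label-independent standard
#' Gaussians; labels are flipped with probability `flip_prob`.
#'
#' Defaults give the 10-relevant/90-noise, 500-sample fixture used for
#' wrapper recovery experiments.
#'
#' @param n_samples Number of samples (default 500).
#' @param n_informative Number of informative features (default 10).
#' @param n_redundant Number of redundant features (default 0).
#' @param n_noise Number of noise features (default 90).
#' @param class_sep Distance between the two class centres, in within-class
#'   standard deviations (default 2).
#' @param flip_prob Probability of flipping each label (default 0).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A list with `data` (tibble, label column `class` with symbols
#'   `"neg"`/`"pos"`) and `truth` (ground-truth feature grouping with
#'   1-based indices).
#' @export
make_informative_dataset <- function(n_samples = 500, n_informative = 10,
                                     n_redundant = 0, n_noise = 90,
                                     class_sep = 2, flip_prob = 0, seed = 1) {
  if (n_samples < 1) abort("`n_samples` must be positive.")
  if (n_informative < 1) abort("`n_informative` must be at least 1.")
  if (n_redundant < 0 || n_noise < 0) abort("Feature counts must be non-negative.")
  n_total <- n_informative + n_redundant + n_noise
  if (n_total < 1) abort("At least one feature is required.")
  with_seed(seed, {
    y_bit <- rep_len(c(0L, 1L), n_samples)[sample(n_samples)]
    # equal-magnitude random-sign direction: every informative feature
    # carries the same share of the class separation (a random unit vector
    # would leave near-zero-loading coordinates effectively uninformative)
    u <- sample(c(-1, 1), n_informative, replace = TRUE) / sqrt(n_informative)
    centers <- outer(ifelse(y_bit == 1, class_sep / 2, -class_sep / 2), u)
    x_inf <- centers + matrix(rnorm(n_samples * n_informative),
                              n_samples, n_informative)
    x <- x_inf
    if (n_redundant > 0) {
      w <- matrix(rnorm(n_informative * n_redundant), n_informative, n_redundant)
      w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
      x_red <- x_inf %*% w +
        0.1 * matrix(rnorm(n_samples * n_redundant), n_samples, n_redundant)
      x <- cbind(x, x_red)
    }
    if (n_noise > 0) {
      x <- cbind(x, matrix(rnorm(n_samples * n_noise), n_samples, n_noise))
    }
    if (flip_prob > 0) {
      flip <- runif(n_samples) < flip_prob
      y_bit[flip] <- 1L - y_bit[flip]
    }
    colnames(x) <- paste0("f", seq_len(n_total))
    data <- as_tibble(as.data.frame(x))
    data$class <- ifelse(y_bit == 1, "pos", "neg")
    inf_idx <- seq_len(n_informative)
    red_idx <- seq_len(n_redundant) + n_informative
    noise_idx <- seq_len(n_noise) + n_informative + n_redundant
    red_map <- if (n_redundant > 0) {
      stats::setNames(rep_len(inf_idx, n_redundant), red_idx)
    } else {
      integer(0)
    }
    list(
      data = data,
      truth = make_ground_truth(inf_idx, red_map, noise_idx)
    )
  })
}

#' Generate an XOR-interaction dataset
#'
#' Two standard-Gaussian features whose product sign determines the label:
#' each is marginally independent of the label, but jointly they determine
#' it.  This is the canonical case where any univariate ranking fails and a
#' multivariate wrapper (or a conditional-information filter) succeeds.
#'
#' @param n_samples Number of samples (at least 8; default 400).
#' @param n_noise Number of appended label-independent Gaussian features
#'   (default 20).
#' @param seed Integer seed.
#' @return As [make_informative_dataset()]: list of `data` and `truth`.
#' @export
make_xor_dataset <- function(n_samples = 400, n_noise = 20, seed = 1) {
  if (n_samples < 8) abort("`n_samples` must be at least 8.")
  if (n_noise < 0) abort("`n_noise` must be non-negative.")
  with_seed(seed, {
    x1 <- rnorm(n_samples)
    x2 <- rnorm(n_samples)
    y <- ifelse(x1 * x2 > 0, "pos", "neg")
    x <- cbind(x1, x2)
    if (n_noise > 0) {
      x <- cbind(x, matrix(rnorm(n_samples * n_noise), n_samples, n_noise))
    }
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    data <- as_tibble(as.data.frame(x))
    data$class <- y
    list(
      data = data,
      truth = make_ground_truth(1:2, integer(0),
                                if (n_noise > 0) 2L + seq_len(n_noise) else integer(0))
    )
  })
}

#' Generate a binary-feature dataset with exactly known information content
#'
#' A variant of [make_informative_dataset()] with 0/1 features, intended for
#' exact mutual-information oracle tests: each informative feature equals the
#' label bit flipped independently with probability `flip_prob`, so its
#' population MI with the label is the closed-form `1 - H2(flip_prob)` bits;
#' noise features are independent fair coin flips.
#'
#' @param n_samples Number of samples (default 200).
#' @param n_informative Number of informative binary features (default 2).
#' @param n_noise Number of fair-coin noise features (default 5).
#' @param flip_prob Per-feature probability of disagreeing with the label
#'   (default 0.1).
#' @param seed Integer seed.
#' @return As [make_informative_dataset()]: list of `data` and `truth`.
#' @export
make_binary_dataset <- function(n_samples = 200, n_informative = 2,
                                n_noise = 5, flip_prob = 0.1, seed = 1) {
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (n_informative < 1) abort("`n_informative` must be at least 1.")
  with_seed(seed, {
    y_bit <- rep_len(c(0L, 1L), n_samples)[sample(n_samples)]
    inf <- sapply(seq_len(n_informative), function(j) {
      flip <- runif(n_samples) < flip_prob
      ifelse(flip, 1L - y_bit, y_bit)
    })
    x <- matrix(inf, n_samples, n_informative)
    if (n_noise > 0) {
      x <- cbind(x, matrix(rbinom(n_samples * n_noise, 1L, 0.5),
                           n_samples, n_noise))
    }
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    data <- as_tibble(as.data.frame(x))
    data$class <- ifelse(y_bit == 1, "pos", "neg")
    list(
      data = data,
      truth = make_ground_truth(seq_len(n_informative), integer(0),
                                if (n_noise > 0) n_informative + seq_len(n_noise) else integer(0))
    )
  })
}

#' Serialize a ground-truth feature grouping to JSON
#'
#' @param truth A ground-truth object from one of the generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "fs_ground_truth"))
  jsonlite::write_json(
    list(
      informative = truth$informative,
      redundant = truth$redundant,
      noise = truth$noise
    ),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.fs_ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$informative), "informative,",
      nrow(x$redundant), "redundant,", length(x$noise), "noise features\n")
  invisible(x)
}
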