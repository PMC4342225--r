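# Information-theoretic filter pre-selection.
#
# All mutual-information quantities are plug-in estimates on empirical
# contingency tables, in bits (log base 2).  Continuous features are
# discretized by equal-frequency binning first; integer-coded features with
# few distinct values pass through untouched.

#' Equal-frequency discretization
#'
#' Bins a numeric vector into `n_bins` approximately equally occupied bins,
#' using ranks: `code = floor((rank - 1) * n_bins / n)` with minimum-rank
#' ties, so tied values always share one bin and, for distinct values, bin
#' occupancies differ by at most one.  Inputs that are already integer-coded
#' with at most `n_bins` distinct values keep their grouping unchanged
#' (codes are the 0-based rank of the distinct value).
#'
#' @param values Numeric vector, non-empty.
#' @param n_bins Number of bins, at least 1 (default 10).
#' @return Integer vector of 0-based bin codes with attribute `n_bins`
#'   (the number of distinct codes actually used is at most `n_bins`).
#' @export
discretize_equal_frequency <- function(values, n_bins = 10) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (n_bins < 1) abort("`n_bins` must be at least 1.")
  distinct <- sort(unique(values))
  if (length(distinct) <= n_bins && all(values == round(values))) {
    codes <- match(values, distinct) - 1L
  } else {
    r <- rank(values, ties.method = "min")
    codes <- as.integer(floor((r - 1) * n_bins / length(values)))
  }
  structure(codes, n_bins = as.integer(n_bins))
}

# Coerce an arbitrary vector to dense 0-based integer codes.
as_codes <- function(x) {
  if (is.integer(x) && !is.null(attr(x, "n_bins"))) {
    x <- as.integer(x)
  }
  f <- factor(x)
  list(codes = as.integer(f) - 1L, n_levels = nlevels(f))
}

mi_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  ind <- outer(px, py)
  sum(p[nz] * log2(p[nz] / ind[nz]))
}

# Fast plug-in MI between two 0-based code vectors with known level counts.
mi_codes <- function(cx, nx, cy, ny) {
  counts <- tabulate(cx * ny + cy + 1L, nbins = nx * ny)
  mi_from_counts(matrix(counts, nrow = nx, ncol = ny, byrow = TRUE))
}

# Plug-in CMI(x; y | z) as the z-weighted sum of conditional MIs.
cmi_codes <- function(cx, nx, cy, ny, cz, nz) {
  n <- length(cx)
  out <- 0
  for (zv in seq_len(nz) - 1L) {
    sel <- cz == zv
    m <- sum(sel)
    if (m > 0) {
      out <- out + (m / n) * mi_codes(cx[sel], nx, cy[sel], ny)
    }
  }
  out
}

#' Mutual information between two discrete variables
#'
#' Plug-in estimate from the empirical joint contingency table, in bits.
#' Inputs may be discretized codes from [discretize_equal_frequency()] or
#' any vectors coercible to factors (e.g. class labels).
#'
#' @param x,y Equal-length vectors.
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  a <- as_codes(x)
  b <- as_codes(y)
  mi_codes(a$codes, a$n_levels, b$codes, b$n_levels)
}

#' Conditional mutual information I(x; y | z)
#'
#' Plug-in estimate \eqn{\sum_z p(z) I(x; y \mid Z = z)} in bits.
#'
#' @param x,y,z Equal-length vectors.
#' @return Non-negative conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    abort("`x`, `y` and `z` must have equal length.")
  }
  a <- as_codes(x)
  b <- as_codes(y)
  c_ <- as_codes(z)
  cmi_codes(a$codes, a$n_levels, b$codes, b$n_levels, c_$codes, c_$n_levels)
}

new_fs_ranking <- function(order, scores, names, criterion, n_features, n_bins = NA_integer_) {
  out <- tibble(
    rank = seq_along(order),
    feature = as.integer(order),
    name = names[order],
    score = as.numeric(scores)
  )
  class(out) <- c("fs_ranking", class(out))
  attr(out, "criterion") <- criterion
  attr(out, "n_features") <- as.integer(n_features)
  attr(out, "n_bins") <- n_bins
  out
}

#' Greedy information-theoretic feature ranking
#'
#' Forward selection under one of the classical mutual-information criteria.
#' The first pick always maximizes the feature-label MI; with `S` the set
#' already selected, candidate `X_k` is then scored by:
#' \describe{
#'   \item{mrmr}{\eqn{I(X_k;Y) - \frac{1}{|S|}\sum_{j \in S} I(X_k;X_j)} —
#'     relevance minus mean redundancy.}
#'   \item{jmi}{\eqn{\sum_{j \in S} I(X_k,X_j;Y)} — cumulative joint MI with
#'     the label.}
#'   \item{cmim}{\eqn{\min_{j \in S} I(X_k;Y\mid X_j)} — worst-case
#'     conditional relevance.}
#'   \item{icap}{\eqn{I(X_k;Y) - \sum_{j \in S}\max(0,\, I(X_k;X_j) -
#'     I(X_k;X_j\mid Y))} — relevance minus positively-capped interaction.}
#' }
#' Ties are broken by the lowest feature index; the procedure is
#' deterministic and invariant to sample order.
#'
#' @param data Data frame of features plus a label column.
#' @param criterion One of `"mrmr"`, `"jmi"`, `"cmim"`, `"icap"`, or
#'   `"correlation"` (which delegates to [correlation_ranking()]).
#' @param n_select Number of features to rank (default: all).
#' @param n_bins Bins for equal-frequency discretization of continuous
#'   features (default 10).
#' @param label Name of the label column; default: last column.
#' @return A `fs_ranking` tibble with columns `rank`, `feature` (1-based
#'   index into the feature columns), `name` and `score` (criterion value at
#'   selection time).
#' @export
rank_features <- function(data, criterion = c("mrmr", "jmi", "cmim", "icap", "correlation"),
                          n_select = NULL, n_bins = 10, label = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "correlation") {
    return(correlation_ranking(data, n_select = n_select, label = label))
  }
  d <- fs_split(data, label)
  n <- d$n_features
  if (is.null(n_select)) n_select <- n
  if (n_select < 1 || n_select > n) {
    abort(sprintf("`n_select` must be in [1, %d].", n))
  }
  disc <- lapply(seq_len(n), function(j) {
    as_codes(discretize_equal_frequency(d$x[, j], n_bins))
  })
  cx <- lapply(disc, `[[`, "codes")
  nx <- vapply(disc, `[[`, integer(1), "n_levels")
  yy <- as_codes(d$y)
  cy <- yy$codes
  ny <- yy$n_levels

  relevance <- vapply(seq_len(n), function(k) mi_codes(cx[[k]], nx[k], cy, ny),
                      numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(n)
  # running per-candidate state, updated when a feature joins S
  red_sum <- numeric(n)   # mrmr: sum of I(Xk;Xj)
  jmi_sum <- numeric(n)   # jmi:  sum of I(Xk,Xj;Y)
  cmim_min <- rep(Inf, n) # cmim: min of I(Xk;Y|Xj)
  icap_pen <- numeric(n)  # icap: sum of max(0, I(Xk;Xj) - I(Xk;Xj|Y))

  for (step in seq_len(n_select)) {
    if (step == 1) {
      cand_scores <- relevance[remaining]
    } else {
      cand_scores <- switch(criterion,
        mrmr = relevance[remaining] - red_sum[remaining] / length(selected),
        jmi = jmi_sum[remaining],
        cmim = cmim_min[remaining],
        icap = relevance[remaining] - icap_pen[remaining]
      )
    }
    pick <- remaining[which.max(cand_scores)]
    selected <- c(selected, pick)
    scores <- c(scores, max(cand_scores))
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0 || step == n_select) break
    # fold the new member into every candidate's running state
    for (k in remaining) {
      if (criterion == "mrmr") {
        red_sum[k] <- red_sum[k] + mi_codes(cx[[k]], nx[k], cx[[pick]], nx[pick])
      } else if (criterion == "jmi") {
        pair <- cx[[k]] * nx[pick] + cx[[pick]]
        jmi_sum[k] <- jmi_sum[k] +
          mi_codes(pair, nx[k] * nx[pick], cy, ny)
      } else if (criterion == "cmim") {
        v <- cmi_codes(cx[[k]], nx[k], cy, ny, cx[[pick]], nx[pick])
        cmim_min[k] <- min(cmim_min[k], v)
      } else if (criterion == "icap") {
        mi_kj <- mi_codes(cx[[k]], nx[k], cx[[pick]], nx[pick])
        cmi_kj_y <- cmi_codes(cx[[k]], nx[k], cx[[pick]], nx[pick], cy, ny)
        icap_pen[k] <- icap_pen[k] + max(0, mi_kj - cmi_kj_y)
      }
    }
  }
  new_fs_ranking(selected, scores, d$feature_names, criterion, n,
                 as.integer(n_bins))
}

#' Rank features by absolute class correlation
#'
#' The correlation baseline: features are ranked by the absolute Pearson
#' correlation between the feature and a 0/1 class encoding (point-biserial
#' correlation).  For more than two classes the maximum over one-vs-rest
#' encodings is used.  Zero-variance features score 0.  Ties are broken by
#' the lower feature index.
#'
#' @inheritParams rank_features
#' @return A `fs_ranking` tibble (see [rank_features()]).
#' @export
correlation_ranking <- function(data, n_select = NULL, label = NULL) {
  d <- fs_split(data, label)
  n <- d$n_features
  if (is.null(n_select)) n_select <- n
  if (n_select < 1 || n_select > n) {
    abort(sprintf("`n_select` must be in [1, %d].", n))
  }
  encodings <- if (length(d$classes) == 2) {
    list(as.numeric(d$y == default_positive(d$classes)))
  } else {
    lapply(d$classes, function(cl) as.numeric(d$y == cl))
  }
  score <- vapply(seq_len(n), function(j) {
    v <- d$x[, j]
    if (sd(v) == 0) return(0)
    max(vapply(encodings, function(e) {
      if (sd(e) == 0) 0 else abs(cor(v, e))
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-score, seq_len(n))[seq_len(n_select)]
  new_fs_ranking(ord, score[ord], d$feature_names, "correlation", n)
}

#' Keep the top fraction of a ranking
#'
#' Returns the first `ceiling(fraction * n_total)` feature indices of a
#' ranking (at least one).  The 10% default is the standard pre-selection
#' threshold for the hybrid filter-then-wrapper pipeline.
#'
#' @param ranking A `fs_ranking` tibble from [rank_features()] or
#'   [correlation_ranking()].
#' @param fraction Fraction of all features to keep, in (0, 1] (default 0.1).
#' @param n_total Total feature count the fraction refers to; defaults to
#'   the ranking's recorded feature universe.
#' @return Integer vector of feature indices, best first.
#' @export
select_top_fraction <- function(ranking, fraction = 0.1, n_total = NULL) {
  if (!(fraction > 0 && fraction <= 1)) {
    abort("`fraction` must be in (0, 1].")
  }
  if (is.null(n_total)) n_total <- attr(ranking, "n_features")
  m <- max(1L, as.integer(ceiling(fraction * n_total)))
  m <- min(m, nrow(ranking))
  ranking$feature[seq_len(m)]
}

#' @export
print.fs_ranking <- function(x, ...) {
  cat(sprintf("Feature ranking (%s criterion, %d of %d features):\n",
              attr(x, "criterion"), nrow(x), attr(x, "n_features")))
  NextMethod()
}

#' Plot a feature ranking
#'
#' Criterion score against rank, the standard scree-style diagnostic for
#' choosing a retention threshold.
#'
#' @param object A `fs_ranking` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fs_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Rank", y = "Criterion score",
      title = sprintf("Greedy %s ranking", attr(object, "criterion"))
    )
}
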