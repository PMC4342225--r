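# Confusion-matrix performance metrics and the selection-stability statistic.

#' Confusion counts for a binary task
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive The class symbol treated as positive; default: the
#'   lexicographically last symbol in `y_true`.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(positive)) positive <- default_positive(unique(y_true))
  if (!positive %in% c(y_true, y_pred)) {
    abort(sprintf("Positive class '%s' absent from the label alphabet.", positive))
  }
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn)
}

# 0/0 metric forms return 0 by convention (conservative: an undefined rate
# never inflates a score).
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Performance metrics from confusion counts
#'
#' Computes the standard binary metrics from TP/FP/TN/FN:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' GMean = sqrt(sensitivity x specificity),
#' F1 = 2 x PPV x sensitivity / (PPV + sensitivity),
#' accuracy = (TP+TN)/total, and Matthews correlation
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any 0/0 form evaluates to 0 (and MCC to 0 when its denominator vanishes).
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (as from [confusion_counts()]).
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `ppv`, `gmean`, `f1`, `accuracy`, `mcc`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp[1]; fp <- counts$fp[1]; tn <- counts$tn[1]; fn <- counts$fn[1]
  total <- tp + fp + tn + fn
  if (total == 0) abort("Confusion counts sum to zero.")
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  ppv <- safe_ratio(tp, tp + fp)
  gmean <- sqrt(sens * spec)
  f1 <- safe_ratio(2 * ppv * sens, ppv + sens)
  acc <- (tp + tn) / total
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  tibble(
    sensitivity = sens, specificity = spec, ppv = ppv,
    gmean = gmean, f1 = f1, accuracy = acc, mcc = mcc
  )
}

#' Full metric set from label vectors
#'
#' Convenience wrapper: for a binary task, metrics are computed against the
#' positive class; for more than two classes each metric is computed
#' one-vs-rest per class and macro-averaged.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble as [compute_metrics()].
#' @export
classification_metrics <- function(y_true, y_pred, positive = NULL) {
  classes <- sort(unique(as.character(y_true)))
  if (length(classes) <= 2) {
    compute_metrics(confusion_counts(y_true, y_pred, positive))
  } else {
    per_class <- lapply(classes, function(cl) {
      compute_metrics(confusion_counts(y_true, y_pred, positive = cl))
    })
    as_tibble(as.list(colMeans(do.call(rbind, per_class))))
  }
}

#' Chance-corrected stability between two selected feature subsets
#'
#' The adjusted overlap statistic for subsets of possibly different sizes:
#' with subset sizes \eqn{k_i, k_j}, overlap \eqn{c}, and \eqn{n} features
#' in total,
#' \deqn{S = \frac{c - k_i k_j / n}{\min(k_i, k_j) - \max(0, k_i + k_j - n)}.}
#' Its range is (-1, 1]; 0 is the expected value when both subsets are drawn
#' uniformly at random, positive values indicate above-chance agreement.
#'
#' @param subset_a,subset_b Integer vectors of feature indices in `1..n`,
#'   non-empty.
#' @param n Total number of features.
#' @return The stability value.
#' @export
pairwise_stability <- function(subset_a, subset_b, n) {
  subset_a <- unique(as.integer(subset_a))
  subset_b <- unique(as.integer(subset_b))
  if (length(subset_a) == 0 || length(subset_b) == 0) {
    abort("Subsets must be non-empty.")
  }
  if (any(c(subset_a, subset_b) < 1) || any(c(subset_a, subset_b) > n)) {
    abort(sprintf("Subset indices must lie in [1, %d].", n))
  }
  ki <- length(subset_a)
  kj <- length(subset_b)
  cc <- length(intersect(subset_a, subset_b))
  den <- min(ki, kj) - max(0, ki + kj - n)
  if (den == 0) {
    abort("Stability undefined: denominator is zero (e.g. both subsets equal the full feature set).")
  }
  (cc - ki * kj / n) / den
}

#' Mean pairwise stability across folds
#'
#' Averages [pairwise_stability()] over all unordered pairs of selected
#' subsets (10 pairs for the usual 5 folds).
#'
#' @param subsets List of at least two integer index vectors.
#' @param n Total number of features.
#' @return A list with `pairwise` (tibble of `i`, `j`, `stability`) and
#'   `mean_stability`.
#' @export
mean_stability <- function(subsets, n) {
  if (length(subsets) < 2) abort("At least two subsets are required.")
  pairs <- utils::combn(length(subsets), 2)
  vals <- apply(pairs, 2, function(p) {
    tryCatch(
      pairwise_stability(subsets[[p[1]]], subsets[[p[2]]], n),
      error = function(e) {
        abort(sprintf("Stability undefined for subset pair (%d, %d): %s",
                      p[1], p[2], conditionMessage(e)))
      }
    )
  })
  list(
    pairwise = tibble(i = pairs[1, ], j = pairs[2, ], stability = vals),
    mean_stability = mean(vals)
  )
}
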