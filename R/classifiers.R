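# The wrapped classifiers: in-house Gaussian naive Bayes, k-nearest
# neighbours, and their combination, behind the single performance contract
# the GA fitness consumes.
#
# The public functions speak data frames; matrix-level cores below carry the
# actual arithmetic and are reused by the GA engine, which evaluates tens of
# thousands of masks and cannot afford per-call data-frame conversion.

# ---- matrix-level cores -------------------------------------------------

nbc_core_fit <- function(x, y, classes) {
  global_var <- apply(x, 2, var)
  global_var[is.na(global_var)] <- 0
  floor_var <- 1e-9 * (global_var + 1)
  k <- length(classes)
  p <- ncol(x)
  priors <- numeric(k)
  means <- matrix(0, k, p)
  vars <- matrix(0, k, p)
  for (ci in seq_len(k)) {
    rows <- y == classes[ci]
    priors[ci] <- mean(rows)
    xv <- x[rows, , drop = FALSE]
    means[ci, ] <- colMeans(xv)
    v <- if (nrow(xv) < 2) rep(0, p) else apply(xv, 2, var)
    vars[ci, ] <- pmax(v, floor_var)
  }
  list(classes = classes, priors = priors, means = means, vars = vars)
}

nbc_core_logpost <- function(fit, x) {
  k <- length(fit$classes)
  out <- matrix(0, nrow(x), k)
  for (ci in seq_len(k)) {
    mu <- fit$means[ci, ]
    v <- fit$vars[ci, ]
    ll <- -0.5 * sweep(sweep(x, 2, mu)^2, 2, v, "/") -
      matrix(0.5 * log(2 * pi * v), nrow(x), ncol(x), byrow = TRUE)
    out[, ci] <- log(fit$priors[ci]) + rowSums(ll)
  }
  out
}

nbc_core_predict <- function(fit, x) {
  logp <- nbc_core_logpost(fit, x)
  # first maximum = lexicographically first class (classes are sorted)
  fit$classes[max.col(logp, ties.method = "first")]
}

knn_core_predict <- function(xtr, ytr, xte, k, scale, classes) {
  if (scale) {
    mu <- colMeans(xtr)
    s <- apply(xtr, 2, sd)
    s[s == 0 | is.na(s)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, s, "/")
  }
  tr_sq <- rowSums(xtr^2)
  cross <- xte %*% t(xtr)
  vapply(seq_len(nrow(xte)), function(i) {
    dist2 <- tr_sq - 2 * cross[i, ] + sum(xte[i, ]^2)
    nn <- order(dist2)[seq_len(k)]
    votes <- tabulate(match(ytr[nn], classes), nbins = length(classes))
    classes[which.max(votes)]
  }, character(1))
}

# Single requested metric straight from label vectors; binary tasks score
# the positive class, multiclass macro-averages one-vs-rest.
metric_core <- function(y_true, y_pred, metric, positive, classes) {
  one <- function(pos) {
    tp <- sum(y_true == pos & y_pred == pos)
    fp <- sum(y_true != pos & y_pred == pos)
    tn <- sum(y_true != pos & y_pred != pos)
    fn <- sum(y_true == pos & y_pred != pos)
    switch(metric,
      accuracy = (tp + tn) / (tp + fp + tn + fn),
      gmean = {
        sens <- safe_ratio(tp, tp + fn)
        spec <- safe_ratio(tn, tn + fp)
        sqrt(sens * spec)
      },
      f1 = {
        sens <- safe_ratio(tp, tp + fn)
        ppv <- safe_ratio(tp, tp + fp)
        safe_ratio(2 * ppv * sens, ppv + sens)
      },
      mcc = {
        den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
        if (den == 0) 0 else (tp * tn - fp * fn) / den
      }
    )
  }
  if (length(classes) <= 2) {
    one(positive %||% default_positive(classes))
  } else {
    mean(vapply(classes, one, numeric(1)))
  }
}

# ---- public data-frame interface ----------------------------------------

# A feature mask may be a logical/0-1 vector of length n or a vector of
# 1-based indices; normalised to sorted unique indices.
normalize_mask <- function(mask, n) {
  if (is.null(mask)) return(seq_len(n))
  mask <- unname(mask)
  idx <- if (is.logical(mask) ||
             (length(mask) == n && all(mask %in% c(0, 1)) && n > 1)) {
    if (length(mask) != n) {
      abort(sprintf("Mask length %d does not match %d features.", length(mask), n))
    }
    which(as.logical(mask))
  } else {
    as.integer(mask)
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0) abort("Feature mask selects no features.")
  if (any(idx < 1) || any(idx > n)) {
    abort(sprintf("Mask indices must lie in [1, %d].", n))
  }
  idx
}

#' Fit a Gaussian naive Bayes classifier
#'
#' In-house naive Bayes with one Gaussian class-conditional density per
#' selected feature.  Priors are the empirical class frequencies; per-class
#' variances are floored at `1e-9 * (global feature variance + 1)` so
#' constant features degrade to the prior rather than producing infinities.
#'
#' @param data Training data frame of features plus a label column.
#' @param mask Feature mask: logical/0-1 vector over all features, or
#'   1-based indices; default all features.
#' @param label Name of the label column; default: last column.
#' @return An object of class `nbc_model`.
#' @export
nbc_fit <- function(data, mask = NULL, label = NULL) {
  d <- fs_split(data, label)
  idx <- normalize_mask(mask, d$n_features)
  x <- d$x[, idx, drop = FALSE]
  global_var <- apply(x, 2, var)
  global_var[is.na(global_var)] <- 0
  floor_var <- 1e-9 * (global_var + 1)
  classes <- d$classes
  priors <- vapply(classes, function(cl) mean(d$y == cl), numeric(1))
  means <- t(vapply(classes, function(cl) {
    colMeans(x[d$y == cl, , drop = FALSE])
  }, numeric(ncol(x))))
  vars <- t(vapply(classes, function(cl) {
    xv <- x[d$y == cl, , drop = FALSE]
    v <- apply(xv, 2, function(col) if (length(col) < 2) 0 else var(col))
    pmax(v, floor_var)
  }, numeric(ncol(x))))
  dim(means) <- c(length(classes), ncol(x))
  dim(vars) <- c(length(classes), ncol(x))
  structure(
    list(
      classes = classes, priors = priors,
      means = means, vars = vars,
      mask = idx, n_features = d$n_features,
      feature_names = d$feature_names[idx]
    ),
    class = "nbc_model"
  )
}

nbc_log_posterior <- function(model, x) {
  # rows: test samples, cols: classes (in model$classes order, sorted)
  logp <- vapply(seq_along(model$classes), function(ci) {
    mu <- model$means[ci, ]
    v <- model$vars[ci, ]
    ll <- -0.5 * sweep(sweep(x, 2, mu)^2, 2, v, "/") -
      matrix(0.5 * log(2 * pi * v), nrow(x), ncol(x), byrow = TRUE)
    log(model$priors[ci]) + rowSums(ll)
  }, numeric(nrow(x)))
  matrix(logp, nrow = nrow(x))
}

#' Predict with a naive Bayes model
#'
#' Argmax over classes of log prior plus summed log Gaussian densities;
#' posterior ties go to the lexicographically first class symbol.
#'
#' @param model An `nbc_model` from [nbc_fit()].
#' @param data Data frame with the same feature columns as at fit time
#'   (a label column, if present, is ignored for prediction).
#' @param type `"class"` (default) for predicted labels, `"prob"` for the
#'   posterior probability matrix.
#' @param label Name of the label column to ignore; default: last column if
#'   it is non-numeric.
#' @return Character vector of predicted labels, or a samples-by-classes
#'   posterior matrix.
#' @export
nbc_predict <- function(model, data, type = c("class", "prob"), label = NULL) {
  type <- match.arg(type)
  x <- extract_features(data, model$n_features, label)
  x <- x[, model$mask, drop = FALSE]
  logp <- nbc_log_posterior(model, x)
  if (type == "prob") {
    m <- apply(logp, 1, max)
    p <- exp(logp - m)
    p <- p / rowSums(p)
    colnames(p) <- model$classes
    return(p)
  }
  # which.max returns the first maximum; classes are sorted, so ties fall to
  # the lexicographically first symbol
  model$classes[apply(logp, 1, which.max)]
}

#' @export
predict.nbc_model <- function(object, newdata, type = c("class", "prob"), ...) {
  nbc_predict(object, newdata, type = match.arg(type))
}

# Pull the numeric feature matrix out of a data frame that may or may not
# carry a label column.
extract_features <- function(data, n_features, label = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  cols <- names(data)
  if (!is.null(label) && label %in% cols) {
    data <- data[setdiff(cols, label)]
  } else if (ncol(data) == n_features + 1 && !is.numeric(data[[ncol(data)]])) {
    data <- data[-ncol(data)]
  }
  if (ncol(data) != n_features) {
    abort(sprintf("Expected %d feature columns, found %d.", n_features, ncol(data)))
  }
  as.matrix(as.data.frame(lapply(data, as.numeric)))
}

#' k-nearest-neighbour prediction
#'
#' Majority vote among the `k` training samples nearest in Euclidean
#' distance over the selected features.  Features are standardized with the
#' training-set mean and standard deviation by default (zero-sd features are
#' left unscaled).  Distance ties are broken by the lower training index;
#' vote ties by the lexicographically first class symbol.
#'
#' @param train Training data frame of features plus a label column.
#' @param test Data frame to predict (label column, if any, ignored).
#' @param k Number of neighbours (default 5); must not exceed the training
#'   sample count.
#' @param mask Feature mask as in [nbc_fit()].
#' @param scale Standardize features with training mean/sd first
#'   (default TRUE).
#' @param label Name of the label column; default: last column.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train, test, k = 5, mask = NULL, scale = TRUE,
                        label = NULL) {
  d <- fs_split(train, label)
  idx <- normalize_mask(mask, d$n_features)
  if (k < 1 || k > nrow(d$x)) {
    abort(sprintf("`k` must lie in [1, %d].", nrow(d$x)))
  }
  xtr <- d$x[, idx, drop = FALSE]
  xte <- extract_features(test, d$n_features, label)[, idx, drop = FALSE]
  if (scale) {
    mu <- colMeans(xtr)
    s <- apply(xtr, 2, sd)
    s[s == 0 | is.na(s)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, s, "/")
  }
  classes <- d$classes
  tr_sq <- rowSums(xtr^2)
  vapply(seq_len(nrow(xte)), function(i) {
    dist2 <- tr_sq - 2 * drop(xtr %*% xte[i, ]) + sum(xte[i, ]^2)
    # order() is stable: equal distances resolve to the lower training index
    nn <- order(dist2)[seq_len(k)]
    votes <- table(factor(d$y[nn], levels = classes))
    classes[which.max(votes)]
  }, character(1))
}

#' Classifier performance over a feature mask
#'
#' The performance contract consumed by the GA fitness: fits the requested
#' classifier(s) on `train` restricted to the masked features, predicts
#' `eval`, and returns the requested metric.  `classifier = "both"` returns
#' the unweighted mean of the naive Bayes and KNN metric values.
#'
#' @param train,eval Data frames of features plus a label column.
#' @param classifier One of `"nbc"`, `"knn"`, `"both"`.
#' @param metric One of `"gmean"`, `"accuracy"`, `"f1"`, `"mcc"`.
#' @param mask Feature mask as in [nbc_fit()].
#' @param knn_k Neighbour count for KNN (default 5).
#' @param scale Standardize features for KNN (default TRUE).
#' @param positive Positive class for binary metrics; default:
#'   lexicographically last symbol.
#' @param label Name of the label column; default: last column.
#' @return The metric value: in `[0, 1]`, or `[-1, 1]` for MCC.
#' @export
evaluate_performance <- function(train, eval, classifier = c("nbc", "knn", "both"),
                                 metric = c("gmean", "accuracy", "f1", "mcc"),
                                 mask = NULL, knn_k = 5, scale = TRUE,
                                 positive = NULL, label = NULL) {
  classifier <- match.arg(classifier)
  metric <- match.arg(metric)
  d <- fs_split(train, label)
  de <- fs_split(eval, label)
  if (!all(de$classes %in% d$classes)) {
    abort("Evaluation data contains classes absent from training data.")
  }
  one <- function(clf) {
    pred <- if (clf == "nbc") {
      nbc_predict(nbc_fit(train, mask, label), eval, label = label)
    } else {
      knn_predict(train, eval, k = knn_k, mask = mask, scale = scale,
                  label = label)
    }
    classification_metrics(de$y, pred, positive)[[metric]]
  }
  switch(classifier,
    nbc = one("nbc"),
    knn = one("knn"),
    both = (one("nbc") + one("knn")) / 2
  )
}
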