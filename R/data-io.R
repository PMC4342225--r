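# Tab-delimited sample-by-feature tables and stratified splitting.
#
# The on-disk dialect: one row per sample, one column per feature, the LAST
# column holding the class label.  A header row is optional and is detected
# when any non-last field of the first line fails numeric parsing.

# Canonicalise a data frame into the internal representation used by every
# downstream module: numeric feature matrix + character label vector.
# `label` names the label column; default is the last column.
fs_split <- function(data, label = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (samples in rows, features in columns).")
  }
  if (ncol(data) < 2) {
    abort("`data` needs at least one feature column and one label column.")
  }
  if (is.null(label)) {
    label <- names(data)[ncol(data)]
  }
  if (!label %in% names(data)) {
    abort(sprintf("Label column '%s' not found in `data`.", label))
  }
  y <- as.character(data[[label]])
  feat <- data[setdiff(names(data), label)]
  if (anyNA(feat) || anyNA(y)) {
    abort("Missing values are not supported.")
  }
  x <- as.matrix(as.data.frame(lapply(feat, as.numeric)))
  if (anyNA(x)) {
    abort("All feature columns must be numeric.")
  }
  colnames(x) <- names(feat)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    abort("At least two distinct class labels are required.")
  }
  if (nrow(x) < length(classes)) {
    abort("Fewer samples than classes.")
  }
  list(
    x = x, y = y, label = label,
    feature_names = colnames(x),
    n_features = ncol(x),
    classes = classes
  )
}

# Default positive class for binary metrics: lexicographically last symbol.
default_positive <- function(classes) sort(classes)[length(classes)]

#' Read a tab-delimited sample-by-feature table
#'
#' Reads the plain-text format used throughout the package: rows are data
#' samples, columns are features, and the last column holds the class label.
#' A header row is detected automatically (any non-last field of the first
#' line that does not parse as a number marks it as a header); otherwise
#' feature names `f1..fn` are generated and the label column is named
#' `class`.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator, default tab.
#' @return A tibble with numeric feature columns and a character label
#'   column (last).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("1.0\t2.0\tA", "2.0\t1.0\tB"), tf)
#' read_feature_table(tf)
#' @export
read_feature_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    abort(sprintf("File '%s' is empty.", path))
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  n_col <- length(fields[[1]])
  if (n_col < 2) {
    abort(sprintf("Line %d has %d field(s); at least 2 are required.",
                  line_no[1], n_col))
  }
  widths <- lengths(fields)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    abort(sprintf(
      "Ragged table: line %d has %d fields but line %d has %d.",
      line_no[bad], widths[bad], line_no[1], n_col
    ))
  }
  first <- fields[[1]]
  header_like <- anyNA(suppressWarnings(as.numeric(first[-n_col])))
  if (header_like) {
    col_names <- first
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0) {
      abort(sprintf("File '%s' has a header but no data rows.", path))
    }
  } else {
    col_names <- c(paste0("f", seq_len(n_col - 1)), "class")
  }
  mat <- do.call(rbind, fields)
  labels <- mat[, n_col]
  feat_chr <- mat[, -n_col, drop = FALSE]
  feat_num <- suppressWarnings(array(as.numeric(feat_chr), dim = dim(feat_chr)))
  if (anyNA(feat_num)) {
    bad <- which(is.na(feat_num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-numeric feature value '%s' at line %d, column %d.",
      feat_chr[bad[1], bad[2]], line_no[bad[1]], bad[2]
    ))
  }
  if (length(unique(labels)) < 2) {
    abort("Label column has a single distinct value; at least 2 classes are required.")
  }
  out <- as_tibble(as.data.frame(feat_num))
  names(out) <- col_names[-n_col]
  out[[col_names[n_col]]] <- labels
  out
}

#' Write a sample-by-feature table to tab-delimited text
#'
#' Inverse of [read_feature_table()]: writes a header row, then one line per
#' sample with the label in the last column.  Numeric values are written
#' with full precision (15 significant digits) so that reading the file back
#' reproduces the numeric content exactly for finite decimals.
#'
#' @param data Data frame of features plus a label column.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @param label Name of the label column; default: last column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, delimiter = "\t", label = NULL) {
  d <- fs_split(data, label)
  chr <- apply(d$x, 2, format, digits = 15, trim = TRUE, scientific = FALSE)
  chr <- matrix(as.character(chr), nrow = nrow(d$x))
  body <- apply(cbind(chr, d$y), 1, paste, collapse = delimiter)
  header <- paste(c(d$feature_names, d$label), collapse = delimiter)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Stratified k-fold assignment
#'
#' Assigns every sample to one of `k` folds such that, within every class,
#' fold sizes differ by at most one.  Deterministic for a fixed seed.
#'
#' @param data Data frame of features plus a label column.
#' @param k Number of folds (default 5, the standard cross-validation setup).
#' @param seed Integer seed controlling the shuffle.
#' @param label Name of the label column; default: last column.
#' @return A tibble with columns `sample` (row index) and `fold`
#'   (integer in `1..k`).
#' @export
stratified_kfold <- function(data, k = 5, seed = 1, label = NULL) {
  d <- fs_split(data, label)
  if (k < 2) abort("`k` must be at least 2.")
  counts <- table(d$y)
  if (any(counts < k)) {
    small <- names(counts)[counts < k][1]
    abort(sprintf(
      "Class '%s' has %d sample(s); stratified %d-fold needs at least %d.",
      small, counts[[small]], k, k
    ))
  }
  fold <- integer(length(d$y))
  with_seed(seed, {
    for (cl in d$classes) {
      idx <- which(d$y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  tibble(sample = seq_along(fold), fold = fold)
}

#' Stratified train/test split
#'
#' Splits samples into a training and a testing part, preserving class
#' proportions.  The union of the two parts is the input and they are
#' disjoint.
#'
#' @param data Data frame of features plus a label column.
#' @param test_fraction Proportion of samples assigned to the test side,
#'   strictly between 0 and 1.
#' @param seed Integer seed.
#' @param label Name of the label column; default: last column.
#' @return A list with tibbles `train` and `test`, each carrying an
#'   attribute `row_indices` giving the source row numbers.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1, label = NULL) {
  d <- fs_split(data, label)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in d$classes) {
      idx <- which(d$y == cl)
      n_test <- round(length(idx) * test_fraction)
      if (n_test < 1 || n_test >= length(idx)) {
        abort(sprintf(
          "test_fraction %.3g leaves class '%s' empty on one side.",
          test_fraction, cl
        ))
      }
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(data)), test_idx)
  train <- as_tibble(data[train_idx, , drop = FALSE])
  test <- as_tibble(data[test_idx, , drop = FALSE])
  attr(train, "row_indices") <- train_idx
  attr(test, "row_indices") <- test_idx
  list(train = train, test = test)
}
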