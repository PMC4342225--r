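# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (double loops over contingency tables, all-pairs distances) and never call
# the implementation paths they check.

write_tmp_table <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

# Two well-separated Gaussian classes; `sep` in within-class sd units.
make_separable_data <- function(n = 60, n_features = 3, sep = 8, seed = 1) {
  withr::with_seed(seed, {
    half <- n %/% 2
    y <- rep(c("neg", "pos"), c(half, n - half))
    x <- matrix(rnorm(n * n_features), n, n_features)
    x[y == "pos", ] <- x[y == "pos", ] + sep
    colnames(x) <- paste0("f", seq_len(n_features))
    out <- tibble::as_tibble(as.data.frame(x))
    out$class <- y
    out[sample(n), ]
  })
}

# Plug-in MI in bits by direct double loop over the joint table.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        out <- out + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  out
}

# CMI(x; y | z) as a z-weighted sum of per-stratum MI oracles.
cmi_oracle <- function(x, y, z) {
  out <- 0
  n <- length(z)
  for (zv in unique(z)) {
    sel <- z == zv
    out <- out + sum(sel) / n * mi_oracle(x[sel], y[sel])
  }
  out
}

# All-pairs KNN oracle with the same tie rules as the implementation:
# distance ties -> lower training index, vote ties -> first sorted class.
knn_oracle <- function(xtr, ytr, xte, k) {
  classes <- sort(unique(ytr))
  apply(xte, 1, function(p) {
    d <- sqrt(colSums((t(xtr) - p)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    counts <- sapply(classes, function(cl) sum(ytr[nn] == cl))
    classes[which.max(counts)]
  })
}

# Pairwise stability oracle straight from its definition.
stability_oracle <- function(a, b, n) {
  ki <- length(a); kj <- length(b); cc <- length(intersect(a, b))
  (cc - ki * kj / n) / (min(ki, kj) - max(0, ki + kj - n))
}

# Exact full-factorial XOR fixture: f1, f2, plus `n_noise_bits` noise bits,
# every combination once, label = XOR of f1 and f2.  All univariate MIs with
# the label are exactly zero by construction.
make_xor_factorial <- function(n_noise_bits = 3) {
  g <- expand.grid(rep(list(0:1), 2 + n_noise_bits))
  names(g) <- paste0("f", seq_len(ncol(g)))
  g$class <- ifelse(xor(g$f1 == 1, g$f2 == 1), "pos", "neg")
  tibble::as_tibble(g)
}
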