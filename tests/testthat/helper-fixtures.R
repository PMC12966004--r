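# Small builders and independent oracles shared across the suite.

tiny_pheno <- function() {
  tidyr::expand_grid(
    genotype = c("g1", "g2"),
    index = "CAT",
    condition = c("CK", "HS"),
    replicate = 1:2
  ) |>
    dplyr::mutate(value = c(10, 12, 5, 7, 20, 22, 18, 16))
}

injury_row <- function(genotype, counts) {
  if (all(counts == round(counts))) counts <- as.integer(counts)
  tibble::tibble(genotype = genotype,
                 class0 = counts[1], class1 = counts[2], class2 = counts[3],
                 class3 = counts[4], class4 = counts[5])
}

# random positive coefficient matrix with named rows/columns
random_cm <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(runif(n * p, 0.2, 1.6), n, p,
              dimnames = list(sprintf("g%d", 1:n), sprintf("idx%d", 1:p)))
  m
}

# eigen oracle: power iteration with deflation on a symmetric PSD matrix;
# independent of base eigen() and of the package's PCA path
eigen_oracle <- function(S, iters = 50000, tol = 1e-14) {
  p <- ncol(S)
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  A <- S
  for (k in seq_len(p)) {
    v <- seq_len(p) / sqrt(sum(seq_len(p)^2))  # fixed, non-degenerate start
    for (i in seq_len(iters)) {
      w <- A %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- as.vector(w) / nw
      if (sum((w - v)^2) < tol || sum((w + v)^2) < tol) { v <- w; break }
      v <- w
    }
    lam <- drop(t(v) %*% A %*% v)
    vals[k] <- lam
    vecs[, k] <- v
    A <- A - lam * tcrossprod(v)
  }
  ord <- order(-vals)
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
}

# exhaustive optimal 1-D partition into k contiguous groups (min within-SS);
# returns group id per element of x (1 = lowest values)
best_partition_1d <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cuts <- utils::combn(n - 1, k - 1)
  best_ss <- Inf
  best <- NULL
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    ss <- 0
    grp <- integer(n)
    for (g in seq_len(k)) {
      idx <- (b[g] + 1):b[g + 1]
      ss <- ss + sum((xs[idx] - mean(xs[idx]))^2)
      grp[idx] <- g
    }
    if (ss < best_ss - 1e-15) { best_ss <- ss; best <- grp }
  }
  out <- integer(n)
  out[ord] <- best
  out
}

# partition equality up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# R^2 by direct residual sums, independent of lm's summary
r_squared_oracle <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# best subset of exactly `size` columns by R^2
best_subset <- function(y, X, size) {
  combos <- utils::combn(ncol(X), size)
  r2 <- apply(combos, 2, function(ix) r_squared_oracle(y, X[, ix, drop = FALSE]))
  sort(colnames(X)[combos[, which.max(r2)]])
}
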