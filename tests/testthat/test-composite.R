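test_that("standardization yields exact z-scores and flags constant columns", {
  cm <- matrix(c(1, 2, 3, 0.8, 0.8, 0.8), 3, 2,
               dimnames = list(c("a", "b", "c"), c("ok", "flat")))
  expect_error(standardize_matrix(cm), "'flat'.*constant")

  z <- standardize_matrix(cm[, "ok", drop = FALSE])
  expect_equal(as.vector(z), c(-1, 0, 1))

  cm2 <- random_cm(8, 4, seed = 2)
  z2 <- standardize_matrix(cm2)
  expect_equal(colMeans(z2), setNames(rep(0, 4), colnames(cm2)), tolerance = 1e-12)
  expect_equal(apply(z2, 2, sd), setNames(rep(1, 4), colnames(cm2)),
               tolerance = 1e-12)
})

test_that("two-index PCA matches the closed form 1 +/- r", {
  for (seed in 1:20) {
    cm <- random_cm(7, 2, seed = 300 + seed)
    z <- standardize_matrix(cm)
    r <- cor(cm[, 1], cm[, 2])
    pca <- principal_components(z, analysis_config(n_components_override = 1))
    expect_equal(pca$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-10)
  }
})

test_that("uncorrelated columns give unit eigenvalues", {
  # orthogonal design: columns of a Helmert-like contrast are exactly uncorrelated
  x <- stats::contr.helmert(6)
  cm <- x + 2  # shift positive; correlation unchanged
  dimnames(cm) <- list(sprintf("g%d", 1:6), sprintf("idx%d", 1:5))
  z <- standardize_matrix(cm)
  pca <- principal_components(z, analysis_config(n_components_override = 1))
  expect_equal(pca$eigenvalues, rep(1, 5), tolerance = 1e-10)
})

test_that("eigendecomposition agrees with a power-iteration oracle", {
  for (p in c(3, 4)) {
    for (seed in 1:10) {
      cm <- random_cm(9, p, seed = 1000 * p + seed)
      z <- standardize_matrix(cm)
      S <- crossprod(z) / (nrow(z) - 1)
      oracle <- eigen_oracle(S)
      pca <- principal_components(z, analysis_config(n_components_override = p))
      expect_equal(pca$eigenvalues, oracle$values, tolerance = 1e-8)
      for (j in seq_len(p)) {
        # eigenvectors agree up to sign
        dot <- abs(sum(pca$loadings[, j] * oracle$vectors[, j]))
        expect_equal(dot, 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("eigenvalues sum to the number of indices and retention honors the threshold", {
  cm <- random_cm(10, 6, seed = 77)
  z <- standardize_matrix(cm)
  pca <- principal_components(z, analysis_config(variance_threshold = 0.8))
  expect_equal(sum(pca$eigenvalues), 6, tolerance = 1e-10)
  expect_gte(pca$cumulative_retained, 0.8)
  if (pca$n_retained > 1) {
    expect_lt(sum(pca$proportions[seq_len(pca$n_retained - 1)]), 0.8)
  }
  expect_error(principal_components(z, analysis_config(n_components_override = 7)),
               "rank")
})

test_that("retained components are oriented by the anchor index", {
  cm <- random_cm(10, 4, seed = 5)
  colnames(cm)[2] <- "Chl a"
  z <- standardize_matrix(cm)
  pca <- principal_components(z, analysis_config(n_components_override = 4))
  anchors <- pca$loadings["Chl a", ]
  largest <- apply(pca$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(anchors > 1e-10 | (abs(anchors) <= 1e-10 & largest > 0)))

  # without the anchor present, the largest-magnitude loading is positive
  cm2 <- random_cm(10, 4, seed = 6)
  pca2 <- principal_components(standardize_matrix(cm2),
                               analysis_config(n_components_override = 4))
  expect_true(all(apply(pca2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("membership values min-max normalize each component", {
  s <- matrix(c(2, 5, 8, -1, 1, 0), 3, 2)
  U <- membership_values(s)
  expect_equal(U[, 1], c(0, 0.5, 1))
  expect_equal(U[, 2], c(0, 1, 0.5))
  expect_error(membership_values(matrix(1, 3, 1)), "identical scores")

  # increasing affine transforms leave memberships unchanged
  expect_equal(membership_values(3.7 * s + 11), U)
})

test_that("weights normalize retained variance proportions", {
  expect_equal(component_weights(0.5), 1)
  # proportions as printed for a three-component retention
  w <- component_weights(c(0.54617, 0.17854, 0.11072))
  expect_equal(w, c(0.54617, 0.17854, 0.11072) / 0.83543, tolerance = 1e-12)
  # hand division frozen to 6 decimals
  expect_equal(w, c(0.653759, 0.213710, 0.132531), tolerance = 1e-6)
  set.seed(9)
  for (i in 1:20) {
    expect_equal(sum(component_weights(runif(sample(1:5, 1)))), 1,
                 tolerance = 1e-12)
  }
})

test_that("H is the weighted membership sum with attained bounds", {
  U <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 0, 1))
  rownames(U) <- c("top", "bottom", "mid")
  W <- c(0.5, 0.3, 0.2)
  sc <- tolerance_values(U, W)
  expect_equal(sc$H, c(1, 0, 0.7))
  expect_equal(tolerance_values(rbind(a = c(1, 0)), c(0.75, 0.25))$H, 0.75)
})

test_that("randomized score identities hold: weights, spans, bounds", {
  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    p <- sample(3:6, 1)
    cm <- matrix(runif(n * p, 0.1, 2), n, p,
                 dimnames = list(sprintf("g%d", 1:n), sprintf("i%d", 1:p)))
    cs <- composite_scores(cm, analysis_config())
    U <- as.matrix(cs$scores[grep("^U", names(cs$scores))])
    W <- attr(cs$scores, "weights")
    expect_equal(sum(W), 1, tolerance = 1e-12)
    expect_equal(unname(apply(U, 2, min)), rep(0, ncol(U)))
    expect_equal(unname(apply(U, 2, max)), rep(1, ncol(U)))
    expect_true(all(cs$scores$H >= -1e-12 & cs$scores$H <= 1 + 1e-12))
  }
})

test_that("every H is invariant to affine rescaling of any coefficient column", {
  cm <- random_cm(10, 5, seed = 31)
  base <- composite_scores(cm, analysis_config())$scores$H
  for (j in seq_len(ncol(cm))) {
    cm2 <- cm
    cm2[, j] <- 2.6 * cm2[, j] + 0.9
    h2 <- composite_scores(cm2, analysis_config())$scores$H
    expect_equal(h2, base, tolerance = 1e-10)
  }
})

test_that("scores scaling choice does not leak into H", {
  # eigenvalue-scaled scores give identical H because membership absorbs scale
  cm <- random_cm(9, 4, seed = 55)
  z <- standardize_matrix(cm)
  pca <- principal_components(z, analysis_config())
  W <- component_weights(pca)
  h_unit <- tolerance_values(membership_values(pca$scores), W)$H
  scaled <- sweep(pca$scores, 2, sqrt(pca$eigenvalues[seq_len(pca$n_retained)]), "*")
  h_scaled <- tolerance_values(membership_values(scaled), W)$H
  expect_equal(h_scaled, h_unit, tolerance = 1e-12)
})

test_that("rank-1 structure concentrates variance on PC1 and H tracks the latent order", {
  set.seed(8)
  theta <- runif(8)
  cm <- sapply(1:5, function(j) 0.2 + j * 0.15 * theta)
  dimnames(cm) <- list(sprintf("g%d", 1:8), sprintf("i%d", 1:5))
  cs <- composite_scores(cm, analysis_config())
  expect_equal(cs$pca$proportions[1], 1, tolerance = 1e-10)
  expect_equal(cs$pca$n_retained, 1)
  expect_equal(order(cs$scores$H), order(theta))
})
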