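#' Column-standardize a coefficient matrix
#'
#' Centers each index column and scales it to unit sample variance
#' (denominator n-1). This puts indices with wildly different native scales
#' (enzyme-activity ratios, length ratios) on an equal footing, so the PCA
#' that follows is a correlation-matrix PCA.
#'
#' @param cm Numeric coefficient matrix (genotypes x indices).
#' @return Matrix of the same shape with zero-mean, unit-variance columns.
#' @export
standardize_matrix <- function(cm) {
  stopifnot(is.matrix(cm), is.numeric(cm))
  if (nrow(cm) < 3) stop("need at least 3 genotypes to standardize", call. = FALSE)
  sds <- apply(cm, 2, sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate) > 0) {
    stop("index '", colnames(cm)[degenerate[1]],
         "' is constant across genotypes; cannot standardize", call. = FALSE)
  }
  scale(cm, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal components of the standardized coefficient matrix
#'
#' Eigendecomposition of the column correlation matrix. Components are
#' sorted by descending eigenvalue; the variance proportion of component i
#' is its eigenvalue over the number of indices. Retention keeps the
#' smallest m components whose cumulative proportion reaches
#' `config$variance_threshold`, unless `config$n_components_override` fixes
#' m directly. Each retained component is sign-oriented so that its loading
#' on `config$anchor_index` is non-negative (higher retention of the anchor
#' trait under stress reads as higher tolerance); when that loading is zero
#' within 1e-10 -- or the anchor is absent -- the largest-magnitude loading
#' is made positive instead. Genotype scores (comprehensive indices) are the
#' standardized matrix times the unit-norm retained eigenvectors.
#'
#' @param z Standardized matrix from [standardize_matrix()].
#' @param config A [analysis_config()] list.
#' @return A list of class `thermotol_pca`: `eigenvalues`, `proportions`,
#'   `loadings` (indices x retained components), `scores` (genotypes x
#'   retained components), `n_retained`, `cumulative_retained`.
#' @export
principal_components <- function(z, config = analysis_config()) {
  stopifnot(is.matrix(z), nrow(z) >= 2)
  p <- ncol(z)
  corr <- crossprod(z) / (nrow(z) - 1)
  eig <- eigen(corr, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  proportions <- values / sum(values)
  rank_ <- sum(values > 1e-10)

  if (!is.null(config$n_components_override)) {
    m <- config$n_components_override
    if (m > rank_) {
      stop(sprintf("requested %d components but matrix rank is %d", m, rank_),
           call. = FALSE)
    }
  } else {
    m <- which(cumsum(proportions) >= config$variance_threshold - 1e-12)[1]
    m <- min(m, rank_)
  }

  loadings <- eig$vectors[, seq_len(m), drop = FALSE]
  rownames(loadings) <- colnames(z)
  anchor <- match(config$anchor_index, colnames(z))
  for (j in seq_len(m)) {
    ref <- if (!is.na(anchor) && abs(loadings[anchor, j]) > 1e-10) {
      loadings[anchor, j]
    } else {
      loadings[which.max(abs(loadings[, j])), j]
    }
    if (ref < 0) loadings[, j] <- -loadings[, j]
  }
  colnames(loadings) <- paste0("PC", seq_len(m))
  scores <- z %*% loadings

  structure(list(
    eigenvalues = values,
    proportions = proportions,
    loadings = loadings,
    scores = scores,
    n_retained = m,
    cumulative_retained = sum(proportions[seq_len(m)])
  ), class = "thermotol_pca")
}

#' @export
print.thermotol_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d of %d components retained (%.3f%% of variance)\n",
              x$n_retained, length(x$eigenvalues), 100 * x$cumulative_retained))
  cat("Eigenvalues:", paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Membership-function values
#'
#' Min-max normalisation of each retained component's genotype scores:
#' \eqn{U_i = (X_i - X_{min}) / (X_{max} - X_{min})}, so every component's
#' scores span exactly \[0, 1\] across genotypes. Exact ties at the extremes
#' share the 0 or 1 value.
#'
#' @param scores Genotype x component score matrix.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
membership_values <- function(scores) {
  stopifnot(is.matrix(scores))
  rng <- apply(scores, 2, range)
  flat <- which(rng[2, ] - rng[1, ] <= 0)
  if (length(flat) > 0) {
    stop("component ", flat[1], " has identical scores for all genotypes; ",
         "membership function undefined", call. = FALSE)
  }
  sweep(sweep(scores, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
}

#' Variance-proportion weights of retained components
#'
#' \eqn{W_i = P_i / \sum P_i} over the retained components, where
#' \eqn{P_i} is component i's share of total variance. Weights are
#' non-negative and sum to 1.
#'
#' @param pca A `thermotol_pca` object, or a numeric vector of retained
#'   variance proportions.
#' @return Numeric weight vector summing to 1.
#' @export
component_weights <- function(pca) {
  p <- if (inherits(pca, "thermotol_pca")) {
    pca$proportions[seq_len(pca$n_retained)]
  } else {
    as.numeric(pca)
  }
  if (length(p) < 1 || any(p < 0)) {
    stop("need at least one non-negative retained proportion", call. = FALSE)
  }
  p / sum(p)
}

#' Composite heat-tolerance value H
#'
#' The weighted sum \eqn{H_g = \sum_i U_{gi} W_i} of membership values: a
#' single tolerance score per genotype in \[0, 1\]. A genotype attaining the
#' per-component maximum on every retained component scores exactly 1.
#'
#' @param U Membership matrix from [membership_values()].
#' @param W Weight vector from [component_weights()].
#' @return A tibble with `genotype`, one `U*` column per component, and `H`;
#'   the weight vector is attached as attribute `"weights"`.
#' @export
tolerance_values <- function(U, W) {
  stopifnot(is.matrix(U), length(W) == ncol(U))
  H <- as.vector(U %*% W)
  out <- tibble::as_tibble(U, .name_repair = ~ paste0("U", seq_along(.x)))
  out <- tibble::add_column(out,
    genotype = rownames(U) %||% as.character(seq_len(nrow(U))), .before = 1)
  out$H <- H
  attr(out, "weights") <- W
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full composite scoring in one call
#'
#' Runs standardization, PCA, membership normalisation and weighting on a
#' coefficient matrix.
#'
#' @param cm Coefficient matrix from [compute_coefficients()].
#' @param config A [analysis_config()] list.
#' @return A list with `pca` (`thermotol_pca`) and `scores` (the
#'   [tolerance_values()] tibble).
#' @export
composite_scores <- function(cm, config = analysis_config()) {
  z <- standardize_matrix(cm)
  pca <- principal_components(z, config)
  U <- membership_values(pca$scores)
  W <- component_weights(pca)
  list(pca = pca, scores = tolerance_values(U, W))
}
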