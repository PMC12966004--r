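#' Validate H against the injury index
#'
#' A sound composite tolerance score should anti-correlate with observed
#' seedling damage: genotypes with high H should have low heat injury index.
#' This computes the Pearson correlation between H and HII over shared
#' genotypes with the usual two-sided t-test, and flags whether the
#' direction is the expected negative one. A wrong direction is reported,
#' not raised: validation is advisory.
#'
#' @param H Named tolerance values, or the [tolerance_values()] tibble.
#' @param hii The [compute_hii()] tibble (or a named numeric vector).
#' @return A list of class `thermotol_validation`: `pearson_r`, `p_value`,
#'   `n`, `direction_ok`.
#' @export
correlate_with_injury <- function(H, hii) {
  if (is.data.frame(H)) H <- setNames(H$H, H$genotype)
  if (is.data.frame(hii)) hii <- setNames(hii$hii, hii$genotype)
  shared <- intersect(names(H), names(hii))
  if (length(shared) < 3) {
    stop("need at least 3 shared genotypes to correlate H with HII",
         call. = FALSE)
  }
  x <- H[shared]; y <- hii[shared]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in H or HII; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(list(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(shared),
    direction_ok = unname(ct$estimate) < 0
  ), class = "thermotol_validation")
}

#' @export
print.thermotol_validation <- function(x, ...) {
  cat(sprintf("H vs HII: Pearson r = %.3f (p = %.3g, n = %d)%s\n",
              x$pearson_r, x$p_value, x$n,
              if (x$direction_ok) "" else "  ** WARNING: correlation is not negative **"))
  invisible(x)
}

#' Classify genotypes into tolerance groups
#'
#' Agglomerative hierarchical clustering of the one-dimensional H values
#' (squared Euclidean distance, average linkage) cut into `n_groups`
#' clusters. Groups are labelled with Roman numerals ordered by descending
#' group-mean H, so Group I always holds the most tolerant genotypes. On
#' one-dimensional data average linkage yields contiguous groups: each group
#' is an interval of the sorted H values.
#'
#' @param H Named tolerance values, or the [tolerance_values()] tibble.
#' @param n_groups Number of groups (at most the number of genotypes).
#' @return A tibble with `genotype`, `H`, `H_rank` (1 = highest H) and
#'   `group`; the dendrogram merge heights are attached as attribute
#'   `"merge_heights"`.
#' @export
cluster_tolerance <- function(H, n_groups = 3L) {
  if (is.data.frame(H)) H <- setNames(H$H, H$genotype)
  if (is.null(names(H))) names(H) <- as.character(seq_along(H))
  if (n_groups > length(H)) {
    stop(sprintf("cannot form %d groups from %d genotypes", n_groups, length(H)),
         call. = FALSE)
  }
  hc <- hclust(dist(H)^2, method = "average")
  member <- cutree(hc, k = n_groups)
  mean_h <- tapply(H, member, mean)
  # relabel clusters I, II, ... by descending mean H
  ord <- order(-mean_h)
  roman <- as.character(utils::as.roman(seq_len(n_groups)))
  relabel <- setNames(roman, names(mean_h)[ord])

  out <- tibble::tibble(
    genotype = names(H),
    H = unname(H),
    H_rank = rank(-H, ties.method = "min"),
    group = factor(unname(relabel[as.character(member)]), levels = roman)
  )
  attr(out, "merge_heights") <- hc$height
  out
}
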