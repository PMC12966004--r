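#' Heat-resistance coefficient matrix
#'
#' Converts paired control/stress means into the dimensionless
#' heat-resistance coefficient \eqn{h = \bar{x}_{HS} / \bar{x}_{CK}} per
#' genotype and index. `h = 1` means the trait is unchanged by stress; values
#' below 1 indicate decline under heat, above 1 induction. The ratio is
#' stored on the unit scale (not x100): downstream scoring is affine
#' invariant so the choice does not affect H, but the fitted regression
#' coefficients live on this scale.
#'
#' @param agg Aggregated phenotype table from [aggregate_replicates()].
#' @param index_list Optional ordered character vector of indices to keep
#'   (columns, in this order). Default: all indices, data order.
#' @return A numeric matrix, genotypes as rows, indices as columns.
#' @export
compute_coefficients <- function(agg, index_list = NULL) {
  stopifnot(all(c("genotype", "index", "condition", "mean") %in% names(agg)))
  if (is.null(index_list)) {
    index_list <- unique(agg$index)
  } else {
    absent <- setdiff(index_list, unique(agg$index))
    if (length(absent) > 0) {
      stop("index not present in data: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  if (anyDuplicated(index_list)) stop("index_list has duplicates", call. = FALSE)
  agg <- agg[agg$index %in% index_list, ]
  genotypes <- unique(agg$genotype)

  wide <- tidyr::pivot_wider(agg[, c("genotype", "index", "condition", "mean")],
                             names_from = "condition", values_from = "mean")
  if (!all(c("CK", "HS") %in% names(wide)) || anyNA(wide$CK) || anyNA(wide$HS)) {
    bad <- if (!"CK" %in% names(wide)) wide[1, ] else wide[is.na(wide$CK) | is.na(wide$HS), ][1, ]
    stop(sprintf("incomplete CK/HS pair for genotype '%s', index '%s'",
                 bad$genotype, bad$index), call. = FALSE)
  }
  zero_ck <- wide[wide$CK <= 0, ]
  if (nrow(zero_ck) > 0) {
    stop(sprintf(
      "control mean is not positive for genotype '%s', index '%s'; ratio undefined",
      zero_ck$genotype[1], zero_ck$index[1]), call. = FALSE)
  }
  wide$h <- wide$HS / wide$CK
  m <- matrix(NA_real_, length(genotypes), length(index_list),
              dimnames = list(genotypes, index_list))
  m[cbind(match(wide$genotype, genotypes), match(wide$index, index_list))] <- wide$h
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("no measurements for genotype '%s', index '%s'",
                 genotypes[miss[1]], index_list[miss[2]]), call. = FALSE)
  }
  m
}

#' Write a coefficient matrix to CSV
#'
#' Genotypes as rows, one column per index, values rendered to six decimals.
#'
#' @param cm Coefficient matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(cm, path) {
  df <- tibble::as_tibble(round(cm, 6), rownames = "genotype")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a coefficient matrix from CSV
#'
#' @param path CSV written by [write_coefficients()] (first column
#'   `genotype`, remaining columns numeric h ratios).
#' @return Numeric matrix with genotype rownames.
#' @export
read_coefficients <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[-1])
  rownames(m) <- df$genotype
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("coefficient matrix must be finite and non-negative", call. = FALSE)
  }
  m
}
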