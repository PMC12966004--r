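#' Run the full heat-tolerance evaluation pipeline
#'
#' Composes every stage: replicate aggregation, heat-resistance
#' coefficients, standardization, correlation-matrix PCA, membership
#' normalisation, variance-proportion weighting into the composite value H,
#' validation against the injury index, stepwise index selection and
#' tolerance grouping. The injury table is optional; without it the
#' validation section is marked skipped and HII columns are absent.
#'
#' @param pheno A phenotype tibble or a path to a phenotype CSV.
#' @param injury Optional injury tibble or CSV path.
#' @param config A [analysis_config()] list.
#' @return A list of class `thermotol_report`: `config`, `genotypes` (tibble
#'   with h columns, comprehensive indices, memberships, H, HII, group,
#'   H_rank), `pca`, `model`, `validation` (or `"skipped"`), `version`.
#' @export
run_pipeline <- function(pheno, injury = NULL, config = analysis_config()) {
  if (is.character(pheno)) pheno <- read_pheno_table(pheno)
  if (is.character(injury)) injury <- read_injury_table(injury)

  agg <- aggregate_replicates(pheno)
  cm <- compute_coefficients(agg, config$index_list)
  cs <- composite_scores(cm, config)
  scores <- cs$scores
  model <- stepwise_select(scores, cm, config)
  groups <- cluster_tolerance(scores, config$n_groups)

  per_genotype <- tibble::as_tibble(cm, rownames = "genotype")
  ci <- tibble::as_tibble(cs$pca$scores,
                          .name_repair = ~ paste0("CI", seq_along(.x)))
  per_genotype <- dplyr::bind_cols(per_genotype, ci)
  per_genotype <- dplyr::left_join(per_genotype, scores, by = "genotype")
  per_genotype <- dplyr::left_join(
    per_genotype, groups[, c("genotype", "H_rank", "group")], by = "genotype")

  validation <- "skipped"
  if (!is.null(injury)) {
    hii <- compute_hii(injury)
    per_genotype <- dplyr::left_join(
      per_genotype, hii[, c("genotype", "hii")], by = "genotype")
    validation <- correlate_with_injury(scores, hii)
    if (!validation$direction_ok) {
      warning("H does not correlate negatively with the injury index; ",
              "check index orientation", call. = FALSE)
    }
  }

  structure(list(
    config = config,
    genotypes = per_genotype,
    pca = cs$pca,
    model = model,
    validation = validation,
    version = as.character(utils::packageVersion("thermotol"))
  ), class = "thermotol_report")
}

#' @export
print.thermotol_report <- function(x, ...) {
  print(x$pca)
  print(x$model)
  if (inherits(x$validation, "thermotol_validation")) print(x$validation)
  cat("\nPer-genotype summary (top of table):\n")
  print(head(x$genotypes[, intersect(
    c("genotype", "H", "H_rank", "group", "hii"), names(x$genotypes))], 10))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits the machine-readable report JSON plus per-genotype, loadings and
#' coefficient CSVs into `dir`. The JSON echoes the fully resolved
#' configuration so a run can be reproduced from its own output.
#'
#' @param report A `thermotol_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "thermotol_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$genotypes, file.path(dir, "genotypes.csv"))
  readr::write_csv(
    tibble::as_tibble(report$pca$loadings, rownames = "index"),
    file.path(dir, "loadings.csv"))
  readr::write_csv(tibble::tibble(
    component = seq_along(report$pca$eigenvalues),
    eigenvalue = report$pca$eigenvalues,
    proportion = report$pca$proportions
  ), file.path(dir, "eigenvalues.csv"))
  json <- list(
    schema = "thermotol-report/1",
    version = report$version,
    config = unclass(report$config),
    pca = list(
      eigenvalues = report$pca$eigenvalues,
      proportions = report$pca$proportions,
      n_retained = report$pca$n_retained,
      cumulative_retained = report$pca$cumulative_retained
    ),
    model = unclass(report$model),
    validation = if (inherits(report$validation, "thermotol_validation")) {
      unclass(report$validation)
    } else "skipped"
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
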