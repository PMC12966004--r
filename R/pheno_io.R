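#' @importFrom stats cor cor.test cutree dist hclust lm pf predict pt rnorm
#'   runif sd setNames
#' @importFrom utils head
#' @importFrom dplyr .data
NULL

CONDITIONS <- c("CK", "HS")

#' Validate a long-format phenotype table
#'
#' A phenotype table holds replicated seedling measurements in tidy long
#' format: one row per genotype x index x condition x replicate. `condition`
#' must be `"CK"` (control) or `"HS"` (heat stress); values must be finite,
#' non-negative numbers (every trait handled here -- pigment contents, enzyme
#' activities, lengths, rates -- is a non-negative quantity).
#'
#' @param df A data frame with columns `genotype`, `index`, `condition`,
#'   `replicate`, `value`.
#' @return The validated table as a tibble, row order preserved.
#' @export
validate_pheno <- function(df) {
  required <- c("genotype", "index", "condition", "replicate", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[required]
  bad_cond <- which(!df$condition %in% CONDITIONS)
  if (length(bad_cond) > 0) {
    stop(sprintf(
      "row %d: condition '%s' is not one of {CK, HS}",
      bad_cond[1], df$condition[bad_cond[1]]), call. = FALSE)
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(val <- as.numeric(df$value))
    bad <- which(is.na(val) & !is.na(df$value))
    if (length(bad) > 0) {
      stop(sprintf("row %d: non-numeric value '%s'", bad[1], df$value[bad[1]]),
           call. = FALSE)
    }
    df$value <- val
  }
  bad_val <- which(!is.finite(df$value))
  if (length(bad_val) > 0) {
    stop(sprintf("row %d: value is missing or non-finite", bad_val[1]),
         call. = FALSE)
  }
  neg <- which(df$value < 0)
  if (length(neg) > 0) {
    stop(sprintf("row %d: negative measurement (%g) for index '%s'",
                 neg[1], df$value[neg[1]], df$index[neg[1]]), call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate) | df$replicate < 1)) {
    stop("replicate ids must be positive integers", call. = FALSE)
  }
  key <- paste(df$genotype, df$index, df$condition, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    i <- dup[1]
    stop(sprintf(
      "duplicate measurement key: genotype '%s', index '%s', condition %s, replicate %d",
      df$genotype[i], df$index[i], df$condition[i], df$replicate[i]),
      call. = FALSE)
  }
  df
}

#' Read a phenotype CSV
#'
#' Expects a UTF-8 CSV with header
#' `genotype,index,condition,replicate,value`.
#'
#' @param path Path to the CSV file.
#' @return A validated phenotype tibble (see [validate_pheno()]).
#' @export
read_pheno_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(),
    index = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer(),
    value = readr::col_character()
  ))
  validate_pheno(df)
}

#' Write a phenotype table to CSV
#'
#' @param table A validated phenotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(table, path) {
  readr::write_csv(validate_pheno(table), path)
  invisible(path)
}

#' Convert a wide phenotype table to long format
#'
#' Convenience reader for spreadsheets laid out one column per index, with
#' `genotype`, `condition` and `replicate` identifier columns. Output is the
#' validated long format used everywhere else.
#'
#' @param df Wide-format data frame.
#' @return A validated long phenotype tibble.
#' @export
pheno_from_wide <- function(df) {
  ids <- c("genotype", "condition", "replicate")
  if (!all(ids %in% names(df))) {
    stop("wide table needs columns genotype, condition, replicate", call. = FALSE)
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(df), -dplyr::all_of(ids),
                              names_to = "index", values_to = "value")
  validate_pheno(long[, c("genotype", "index", "condition", "replicate", "value")])
}

#' Average replicate measurements
#'
#' Collapses a phenotype table to one cell per genotype x index x condition
#' (arithmetic mean over replicates). Averaging precedes the stress/control
#' ratio so that noisy control replicates do not enter the denominator
#' one-by-one. Every (genotype, index) pair must be observed under both
#' conditions: the downstream min-max normalisations are undefined on
#' partially observed genotypes, so missingness is a hard error.
#'
#' @param table A validated phenotype tibble.
#' @return A tibble with columns `genotype`, `index`, `condition`, `mean`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(table) {
  table <- validate_pheno(table)
  agg <- dplyr::summarise(
    dplyr::group_by(table, .data$genotype, .data$index, .data$condition),
    mean = mean(.data$value), n_replicates = dplyr::n(), .groups = "drop")
  pair_check <- dplyr::summarise(
    dplyr::group_by(agg, .data$genotype, .data$index),
    n_cond = dplyr::n_distinct(.data$condition), .groups = "drop")
  bad <- pair_check[pair_check$n_cond < 2L, ]
  if (nrow(bad) > 0) {
    stop(sprintf(
      "incomplete CK/HS pair: genotype '%s', index '%s' observed under only one condition",
      bad$genotype[1], bad$index[1]), call. = FALSE)
  }
  agg
}

#' Validate an injury-grade count table
#'
#' One row per genotype with counts of seedlings in damage classes 0-4
#' (columns `class0`..`class4`). Counts are non-negative integers and each
#' genotype must have at least one scored seedling.
#'
#' @param df Data frame with columns `genotype`, `class0`..`class4`.
#' @return Validated tibble.
#' @export
validate_injury <- function(df) {
  classes <- paste0("class", 0:4)
  required <- c("genotype", classes)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("injury table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[required]
  for (cl in classes) {
    v <- df[[cl]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("injury counts must be non-negative integers (column ", cl, ")",
           call. = FALSE)
    }
    df[[cl]] <- as.integer(v)
  }
  if (anyDuplicated(df$genotype)) {
    stop("duplicate genotype in injury table: ",
         df$genotype[duplicated(df$genotype)][1], call. = FALSE)
  }
  n <- rowSums(as.matrix(df[classes]))
  if (any(n < 1)) {
    stop("genotype '", df$genotype[which(n < 1)[1]],
         "' has zero scored seedlings", call. = FALSE)
  }
  df
}

#' Read an injury-grade CSV
#'
#' @param path CSV with header `genotype,class0,class1,class2,class3,class4`.
#' @return Validated injury tibble.
#' @export
read_injury_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_injury(readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(), .default = readr::col_double())))
}

#' Analysis configuration
#'
#' Bundles the tunable choices of the evaluation pipeline.
#'
#' @param index_list Optional character vector: the indices entering the PCA,
#'   in order. `NULL` means every index present in the data (data order).
#' @param anchor_index Index used to orient principal components: each
#'   retained component is flipped, if needed, so its loading on this index
#'   is non-negative. Default `"Chl a"`, the lead tolerance indicator
#'   (higher chlorophyll-a retention under stress = more tolerant).
#' @param variance_threshold Retain the smallest number of components whose
#'   cumulative variance proportion reaches this fraction. Default 0.80.
#' @param n_components_override Optional fixed component count, overriding
#'   the threshold rule.
#' @param alpha_enter Partial-F significance level to enter a predictor in
#'   stepwise regression. Default 0.05.
#' @param alpha_remove Level at or above which an entered predictor is
#'   removed. Default 0.10. Must exceed `alpha_enter`.
#' @param n_groups Number of tolerance groups for clustering. Default 3.
#' @param seed Non-negative integer seed for any randomised step.
#' @return A list of class `thermotol_config`.
#' @export
analysis_config <- function(index_list = NULL,
                            anchor_index = "Chl a",
                            variance_threshold = 0.80,
                            n_components_override = NULL,
                            alpha_enter = 0.05,
                            alpha_remove = 0.10,
                            n_groups = 3L,
                            seed = 0L) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1,
            alpha_enter > 0, alpha_remove < 1,
            n_groups >= 1, seed >= 0)
  if (!(alpha_enter < alpha_remove)) {
    stop("alpha_enter must be smaller than alpha_remove", call. = FALSE)
  }
  if (!is.null(n_components_override)) {
    stopifnot(n_components_override >= 1)
    n_components_override <- as.integer(n_components_override)
  }
  structure(list(
    index_list = index_list,
    anchor_index = anchor_index,
    variance_threshold = variance_threshold,
    n_components_override = n_components_override,
    alpha_enter = alpha_enter,
    alpha_remove = alpha_remove,
    n_groups = as.integer(n_groups),
    seed = as.integer(seed)
  ), class = "thermotol_config")
}

#' Read an analysis configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of
#'   [analysis_config()].
#' @return A `thermotol_config` list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, raw)
}
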