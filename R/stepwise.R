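#' Stepwise selection of a minimal predictive index equation
#'
#' Regresses the composite tolerance value H on the heat-resistance
#' coefficients and selects a small index subset by classical
#' forward-entry / backward-removal stepwise OLS: at each step the candidate
#' with the smallest partial-F p-value enters if it is at or below
#' `alpha_enter`; any entered predictor whose partial-F p-value reaches
#' `alpha_remove` is then removed; the loop runs to a fixed point. Entry and
#' removal thresholds default to 0.05 / 0.10, the conventional defaults of
#' classical stepwise packages. Steps that would leave one or fewer residual
#' degrees of freedom are refused, and candidates nearly collinear with the
#' current model (tolerance below 1e-8) are skipped. Ties on p-value break
#' by lexicographic index label, which makes the result independent of
#' candidate column order.
#'
#' @param H Numeric tolerance values named by genotype, or the tibble
#'   returned by [tolerance_values()].
#' @param cm Coefficient matrix (genotypes x candidate indices); rows are
#'   matched to `H` by genotype name.
#' @param config A [analysis_config()] list (supplies `alpha_enter`,
#'   `alpha_remove`).
#' @return A list of class `thermotol_model`: `selected_indices`,
#'   `coefficients` (named, h-ratio scale), `intercept`, `r_squared`,
#'   `f_statistic`, `p_value`, `n_obs`, `standardized_coefficients`,
#'   `empty_model` flag, `skipped_collinear` log.
#' @export
stepwise_select <- function(H, cm, config = analysis_config()) {
  if (is.data.frame(H)) {
    y <- setNames(H$H, H$genotype)
  } else {
    y <- H
  }
  stopifnot(is.matrix(cm))
  if (!is.null(names(y)) && !is.null(rownames(cm))) {
    if (!all(rownames(cm) %in% names(y))) {
      stop("H is missing genotypes present in the coefficient matrix",
           call. = FALSE)
    }
    y <- y[rownames(cm)]
  }
  n <- length(y)
  if (n < 4) stop("stepwise selection needs at least 4 observations", call. = FALSE)
  if (n != nrow(cm)) stop("H and coefficient matrix disagree on genotypes", call. = FALSE)

  labels <- colnames(cm)
  safe <- paste0("x", seq_along(labels))
  dat <- as.data.frame(cm)
  names(dat) <- safe
  dat$.y <- as.numeric(y)

  # summary.lm warns on exact fits; those are expected here and handled by
  # the perfect-fit entry guard
  quiet_summary <- function(fit) {
    withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }

  # partial-F p-value of each term in the fit of .y on `terms`
  term_pvals <- function(terms) {
    fit <- lm(stats::reformulate(terms, response = ".y"), data = dat)
    tab <- quiet_summary(fit)$coefficients
    pv <- tab[terms, 4]
    names(pv) <- terms
    pv
  }

  included <- character(0)  # safe names
  skipped <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break  # guards against pathological enter/remove cycles
    changed <- FALSE

    candidates <- setdiff(safe, included)
    # lexicographic order of the *labels* gives a deterministic tie-break
    candidates <- candidates[order(labels[match(candidates, safe)])]
    df_after_entry <- n - (length(included) + 1) - 1
    # once the fit is numerically exact the residuals are float noise, not
    # signal; further entries would be spurious
    perfect_fit <- length(included) > 0 &&
      quiet_summary(lm(stats::reformulate(included, response = ".y"),
                       data = dat))$r.squared >= 1 - 1e-12
    if (length(candidates) > 0 && df_after_entry >= 2 && !perfect_fit) {
      entry_p <- rep(NA_real_, length(candidates))
      for (i in seq_along(candidates)) {
        cand <- candidates[i]
        if (length(included) > 0) {
          aux <- lm(stats::reformulate(included, response = cand), data = dat)
          tol <- 1 - quiet_summary(aux)$r.squared
          if (!is.finite(tol) || tol < 1e-8) {
            skipped <- union(skipped, labels[match(cand, safe)])
            next
          }
        } else if (sd(dat[[cand]]) == 0) {
          skipped <- union(skipped, labels[match(cand, safe)])
          next
        }
        entry_p[i] <- term_pvals(c(included, cand))[cand]
      }
      if (any(is.finite(entry_p)) && min(entry_p, na.rm = TRUE) <= config$alpha_enter) {
        best <- candidates[which.min(entry_p)]
        included <- c(included, best)
        changed <- TRUE
      }
    }

    while (length(included) > 0) {
      pv <- term_pvals(included)
      # remove worst offender first; label order breaks exact ties
      ord <- order(-pv, labels[match(included, safe)])
      worst <- included[ord[1]]
      if (pv[worst] >= config$alpha_remove) {
        included <- setdiff(included, worst)
        changed <- TRUE
      } else break
    }

    if (!changed) break
  }

  sel_labels <- labels[match(included, safe)]
  if (length(included) == 0) {
    warning("no candidate index met the entry criterion; returning the empty model",
            call. = FALSE)
    return(structure(list(
      selected_indices = character(0),
      coefficients = numeric(0),
      intercept = mean(dat$.y),
      r_squared = 0, f_statistic = NA_real_, p_value = NA_real_,
      n_obs = n, standardized_coefficients = numeric(0),
      empty_model = TRUE, skipped_collinear = skipped
    ), class = "thermotol_model"))
  }

  fit <- lm(stats::reformulate(included, response = ".y"), data = dat)
  k <- length(included)
  r2 <- quiet_summary(fit)$r.squared
  fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  pval <- pf(fstat, k, n - k - 1, lower.tail = FALSE)
  coefs <- setNames(stats::coef(fit)[included], sel_labels)
  std <- coefs * vapply(included, function(s) sd(dat[[s]]), 0) / sd(dat$.y)

  structure(list(
    selected_indices = sel_labels,
    coefficients = coefs,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    f_statistic = fstat,
    p_value = pval,
    n_obs = n,
    standardized_coefficients = std,
    empty_model = FALSE,
    skipped_collinear = skipped
  ), class = "thermotol_model")
}

#' @export
print.thermotol_model <- function(x, ...) {
  if (x$empty_model) {
    cat("Stepwise model: empty (no index met the entry criterion)\n")
    return(invisible(x))
  }
  terms <- paste(sprintf("%.3f*%s", x$coefficients, x$selected_indices),
                 collapse = " + ")
  cat(sprintf("H = %s %+0.3f\n", terms, x$intercept))
  cat(sprintf("R^2 = %.3f, F = %.3f, p = %.3g, n = %d\n",
              x$r_squared, x$f_statistic, x$p_value, x$n_obs))
  invisible(x)
}

#' Predict tolerance values for new genotypes
#'
#' Applies a fitted index equation to new heat-resistance coefficients:
#' \eqn{\hat H = b_0 + \sum_j b_j h_j}. Predictions are reported unclipped --
#' a genotype outside the calibration range can score below 0 or above 1 --
#' with an `out_of_range` attribute flagging such values.
#'
#' @param model A `thermotol_model`.
#' @param new_coefficients A named numeric vector (one genotype), or a
#'   matrix / data frame with one column per selected index and one row per
#'   genotype.
#' @return Numeric predictions (named by genotype when row names exist),
#'   with logical attribute `out_of_range`.
#' @export
predict_h <- function(model, new_coefficients) {
  stopifnot(inherits(model, "thermotol_model"))
  if (is.numeric(new_coefficients) && !is.matrix(new_coefficients)) {
    new_coefficients <- matrix(new_coefficients, nrow = 1,
                               dimnames = list(NULL, names(new_coefficients)))
  }
  new_coefficients <- as.matrix(as.data.frame(new_coefficients))
  needed <- model$selected_indices
  absent <- setdiff(needed, colnames(new_coefficients))
  if (length(absent) > 0) {
    stop("new coefficients are missing selected index: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pred <- if (length(needed) == 0) {
    rep(model$intercept, nrow(new_coefficients))
  } else {
    model$intercept +
      as.vector(new_coefficients[, needed, drop = FALSE] %*% model$coefficients)
  }
  names(pred) <- rownames(new_coefficients)
  attr(pred, "out_of_range") <- pred < 0 | pred > 1
  pred
}

#' Serialize a fitted model to JSON
#'
#' @param model A `thermotol_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON written by [write_model()].
#' @return A `thermotol_model`.
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$selected_indices <- as.character(raw$selected_indices)
  raw$coefficients <- setNames(as.numeric(raw$coefficients),
                               raw$selected_indices)
  raw$standardized_coefficients <- setNames(
    as.numeric(raw$standardized_coefficients), raw$selected_indices)
  structure(raw, class = "thermotol_model")
}
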