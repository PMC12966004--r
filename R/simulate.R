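#' Default simulated index panel
#'
#' Six physiological/morphological indices: four "benefit" traits whose
#' stress/control ratio rises with tolerance (pigment retention, antioxidant
#' enzyme induction) and two "hazard" traits whose ratio falls with
#' tolerance (heat-forced hypocotyl elongation, membrane-damage marker).
#' Response is linear in the latent tolerance factor:
#' expected h = a + b * theta, kept positive over theta in \[0, 1\].
#'
#' @return A tibble with columns `label`, `control_mean`, `a`, `b`, `sign`.
#' @export
default_index_specs <- function() {
  tibble::tribble(
    ~label,             ~control_mean, ~a,   ~b,    ~sign,
    "Chl a",            1.8,           0.3,   0.7,  "benefit",
    "Chl b",            0.7,           0.3,   0.7,  "benefit",
    "CAT",              45,            0.3,   0.7,  "benefit",
    "SOD",              220,           0.3,   0.7,  "benefit",
    "Hypocotyl length", 4.5,           1.6,  -0.9,  "hazard",
    "MDA",              12,            1.6,  -0.9,  "hazard"
  )
}

#' Simulation configuration for a synthetic heat-tolerance trial
#'
#' Describes a simulated growth-chamber trial: `n_genotypes` genotypes, each
#' with a latent tolerance factor theta drawn Uniform(0, 1); `n_replicates`
#' replicate measurements per index under both control (CK) and heat stress
#' (HS); and `n_seedlings` seedlings scored into the five injury classes.
#' CK replicates are Normal around the control mean with coefficient of
#' variation `replicate_cv` (truncated at zero); HS replicates are Normal
#' around control_mean * (a + b*theta) with the same CV. Injury classes are
#' Binomial(4, p) per seedling with p = clamp(1 - theta + noise, 0, 1),
#' noise ~ Normal(0, `grade_noise_sd`) drawn once per genotype, so the
#' expected injury index is (1 - theta) * 100 when noise is off.
#'
#' @param n_genotypes Number of genotypes (default 10).
#' @param n_replicates Replicates per cell (default 3).
#' @param index_specs Index panel as in [default_index_specs()].
#' @param replicate_cv Replicate coefficient of variation (default 0.05).
#' @param n_seedlings Seedlings scored per genotype (default 30).
#' @param grade_noise_sd SD of the per-genotype noise on the injury
#'   probability (default 0.05).
#' @param seed Non-negative integer seed; identical seeds give byte-identical
#'   trials.
#' @return A list of class `thermotol_simconfig`.
#' @export
simulation_config <- function(n_genotypes = 10L,
                              n_replicates = 3L,
                              index_specs = default_index_specs(),
                              replicate_cv = 0.05,
                              n_seedlings = 30L,
                              grade_noise_sd = 0.05,
                              seed = 0L) {
  stopifnot(n_genotypes >= 1, n_replicates >= 1, n_seedlings >= 1,
            replicate_cv >= 0, grade_noise_sd >= 0, seed >= 0)
  index_specs <- tibble::as_tibble(index_specs)
  needed <- c("label", "control_mean", "a", "b")
  if (!all(needed %in% names(index_specs))) {
    stop("index_specs needs columns label, control_mean, a, b", call. = FALSE)
  }
  if (anyDuplicated(index_specs$label)) {
    stop("index labels must be unique", call. = FALSE)
  }
  # h(theta) = a + b*theta must stay positive on [0, 1] (endpoints suffice)
  bad <- index_specs$control_mean <= 0 | index_specs$a <= 0 |
    (index_specs$a + index_specs$b) <= 0
  if (any(bad)) {
    stop("index '", index_specs$label[which(bad)[1]],
         "': expected stress response a + b*theta must be positive on [0, 1]",
         call. = FALSE)
  }
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    index_specs = index_specs,
    replicate_cv = replicate_cv,
    n_seedlings = as.integer(n_seedlings),
    grade_noise_sd = grade_noise_sd,
    seed = as.integer(seed)
  ), class = "thermotol_simconfig")
}

# deterministic 31-bit child seed from (seed, label); keeps each index on its
# own substream so adding an index never perturbs another column's draws
child_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 1000003
  (seed * 1000003 + h) %% 2147483647
}

rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  pmax(rnorm(n, mean, sd), 0)
}

#' Generate a complete synthetic trial
#'
#' Draws latent tolerance factors, replicated CK/HS phenotype measurements
#' and five-grade injury counts from a seeded generator (see
#' [simulation_config()] for the generative model). Each index and the
#' injury scoring consume independent child streams keyed by the trial seed
#' and the index label, so the output is reproducible column-by-column.
#'
#' @param config A [simulation_config()] list.
#' @return A list with `pheno` (long phenotype tibble), `injury`
#'   (grade-count tibble) and `truth` (tibble of `genotype`, `theta`, plus
#'   one `h.<label>` column per index with the noise-free expected ratio).
#' @export
generate_trial <- function(config = simulation_config()) {
  stopifnot(inherits(config, "thermotol_simconfig"))
  g <- config$n_genotypes
  genotypes <- sprintf("G%02d", seq_len(g))

  set.seed(config$seed)
  theta <- runif(g)

  specs <- config$index_specs
  pheno <- vector("list", nrow(specs))
  truth_h <- matrix(NA_real_, g, nrow(specs),
                    dimnames = list(genotypes, specs$label))
  for (j in seq_len(nrow(specs))) {
    lab <- specs$label[j]
    mu <- specs$control_mean[j]
    h_true <- specs$a[j] + specs$b[j] * theta
    truth_h[, j] <- h_true
    set.seed(child_seed(config$seed, lab))
    rows <- vector("list", g)
    for (i in seq_len(g)) {
      ck <- rnorm_trunc0(config$n_replicates, mu, config$replicate_cv * mu)
      hs_mean <- mu * h_true[i]
      hs <- rnorm_trunc0(config$n_replicates, hs_mean,
                         config$replicate_cv * hs_mean)
      rows[[i]] <- tibble::tibble(
        genotype = genotypes[i],
        index = lab,
        condition = rep(c("CK", "HS"), each = config$n_replicates),
        replicate = rep(seq_len(config$n_replicates), 2),
        value = c(ck, hs)
      )
    }
    pheno[[j]] <- dplyr::bind_rows(rows)
  }
  pheno <- dplyr::bind_rows(pheno)

  set.seed(child_seed(config$seed, ".injury"))
  noise <- rnorm(g, 0, config$grade_noise_sd)
  p_injury <- pmin(pmax(1 - theta + noise, 0), 1)
  counts <- matrix(0L, g, 5, dimnames = list(genotypes, paste0("class", 0:4)))
  for (i in seq_len(g)) {
    cls <- stats::rbinom(config$n_seedlings, 4, p_injury[i])
    counts[i, ] <- tabulate(cls + 1L, nbins = 5L)
  }
  injury <- tibble::as_tibble(counts, rownames = "genotype")

  truth <- tibble::as_tibble(truth_h, rownames = "genotype")
  names(truth)[-1] <- paste0("h.", names(truth)[-1])
  truth <- tibble::add_column(truth, theta = theta, .after = "genotype")

  list(pheno = validate_pheno(pheno), injury = validate_injury(injury),
       truth = truth)
}

#' Rank agreement between latent tolerance and recovered H
#'
#' Spearman rank correlation between the simulator's ground-truth theta and
#' the pipeline's composite H. Equals 1 exactly when H recovers the
#' tolerance ranking perfectly (e.g. the noiseless pipeline, where every
#' coefficient column is an exact affine function of theta).
#'
#' @param truth The `truth` tibble from [generate_trial()].
#' @param scores Named H values, or the [tolerance_values()] tibble.
#' @return Spearman correlation in \[-1, 1\].
#' @export
recovery_statistic <- function(truth, scores) {
  if (is.data.frame(scores)) scores <- setNames(scores$H, scores$genotype)
  shared <- intersect(truth$genotype, names(scores))
  if (length(shared) < 3) {
    stop("need at least 3 shared genotypes for the recovery statistic",
         call. = FALSE)
  }
  theta <- truth$theta[match(shared, truth$genotype)]
  cor(theta, scores[shared], method = "spearman")
}
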