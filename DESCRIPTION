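Package: thermotol
Title: Composite Heat-Tolerance Evaluation for Seedling Phenotyping Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates long-term heat tolerance of plant genotypes from paired
    control/heat-stress seedling phenotype measurements and graded injury
    counts. Implements the heat injury index (HII) from five-grade damage
    counts, heat-resistance coefficients (stress/control trait ratios),
    correlation-matrix principal component analysis with membership-function
    (min-max) normalisation and variance-proportion weights yielding a
    composite tolerance value H per genotype, stepwise regression to distil
    H into a minimal predictive index equation, validation of H against the
    injury index, and hierarchical tolerance grouping. Includes a seeded
    synthetic trial generator with a latent tolerance factor so the whole
    pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    ggplot2
Config/testthat/edition: 3
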