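#' Heat injury index from graded damage counts
#'
#' Seedlings are scored into five damage classes after prolonged heat stress:
#' class 0 (no symptoms) through class 4 (more than half of the cotyledon and
#' true-leaf area dehydrated/yellowing). The heat injury index summarises a
#' genotype's counts \eqn{N_0..N_4} as
#' \deqn{HII = \frac{\sum_i i \, N_i}{4N} \times 100,}
#' a percentage: 0 when every seedling is undamaged, 100 when every seedling
#' is in the worst class. Moving one seedling up one class raises HII by
#' exactly \eqn{100/(4N)}, and scaling all counts by a common factor leaves
#' it unchanged.
#'
#' @param grades An injury-grade table (see [validate_injury()]).
#' @return A tibble with columns `genotype`, `n_seedlings`, `hii`.
#' @examples
#' g <- tibble::tibble(genotype = c("a", "b"),
#'                     class0 = c(10L, 0L), class1 = c(0L, 0L),
#'                     class2 = c(0L, 0L), class3 = c(0L, 0L),
#'                     class4 = c(0L, 10L))
#' compute_hii(g)  # hii 0 and 100
#' @export
compute_hii <- function(grades) {
  grades <- validate_injury(grades)
  counts <- as.matrix(grades[paste0("class", 0:4)])
  n <- rowSums(counts)
  weighted <- as.vector(counts %*% (0:4))
  tibble::tibble(
    genotype = grades$genotype,
    n_seedlings = as.integer(n),
    hii = weighted / (4 * n) * 100
  )
}
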