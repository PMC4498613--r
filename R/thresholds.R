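#' Effective number of independent tests in a genome scan
#'
#' The number of effectively independent tests of a one-dimensional scan is
#' proportional to the genome length; at 10 cM marker density the
#' coefficient is 0.072 tests per cM for a genome-wide error of 0.05 and
#' 0.084 for 0.01.  For RIL populations the genome length is first expanded
#' by 1.9 to account for the accumulated recombination.  The value is kept
#' un-rounded.
#'
#' @param genome_length genome length in cM (sum over chromosomes).
#' @param alpha_g genome-wide type-I error (0.05 or 0.01 for the built-in
#'   coefficients).
#' @param population population kind (`"F2"` allowed here).
#' @param meff_coef optional user coefficient (tests per cM) overriding the
#'   built-in 10 cM-density values.
#' @return real-valued effective test count `M_eff`.
#' @export
#' @examples
#' effective_tests(1000)           # 72
#' effective_tests(1000, population = "RIL")  # 136.8
effective_tests <- function(genome_length, alpha_g = 0.05,
                            population = "DH", meff_coef = NULL) {
  if (!is.finite(genome_length) || genome_length <= 0)
    stop("genome length must be positive")
  if (is.null(meff_coef)) {
    meff_coef <- if (isTRUE(all.equal(alpha_g, 0.05))) 0.072
    else if (isTRUE(all.equal(alpha_g, 0.01))) 0.084
    else stop("built-in coefficients exist only for alpha_g 0.05/0.01; ",
              "supply meff_coef for other levels or marker densities")
  }
  meff_coef * genome_length * genome_expansion(population)
}

# chi-square degrees of freedom of the scan statistic
threshold_df <- function(population, e,
                         scope = c("overall", "average_effect",
                                   "interaction")) {
  scope <- match.arg(scope)
  population <- match_population(population, allow_f2 = TRUE)
  per <- if (population == "F2") 2L else 1L
  switch(scope,
         overall = per * e,
         average_effect = per,
         interaction = per * (e - 1L))
}

#' Empirical genome-wide LOD threshold
#'
#' Bonferroni-corrects the genome-wide error over the effective test count,
#' `alpha_p = alpha_g / M_eff`, and converts the chi-square critical value
#' to the LOD scale: `LOD = qchisq(1 - alpha_p, df) / (2 ln 10)`.  The
#' degrees of freedom are the number of genetic parameters tested: `e` per
#' scan position for DH/BC1/RIL (`2e` for F2) for the overall test, 1 (2)
#' for the average effect and `e - 1` (`2(e-1)`) for the interaction
#' effects.
#'
#' @inheritParams effective_tests
#' @param e number of environments.
#' @param scope which statistic the threshold is for: `"overall"` (LOD),
#'   `"average_effect"` (LOD_A) or `"interaction"` (LOD_AE).
#' @param df optional explicit degrees of freedom overriding the rule.
#' @return LOD threshold (numeric scalar).
#' @export
#' @examples
#' lod_threshold(900, e = 2)             # 3.11 for the simulation genome
#' lod_threshold(1000, e = 4)            # 4.19
#' lod_threshold(1000, e = 4, population = "F2")  # 5.87
lod_threshold <- function(genome_length, alpha_g = 0.05, population = "DH",
                          e = 2, scope = "overall", meff_coef = NULL,
                          df = NULL) {
  if (!is.finite(alpha_g) || alpha_g <= 0 || alpha_g >= 1)
    stop("alpha_g must lie in (0, 1)")
  meff <- effective_tests(genome_length, alpha_g, population, meff_coef)
  alpha_p <- alpha_g / meff
  if (is.null(df)) df <- threshold_df(population, e, scope)
  stats::qchisq(alpha_p, df = df, lower.tail = FALSE) / (2 * log(10))
}

#' Permutation-test genome-wide LOD threshold
#'
#' Permutes whole phenotype rows (keeping each individual's environment
#' vector together) against the genotype rows, reruns the full pipeline
#' (stepwise selection plus scan) on every permuted dataset and returns the
#' `(1 - alpha_g)` percentile of the genome-wide maximum LOD.
#'
#' @inheritParams qei_scan
#' @param n_perm number of permutations (>= 100 recommended).
#' @param alpha_g genome-wide type-I error.
#' @param seed integer seed for the permutation stream.
#' @param statistic which profile column to maximize (default `"LOD"`).
#' @return the threshold, with the vector of per-permutation maxima in
#'   attribute `"max_lod"`.
#' @export
permutation_threshold <- function(genotypes, phenotypes, map = NULL,
                                  population = "DH", n_perm = 200,
                                  alpha_g = 0.05, seed = 1L, step = 1,
                                  p_in = 0.001, p_out = 0.002,
                                  statistic = "LOD") {
  if (n_perm < 100)
    warning("fewer than 100 permutations: percentile estimate is coarse")
  if (n_perm * alpha_g < 1)
    warning("n_perm too small for the requested percentile")
  phenotypes <- as.matrix(phenotypes)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(b) {
    yp <- phenotypes[sample.int(nrow(phenotypes)), , drop = FALSE]
    prof <- qei_scan(genotypes, yp, map, population,
                     step = step, p_in = p_in, p_out = p_out)
    max(prof[[statistic]])
  }, numeric(1))
  thr <- unname(stats::quantile(maxima, 1 - alpha_g, type = 7))
  attr(thr, "max_lod") <- maxima
  thr
}
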