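#' Standard simulation genome
#'
#' The benchmark genome used throughout the simulation studies: six
#' chromosomes, each 150 cM long with 16 evenly spaced markers (10 cM
#' density, 900 cM total).
#'
#' @param n_chr number of chromosomes.
#' @param chr_length chromosome length in cM.
#' @param n_markers markers per chromosome (evenly spaced from 0 to
#'   `chr_length`).
#' @return a [genetic_map()].
#' @export
standard_map <- function(n_chr = 6, chr_length = 150, n_markers = 16) {
  pos <- seq(0, chr_length, length.out = n_markers)
  genetic_map(
    marker = paste0("M", rep(seq_len(n_chr), each = n_markers), "_",
                    rep(seq_len(n_markers), n_chr)),
    chromosome = rep(as.character(seq_len(n_chr)), each = n_markers),
    position_cM = rep(pos, n_chr))
}

#' Benchmark unlinked five-QTL architecture
#'
#' Five QTL on chromosomes 1-5 at 16, 3, 33, 26 and 35 cM covering three
#' interaction levels in two environments: no interaction (Q1, Q5 with
#' average effect 0.5), strong crossover interaction (Q2, effects +0.5/-0.5)
#' and environment-specific effects (Q3, Q4 with average 0.25 and
#' interaction +/-0.25).
#'
#' @return a [qtl_architecture()] with 2 environments.
#' @export
arch_unlinked <- function() {
  # per-environment additive effects a_h = average + interaction
  eff <- rbind(c(0.5, 0.5),    # Q1: A = 0.5,  AE = ( 0,  0)
               c(0.5, -0.5),   # Q2: A = 0,    AE = (+0.5, -0.5)
               c(0.0, 0.5),    # Q3: A = 0.25, AE = (-0.25, +0.25)
               c(0.5, 0.0),    # Q4: A = 0.25, AE = (+0.25, -0.25)
               c(0.5, 0.5))    # Q5: A = 0.5,  AE = ( 0,  0)
  qtl_architecture(chromosome = as.character(1:5),
                   position_cM = c(16, 3, 33, 26, 35),
                   effects = eff)
}

#' Benchmark linked two-QTL architectures
#'
#' Eight effect scenarios (`"L1"` to `"L8"`) for two QTL at 25 and 55 cM on
#' chromosome 1, covering different interaction levels and linkage phases
#' (coupling/repulsion) in two environments.
#'
#' @param model one of `"L1"` .. `"L8"`.
#' @return a [qtl_architecture()] with 2 environments.
#' @export
arch_linked <- function(model = c("L1", "L2", "L3", "L4",
                                  "L5", "L6", "L7", "L8")) {
  model <- match.arg(model)
  # rows: Q1, Q2; columns: effect in E1, effect in E2
  eff <- switch(model,
    L1 = rbind(c(0.5, -0.5), c(0.5, 0.0)),
    L2 = rbind(c(0.5, -0.5), c(0.5, 0.5)),
    L3 = rbind(c(0.5, -0.5), c(0.5, -0.5)),
    L4 = rbind(c(0.5, 0.0),  c(0.5, 0.5)),
    L5 = rbind(c(0.5, 0.0),  c(0.5, 0.0)),
    L6 = rbind(c(0.5, 0.5),  c(0.5, 0.5)),
    L7 = rbind(c(0.5, -0.5), c(-0.5, 0.5)),
    L8 = rbind(c(0.5, -0.5), c(0.0, 0.5)))
  qtl_architecture(chromosome = c("1", "1"), position_cM = c(25, 55),
                   effects = eff)
}
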