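#' Mapping functions and population types
#'
#' Recombination arithmetic for biparental mapping populations under the
#' Haldane (no-interference) mapping function, including the accumulated
#' recombination fraction of recombinant inbred lines (RIL) obtained by
#' repeated selfing.
#'
#' @name mapping-functions
NULL

.POP_KINDS <- c("DH", "BC1", "RIL")

#' Validate a population type
#'
#' Doubled haploid (DH), first backcross (BC1) and selfed recombinant inbred
#' line (RIL) populations all carry two genotype classes per locus and one
#' genetic degree of freedom per environment in the interaction scan.  F2 is
#' accepted only where the degrees-of-freedom rule of the threshold
#' calculator needs it.
#'
#' @param population character scalar, one of `"DH"`, `"BC1"`, `"RIL"`
#'   (and `"F2"` when `allow_f2 = TRUE`).
#' @param allow_f2 logical; permit `"F2"` (threshold calculator only).
#' @return the matched population string.
#' @export
match_population <- function(population, allow_f2 = FALSE) {
  kinds <- if (allow_f2) c(.POP_KINDS, "F2") else .POP_KINDS
  match.arg(toupper(population), kinds)
}

#' Genome-length expansion factor for threshold calculation
#'
#' The accumulated recombination of a RIL population inflates map distances
#' by roughly 1.9 at usual marker densities, so the genome length entering
#' the effective-test count is multiplied by 1.9 for RILs and left unchanged
#' for DH/BC1 (and F2).
#'
#' @param population population kind (see [match_population()]).
#' @return numeric expansion factor (1 or 1.9).
#' @export
genome_expansion <- function(population) {
  population <- match_population(population, allow_f2 = TRUE)
  if (population == "RIL") 1.9 else 1.0
}

#' Haldane map distance to recombination fraction
#'
#' @param d map distance in centiMorgans (cM), `d >= 0`.
#' @return recombination fraction `r = (1 - exp(-2 d / 100)) / 2` in `[0, 0.5)`.
#' @seealso [inverse_haldane()], [ril_accumulated_R()]
#' @export
#' @examples
#' haldane_r(10)   # 0.0906
haldane_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("map distance must be finite and non-negative (got ",
         paste(format(d[!is.finite(d) | d < 0]), collapse = ", "), ")")
  (1 - exp(-2 * d / 100)) / 2
}

#' Recombination fraction to Haldane map distance
#'
#' @param r recombination fraction in `[0, 0.5)`.
#' @return map distance in cM, `d = -50 log(1 - 2 r)`.
#' @export
inverse_haldane <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Accumulated recombination fraction in RILs
#'
#' Repeated selfing accumulates recombination between two loci: the
#' population-level fraction observed in a RIL is `R = 2 r / (1 + 2 r)`,
#' where `r` is the one-meiosis fraction.
#'
#' @param r one-meiosis recombination fraction in `[0, 0.5]`.
#' @return accumulated fraction `R`, with `R >= r` and fixed point at 0.5.
#' @export
ril_accumulated_R <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("recombination fraction must lie in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Effective recombination fraction for a population
#'
#' Maps a distance to the recombination fraction actually observed between
#' loci in the given population: the one-meiosis Haldane fraction for DH and
#' BC1, the accumulated fraction for RIL.
#'
#' @param d map distance in cM.
#' @param population population kind.
#' @return recombination fraction.
#' @export
pop_recomb <- function(d, population) {
  population <- match_population(population)
  r <- haldane_r(d)
  if (population == "RIL") ril_accumulated_R(r) else r
}

#' Construct a genetic map
#'
#' @param marker character vector of genome-wide unique marker names.
#' @param chromosome chromosome identifier per marker; chromosomes keep their
#'   order of first appearance.
#' @param position_cM numeric positions in cM, strictly increasing within
#'   each chromosome.
#' @return an object of class `genetic_map`: a data.frame with columns
#'   `marker`, `chromosome`, `position_cM`, rows ordered by chromosome then
#'   position.
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  if (length(marker) != length(chromosome) ||
      length(marker) != length(position_cM))
    stop("marker, chromosome and position_cM must have equal length")
  if (anyDuplicated(marker))
    stop("duplicated marker name(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(!is.finite(position_cM)) || any(position_cM < 0))
    stop("positions must be finite and >= 0 cM")
  chr_levels <- unique(chromosome)
  ord <- order(match(chromosome, chr_levels), position_cM)
  map <- data.frame(marker = marker[ord],
                    chromosome = factor(chromosome[ord], levels = chr_levels),
                    position_cM = position_cM[ord],
                    stringsAsFactors = FALSE)
  for (ch in chr_levels) {
    pos <- map$position_cM[map$chromosome == ch]
    if (any(diff(pos) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  nchr <- nlevels(x$chromosome)
  cat("Genetic map:", nrow(x), "markers on", nchr, "chromosome(s),",
      format(genome_length(x), digits = 6), "cM total\n")
  invisible(x)
}

#' Total genome length of a map
#'
#' Sum over chromosomes of (last - first marker position).
#'
#' @param map a [genetic_map()].
#' @return length in cM.
#' @export
genome_length <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  sum(tapply(map$position_cM, map$chromosome, function(p) max(p) - min(p)))
}

#' Split a map into per-chromosome components
#'
#' @param map a [genetic_map()].
#' @return named list (one per chromosome) of data.frames with columns
#'   `marker`, `position_cM`.
#' @keywords internal
map_by_chromosome <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  out <- split(map[c("marker", "position_cM")], map$chromosome)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
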