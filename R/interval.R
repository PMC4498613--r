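#' Conditional QTL-genotype probabilities in a marker interval
#'
#' For a putative QTL at a testing position inside a marker interval, the
#' individuals of a two-genotype population fall into four groups by the
#' phase of the two flanking markers (P1/P1, P1/P2, P2/P1, P2/P2).  Within
#' each group the two QTL genotypes occur with probabilities `pi[l, k]`
#' determined by the recombination fractions between the QTL and the
#' flanking markers.  The flanking-pair fraction is composed from the two
#' sub-interval fractions by the no-interference identity
#' `r = r1 + r2 - 2 r1 r2`, so the three fractions are always internally
#' consistent at every scan position.
#'
#' For RILs each gamete-level fraction is first mapped through the
#' accumulated-recombination transform `R = 2 r / (1 + 2 r)` and the same
#' group-probability formulas are applied to the accumulated fractions.
#'
#' When the testing position coincides with a marker (`d_left = 0` or
#' `d_right = 0`), membership collapses to the indicator of that marker's
#' genotype; recombinant flanking pairs, impossible at `r = 0`, inherit the
#' QTL genotype of the coincident marker.
#'
#' @param d_left distance (cM) from the left flanking marker to the QTL.
#' @param d_right distance (cM) from the QTL to the right flanking marker.
#' @param population population kind (`"DH"`, `"BC1"` or `"RIL"`).
#' @return a list of class `interval_probabilities` with elements `r1`,
#'   `r2`, `r` (recombination fractions actually used), `pi` (4 x 2 matrix,
#'   rows = flanking groups P1/P1, P1/P2, P2/P1, P2/P2; columns = QTL
#'   genotypes QQ, qq; each row sums to 1) and `lambda`, `rho` (coefficients
#'   of the conditional expectation `E(g | x_left, x_right) =
#'   lambda * x_left + rho * x_right`).
#' @export
#' @examples
#' ip <- interval_probabilities(5, 5, "DH")
#' ip$pi[1, 1]  # 0.99751: non-recombinant flanking pair, QQ
interval_probabilities <- function(d_left, d_right, population = "DH") {
  population <- match_population(population)
  if (d_left < 0 || d_right < 0)
    stop("testing position lies outside the interval (negative flanking distance)")
  r1 <- pop_recomb(d_left, population)
  r2 <- pop_recomb(d_right, population)
  r <- r1 + r2 - 2 * r1 * r2
  pi <- pi_from_r(r1, r2, r)
  # E(g | group l) = pi[l,1] - pi[l,2]; solve for lambda, rho from groups 1, 2
  e1 <- pi[1, 1] - pi[1, 2]
  e2 <- pi[2, 1] - pi[2, 2]
  structure(list(r1 = r1, r2 = r2, r = r,
                 pi = pi,
                 lambda = (e1 + e2) / 2, rho = (e1 - e2) / 2,
                 population = population),
            class = "interval_probabilities")
}

# 4 x 2 group-conditional QTL genotype probabilities from the three
# recombination fractions.  Degenerate fractions (0) are handled by the
# coincident-marker rule.
pi_from_r <- function(r1, r2, r) {
  if (r <= 0) {
    # QTL coincides with both flanking markers (zero-length interval)
    p11 <- 1; p21 <- 1; p31 <- 0
  } else {
    if (r1 == 0) {
      p11 <- 1; p21 <- 1; p31 <- 0            # QTL on the left marker
    } else if (r2 == 0) {
      p11 <- 1; p21 <- 0; p31 <- 1            # QTL on the right marker
    } else {
      p11 <- (1 - r1) * (1 - r2) / (1 - r)
      p21 <- (1 - r1) * r2 / r
      p31 <- r1 * (1 - r2) / r
    }
  }
  pi <- rbind(c(p11, 1 - p11),
              c(p21, 1 - p21),
              c(p31, 1 - p31),
              c(1 - p11, p11))
  dimnames(pi) <- list(c("P1/P1", "P1/P2", "P2/P1", "P2/P2"), c("QQ", "qq"))
  pi
}

#' Per-individual QTL-genotype priors at a testing position
#'
#' Computes, for every individual, the prior probability of the QQ genotype
#' at a testing position given that individual's nearest informative flanking
#' markers.  Individuals with complete flanking genotypes use the interval's
#' own markers; individuals with missing flanking genotypes fall back to the
#' nearest non-missing markers on the same chromosome (with the composed
#' no-interference fraction over the larger bracket); individuals informative
#' on one side only use the single-marker conditional `(1 - r)` vs `r`;
#' individuals with no informative marker on the chromosome get `NA` and are
#' excluded from the interval's likelihood.
#'
#' @param geno_chr n x m genotype matrix (codes +1/-1/NA) for one
#'   chromosome, columns in map order.
#' @param pos_chr marker positions (cM) for the chromosome.
#' @param k index of the interval's left marker.
#' @param scan_pos testing position in cM (within the interval).
#' @param population population kind.
#' @return numeric vector of length n: `P(QQ)` per individual (NA = drop).
#' @keywords internal
individual_pi1 <- function(geno_chr, pos_chr, k, scan_pos, population) {
  n <- nrow(geno_chr)
  m <- ncol(geno_chr)
  xl <- geno_chr[, k]
  xr <- geno_chr[, k + 1L]
  pi1 <- numeric(n)

  complete <- !is.na(xl) & !is.na(xr)
  if (any(complete)) {
    ip <- interval_probabilities(scan_pos - pos_chr[k],
                                 pos_chr[k + 1L] - scan_pos, population)
    grp <- ifelse(xl[complete] > 0,
                  ifelse(xr[complete] > 0, 1L, 2L),
                  ifelse(xr[complete] > 0, 3L, 4L))
    pi1[complete] <- ip$pi[grp, 1L]
  }

  for (i in which(!complete)) {
    li <- max(which(!is.na(geno_chr[i, seq_len(k)])), -Inf)
    right_ok <- which(!is.na(geno_chr[i, (k + 1L):m])) + k
    ri <- if (length(right_ok)) right_ok[1L] else Inf
    if (is.finite(li) && is.finite(ri)) {
      ip <- interval_probabilities(scan_pos - pos_chr[li],
                                   pos_chr[ri] - scan_pos, population)
      grp <- if (geno_chr[i, li] > 0) {
        if (geno_chr[i, ri] > 0) 1L else 2L
      } else {
        if (geno_chr[i, ri] > 0) 3L else 4L
      }
      pi1[i] <- ip$pi[grp, 1L]
    } else if (is.finite(li)) {
      r <- pop_recomb(scan_pos - pos_chr[li], population)
      pi1[i] <- if (geno_chr[i, li] > 0) 1 - r else r
    } else if (is.finite(ri)) {
      r <- pop_recomb(pos_chr[ri] - scan_pos, population)
      pi1[i] <- if (geno_chr[i, ri] > 0) 1 - r else r
    } else {
      pi1[i] <- NA_real_
    }
  }
  pi1
}
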