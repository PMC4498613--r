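#' QTL architecture for simulation and closed-form variance
#'
#' Specifies the true QTL of a simulated trait: map location and additive
#' effect in each environment.  The average effect of QTL `j` is
#' `abar_j = mean_h(a_jh)` and its interaction (QEI) effect in environment
#' `h` is `ae_jh = a_jh - abar_j`, so the interaction effects of each QTL
#' sum to zero over environments by construction.
#'
#' @param chromosome chromosome identifier per QTL.
#' @param position_cM QTL position in cM per QTL.
#' @param effects numeric matrix, one row per QTL, one column per
#'   environment: additive effect `a_jh` (half the difference between the
#'   two genotypic values) in trait units.
#' @return object of class `qtl_architecture`: list with `chromosome`,
#'   `position_cM`, `effects`, `avg` (per-QTL average effect) and `qei`
#'   (per-QTL-by-environment interaction effects).
#' @export
qtl_architecture <- function(chromosome, position_cM, effects) {
  effects <- rbind(effects)
  storage.mode(effects) <- "double"
  nq <- nrow(effects)
  if (length(chromosome) != nq || length(position_cM) != nq)
    stop("chromosome, position_cM and rows of effects must agree")
  avg <- rowMeans(effects)
  structure(list(chromosome = as.character(chromosome),
                 position_cM = as.numeric(position_cM),
                 effects = effects,
                 avg = avg,
                 qei = effects - avg),
            class = "qtl_architecture")
}

#' @export
print.qtl_architecture <- function(x, ...) {
  cat("QTL architecture:", length(x$chromosome), "QTL,",
      ncol(x$effects), "environment(s)\n")
  df <- data.frame(chromosome = x$chromosome, position_cM = x$position_cM,
                   avg_effect = x$avg)
  print(cbind(df, x$effects), ...)
  invisible(x)
}

#' Number of environments of an architecture
#' @param arch a [qtl_architecture()].
#' @return integer.
#' @export
n_environments <- function(arch) ncol(arch$effects)

#' Trial design for the simulator
#'
#' @param population population kind (`"DH"`, `"BC1"`, `"RIL"`).
#' @param n population size (individuals).
#' @param e number of environments.
#' @param H2 broad-sense heritability in `(0, 1]`, enforced per environment
#'   through the residual variance `sigma2_h = V_G,h (1 - H2) / H2`.
#' @param mu per-environment intercepts (recycled; default 0).
#' @param seed integer random seed.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(population = "DH", n = 200, e = 2, H2 = 0.5,
                         mu = 0, seed = 1L) {
  population <- match_population(population)
  if (n < 1) stop("population size n must be >= 1")
  if (e < 1) stop("need at least one environment")
  if (!is.finite(H2) || H2 <= 0 || H2 > 1)
    stop("H2 must lie in (0, 1]")
  structure(list(population = population, n = as.integer(n),
                 e = as.integer(e), H2 = H2,
                 mu = rep_len(as.numeric(mu), e), seed = as.integer(seed)),
            class = "trial_design")
}

# Merge the markers of one chromosome with the QTL lying on it; returns
# positions, a locus-type flag and (for QTL) the architecture row index.
merge_loci <- function(pos_chr, arch_idx, arch) {
  qpos <- arch$position_cM[arch_idx]
  pos <- c(pos_chr, qpos)
  type <- c(rep.int(0L, length(pos_chr)), rep.int(1L, length(qpos)))
  qidx <- c(rep.int(NA_integer_, length(pos_chr)), arch_idx)
  ord <- order(pos, type)   # marker first when a QTL sits exactly on it
  list(pos = pos[ord], type = type[ord], qidx = qidx[ord])
}

#' Simulate marker and QTL genotypes of a biparental population
#'
#' Each chromosome is simulated as a first-order Markov chain over the
#' merged (marker and QTL) loci: the first locus is P1 or P2 with
#' probability 1/2, and each subsequent locus switches parental class with
#' the recombination fraction of the inter-locus distance -- the Haldane
#' gamete fraction for DH/BC1, the accumulated fraction for RIL (single-pass
#' chain, marginally equivalent to iterated selfing).
#'
#' @param map a [genetic_map()].
#' @param arch a [qtl_architecture()]; may have zero QTL (null genome).
#' @param design a [trial_design()].  The design's seed is consumed via
#'   `set.seed` unless `use_seed = FALSE`.
#' @param use_seed set the RNG seed from the design (default TRUE).
#' @return list of class `sim_genotypes` with `markers` (n x m matrix of
#'   +1/-1 codes, columns named by marker), `qtl` (n x nQTL matrix of true
#'   QTL genotypes) and `map`.
#' @export
simulate_genotypes <- function(map, arch, design, use_seed = TRUE) {
  stopifnot(inherits(map, "genetic_map"), inherits(arch, "qtl_architecture"),
            inherits(design, "trial_design"))
  if (use_seed) set.seed(design$seed)
  chrs <- map_by_chromosome(map)
  nq <- length(arch$chromosome)
  for (j in seq_len(nq)) {
    ch <- arch$chromosome[j]
    if (!ch %in% names(chrs))
      stop("QTL ", j, " lies on unknown chromosome ", ch)
    rng <- range(chrs[[ch]]$position_cM)
    if (arch$position_cM[j] < rng[1] || arch$position_cM[j] > rng[2])
      stop("QTL ", j, " at ", arch$position_cM[j],
           " cM is outside the map span of chromosome ", ch)
  }
  n <- design$n
  markers <- matrix(NA_real_, n, nrow(map),
                    dimnames = list(NULL, map$marker))
  qtl <- matrix(NA_real_, n, nq)
  mcol <- 0L
  for (ch in names(chrs)) {
    loci <- merge_loci(chrs[[ch]]$position_cM,
                       which(arch$chromosome == ch), arch)
    L <- length(loci$pos)
    g <- matrix(0, n, L)
    g[, 1L] <- ifelse(stats::runif(n) < 0.5, 1, -1)
    if (L > 1L) {
      rr <- pop_recomb(diff(loci$pos), design$population)
      for (l in 2L:L) {
        flip <- stats::runif(n) < rr[l - 1L]
        g[, l] <- ifelse(flip, -g[, l - 1L], g[, l - 1L])
      }
    }
    is_m <- loci$type == 0L
    nm <- sum(is_m)
    markers[, mcol + seq_len(nm)] <- g[, is_m, drop = FALSE]
    mcol <- mcol + nm
    if (any(!is_m)) qtl[, loci$qidx[!is_m]] <- g[, !is_m, drop = FALSE]
  }
  structure(list(markers = markers, qtl = qtl, map = map,
                 population = design$population),
            class = "sim_genotypes")
}

#' Closed-form per-environment genetic variance of an architecture
#'
#' With two genotype classes at frequency 1/2 each, the genetic variance in
#' environment `h` is `sum_j a_jh^2 + 2 sum_{j<j'} a_jh a_j'h D_jj'` where
#' the linkage disequilibrium term `D_jj' = 1 - 2 r_jj'` uses the Haldane
#' recombination fraction of the QTL-QTL distance (accumulated fraction for
#' RILs) and `D = 0` across chromosomes.
#'
#' @param arch a [qtl_architecture()].
#' @param map unused placeholder kept for interface symmetry (distances come
#'   from the architecture's own positions); may be `NULL`.
#' @param population population kind.
#' @return numeric vector of per-environment genetic variances.
#' @export
genetic_variance <- function(arch, map = NULL, population = "DH") {
  population <- match_population(population)
  a <- arch$effects
  nq <- nrow(a)
  vg <- colSums(a^2)
  if (nq > 1L) {
    for (j in seq_len(nq - 1L)) {
      for (jp in (j + 1L):nq) {
        if (arch$chromosome[j] != arch$chromosome[jp]) next
        r <- pop_recomb(abs(arch$position_cM[j] - arch$position_cM[jp]),
                        population)
        vg <- vg + 2 * a[j, ] * a[jp, ] * (1 - 2 * r)
      }
    }
  }
  unname(vg)
}

#' Expected per-QTL percentage of variance explained
#'
#' Closed-form oracle for the simulated designs.  The phenotypic variance is
#' `V_P = mean_h(V_G,h) / H2`; the variance contributed by QTL `j` is
#' `mean_h(a_jh^2) = abar_j^2 + mean_h(ae_jh^2)`, split into the
#' average-effect part `abar_j^2` and the interaction part `mean_h(ae_jh^2)`.
#'
#' @inheritParams genetic_variance
#' @param H2 broad-sense heritability in `(0, 1]`.
#' @return data.frame with one row per QTL: `PVE_A`, `PVE_AE`, `PVE` (in %).
#' @export
expected_pve <- function(arch, map = NULL, population = "DH", H2 = 0.5) {
  if (!is.finite(H2) || H2 <= 0 || H2 > 1) stop("H2 must lie in (0, 1]")
  vg <- genetic_variance(arch, map, population)
  vp <- mean(vg) / H2
  if (vp == 0) {
    z <- numeric(nrow(arch$effects))
    return(data.frame(PVE_A = z, PVE_AE = z, PVE = z))
  }
  pve_a <- 100 * arch$avg^2 / vp
  pve_ae <- 100 * rowMeans(arch$qei^2) / vp
  data.frame(PVE_A = pve_a, PVE_AE = pve_ae, PVE = pve_a + pve_ae)
}

#' Residual variances implied by a heritability level
#'
#' `sigma2_h = V_G,h (1 - H2) / H2` per environment.  Environments whose
#' genetic variance is zero (environment-specific architectures) receive the
#' mean of the non-zero residual variances so that every environment carries
#' noise; if all are zero a floor variance must be supplied.
#'
#' @inheritParams expected_pve
#' @param floor_sigma2 fallback residual variance when every `V_G,h` is 0.
#' @return numeric vector of per-environment residual variances.
#' @export
residual_variances <- function(arch, population = "DH", H2 = 0.5,
                               floor_sigma2 = NULL) {
  vg <- genetic_variance(arch, NULL, population)
  s2 <- vg * (1 - H2) / H2
  if (any(vg == 0)) {
    if (all(vg == 0)) {
      if (is.null(floor_sigma2))
        stop("all environments have zero genetic variance; ",
             "supply floor_sigma2")
      s2[] <- floor_sigma2
    } else {
      s2[vg == 0] <- mean(s2[vg > 0])
    }
  }
  s2
}

#' Simulate multi-environment phenotypes
#'
#' `y_ih = mu_h + sum_j a_jh g_ij + eps_ih`, with independent
#' `eps_ih ~ N(0, sigma2_h)` and `sigma2_h` from [residual_variances()].
#'
#' @param genotypes a [simulate_genotypes()] result carrying the true QTL
#'   genotype columns.
#' @param arch the [qtl_architecture()] used to simulate the genotypes.
#' @param design the [trial_design()].
#' @return n x e numeric matrix of phenotypes (class `matrix`), with the
#'   genotypic values in attribute `"genotypic_value"`.
#' @export
simulate_phenotypes <- function(genotypes, arch, design) {
  stopifnot(inherits(genotypes, "sim_genotypes"))
  n <- nrow(genotypes$markers)
  e <- design$e
  if (ncol(arch$effects) != e)
    stop("architecture has ", ncol(arch$effects), " environments; design has ", e)
  gv <- matrix(rep(design$mu, each = n), n, e)
  if (length(arch$chromosome))
    gv <- gv + genotypes$qtl %*% arch$effects
  if (design$H2 < 1) {
    s2 <- residual_variances(arch, design$population, design$H2)
    eps <- matrix(stats::rnorm(n * e, sd = rep(sqrt(s2), each = n)), n, e)
    y <- gv + eps
  } else {
    y <- gv
  }
  colnames(y) <- paste0("E", seq_len(e))
  attr(y, "genotypic_value") <- gv
  y
}

#' Simulate a null (no-QTL) dataset
#'
#' Genotypes as in [simulate_genotypes()] with an empty architecture;
#' phenotypes are pure `N(0, sigma2_h)` noise, used to calibrate genome-wide
#' LOD thresholds.
#'
#' @param map a [genetic_map()].
#' @param population population kind.
#' @param n population size.
#' @param e number of environments.
#' @param sigma2 per-environment noise variance (recycled).
#' @param seed integer seed.
#' @return list with `genotypes` (a `sim_genotypes`) and `phenotypes`
#'   (n x e matrix).
#' @export
simulate_null <- function(map, population = "DH", n = 200, e = 2,
                          sigma2 = 1, seed = 1L) {
  arch <- qtl_architecture(character(0), numeric(0),
                           matrix(numeric(0), 0, e))
  design <- trial_design(population, n, e, H2 = 0.5, seed = seed)
  g <- simulate_genotypes(map, arch, design)
  s2 <- rep_len(sigma2, e)
  y <- matrix(stats::rnorm(n * e, sd = rep(sqrt(s2), each = n)), n, e)
  colnames(y) <- paste0("E", seq_len(e))
  list(genotypes = g, phenotypes = y)
}

#' Simulate a complete trial (genotypes + phenotypes)
#'
#' @inheritParams simulate_genotypes
#' @return list with `genotypes` and `phenotypes`.
#' @export
simulate_trial <- function(map, arch, design) {
  g <- simulate_genotypes(map, arch, design)
  y <- simulate_phenotypes(g, arch, design)
  list(genotypes = g, phenotypes = y)
}
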