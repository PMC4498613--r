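#' Null-model fit at a testing position
#'
#' Under H0 (no QTL at the testing position) the adjusted phenotypes of each
#' environment follow a single normal distribution; the MLE is the sample
#' mean and the biased (1/n) variance, and the log-likelihood is available
#' in closed form.
#'
#' @param dy n x e matrix of background-adjusted phenotypes (NA allowed).
#' @return list of class `mixture_fit` with `mu` (per-environment means),
#'   `sigma2`, `loglik` (natural log) and `n_obs` per environment.
#' @export
fit_h0 <- function(dy) {
  dy <- as.matrix(dy)
  e <- ncol(dy)
  mu <- colMeans(dy, na.rm = TRUE)
  n_obs <- colSums(!is.na(dy))
  if (any(n_obs < 2))
    stop("need at least 2 non-missing values per environment")
  s2 <- colSums(sweep(dy, 2, mu)^2, na.rm = TRUE) / n_obs
  if (any(s2 <= 0))
    stop("zero phenotypic variance in environment ",
         paste(which(s2 <= 0), collapse = ", "))
  ll <- -sum(n_obs / 2 * (log(2 * pi * s2) + 1))
  structure(list(hypothesis = "H0", mu = mu, sigma2 = s2,
                 loglik = ll, n_obs = n_obs),
            class = "mixture_fit")
}

# Initialization from the two double-homozygote flanking groups; falls back
# to overall mean +/- half the pooled SD when a group is empty.
em_init <- function(dy, pi1) {
  g1 <- !is.na(pi1) & pi1 >= 0.5 + 1e-9 & pi1 >= max(pi1, na.rm = TRUE) - 1e-12
  g4 <- !is.na(pi1) & pi1 <= 0.5 - 1e-9 & pi1 <= min(pi1, na.rm = TRUE) + 1e-12
  e <- ncol(dy)
  mu0 <- colMeans(dy, na.rm = TRUE)
  sd0 <- apply(dy, 2L, stats::sd, na.rm = TRUE)
  if (sum(g1) >= 1 && sum(g4) >= 1) {
    mu1 <- colMeans(dy[g1, , drop = FALSE], na.rm = TRUE)
    mu2 <- colMeans(dy[g4, , drop = FALSE], na.rm = TRUE)
    both <- g1 | g4
    centred <- dy
    centred[g1, ] <- sweep(dy[g1, , drop = FALSE], 2, mu1)
    centred[g4, ] <- sweep(dy[g4, , drop = FALSE], 2, mu2)
    s2 <- colSums(centred[both, , drop = FALSE]^2, na.rm = TRUE) /
      pmax(colSums(!is.na(dy[both, , drop = FALSE])), 1)
    bad <- !is.finite(mu1) | !is.finite(mu2) | !is.finite(s2) | s2 <= 0
    if (any(bad)) {
      mu1[bad] <- mu0[bad] + sd0[bad] / 2
      mu2[bad] <- mu0[bad] - sd0[bad] / 2
      s2[bad] <- sd0[bad]^2
    }
  } else {
    mu1 <- mu0 + sd0 / 2
    mu2 <- mu0 - sd0 / 2
    s2 <- sd0^2
  }
  s2 <- pmax(s2, 1e-10)
  list(mu1 = mu1, mu2 = mu2, sigma2 = s2)
}

mixture_fit_from_cpp <- function(res, hypothesis) {
  if (!res$converged)
    warning("ECM (", hypothesis, ") did not converge in ",
            res$iterations, " iterations")
  structure(list(hypothesis = hypothesis,
                 mu1 = res$mu1, mu2 = res$mu2, sigma2 = res$sigma2,
                 loglik = res$loglik, iterations = res$iterations,
                 converged = res$converged, lagrange = res$lagrange,
                 weights = cbind(QQ = res$w1, qq = 1 - res$w1),
                 f1 = res$f1),
            class = "mixture_fit")
}

#' Unconstrained mixture fit at a testing position (H1)
#'
#' Fits, by ECM, the two-component normal mixture in which each individual
#' carries one QTL genotype shared across environments: component densities
#' are products of per-environment normals with genotype-specific means and
#' a common (per-environment) variance.  Mixing proportions are the
#' individual-specific priors from the flanking markers.
#'
#' @param dy n x e matrix of background-adjusted phenotypes.
#' @param pi1 length-n vector of prior `P(QQ)` per individual (from
#'   [interval_probabilities()] group membership, or [individual_pi1]);
#'   `NA` excludes the individual.  A 4 x 2 `pi` matrix plus a group vector
#'   may be supplied instead via `groups`.
#' @param groups optional integer vector (1-4) of flanking-marker groups;
#'   used with `pi1` given as an `interval_probabilities` object.
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param maxit maximum ECM iterations (default 200).
#' @param likelihood `"product"` (default) treats an individual's genotype
#'   as shared across environments, so component densities multiply over
#'   environments — the model whose ECM has exactly the mean/variance
#'   updates used here.  `"sum"` weights components by the sum of
#'   per-environment densities instead (comparison variant).
#' @return a `mixture_fit` with per-environment `mu1`, `mu2`, `sigma2`,
#'   `loglik`, posterior `weights`, `iterations`, `converged`.
#' @export
fit_h1 <- function(dy, pi1, groups = NULL, tol = 1e-6, maxit = 200,
                   likelihood = c("product", "sum")) {
  likelihood <- match.arg(likelihood)
  dy <- as.matrix(dy)
  pi1 <- resolve_pi1(pi1, groups, nrow(dy))
  init <- em_init(dy, pi1)
  res <- cpp_fit_mixture(dy, pi1, init$mu1, init$mu2, init$sigma2,
                         FALSE, tol, maxit, likelihood == "sum")
  mixture_fit_from_cpp(res, "H1")
}

#' Constrained mixture fit at a testing position (H2)
#'
#' As [fit_h1()], but the average effect is constrained to zero:
#' `sum_h (mu_1h - mu_2h) = 0`, enforced in each conditional-maximization
#' step through a single Lagrange multiplier.  The converged fit satisfies
#' the constraint to numerical tolerance; the final multiplier is returned
#' in `$lagrange`.
#'
#' @inheritParams fit_h1
#' @return a `mixture_fit`.
#' @export
fit_h2 <- function(dy, pi1, groups = NULL, tol = 1e-6, maxit = 200,
                   likelihood = c("product", "sum")) {
  likelihood <- match.arg(likelihood)
  dy <- as.matrix(dy)
  pi1 <- resolve_pi1(pi1, groups, nrow(dy))
  init <- em_init(dy, pi1)
  # start from a constraint-satisfying point
  shift <- mean(init$mu1 - init$mu2) / 2
  res <- cpp_fit_mixture(dy, pi1, init$mu1 - shift, init$mu2 + shift,
                         init$sigma2, TRUE, tol, maxit, likelihood == "sum")
  mixture_fit_from_cpp(res, "H2")
}

resolve_pi1 <- function(pi1, groups, n) {
  if (inherits(pi1, "interval_probabilities")) {
    if (is.null(groups))
      stop("supply flanking-marker groups with an interval_probabilities object")
    pi1 <- pi1$pi[groups, 1L]
  }
  if (length(pi1) != n)
    stop("pi1 must have one entry per individual")
  as.numeric(pi1)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Mixture fit (", x$hypothesis, "): loglik = ",
      format(x$loglik, digits = 8), sep = "")
  if (!is.null(x$iterations))
    cat(", ", x$iterations, " iterations",
        if (isFALSE(x$converged)) " (NOT converged)", sep = "")
  cat("\n")
  invisible(x)
}

#' LOD decomposition from the three hypothesis fits
#'
#' `LOD_A = (l1 - l2)/ln 10` tests the average effect, `LOD_AE =
#' (l2 - l0)/ln 10` tests the interaction effects, and their sum `LOD =
#' (l1 - l0)/ln 10` tests any effect.  Values below `-1e-6` indicate an ECM
#' convergence failure and are flagged.
#'
#' @param fit0,fit1,fit2 `mixture_fit` objects from [fit_h0()], [fit_h1()],
#'   [fit_h2()] on identical data.
#' @return named numeric vector `c(LOD, LOD_A, LOD_AE)`.
#' @export
lod_scores <- function(fit0, fit1, fit2) {
  l0 <- fit0$loglik; l1 <- fit1$loglik; l2 <- fit2$loglik
  out <- c(LOD = (l1 - l0), LOD_A = (l1 - l2), LOD_AE = (l2 - l0)) / log(10)
  if (any(out < -1e-6))
    warning("negative LOD component beyond tolerance: convergence failure?")
  out
}

#' Additive and interaction effects from an H1 fit
#'
#' `a_h = (mu_1h - mu_2h) / 2`; the average effect is `abar = mean_h(a_h)`
#' and the interaction effects are `ae_h = a_h - abar` (summing to zero).
#'
#' @param fit a `mixture_fit` from [fit_h1()].
#' @return list with `a` (per-environment effects), `avg`, `qei`.
#' @export
estimate_effects <- function(fit) {
  a <- (fit$mu1 - fit$mu2) / 2
  avg <- mean(a)
  list(a = a, avg = avg, qei = a - avg)
}

#' Variance decomposition of the fitted genotype-by-environment means
#'
#' Orthogonal two-way decomposition of the 2 x e table of fitted genotype
#' means: with marginal genotype frequencies `f_k.` (estimated by the mean
#' posterior weights) and cell frequencies `f_kh = f_k./e`, the grand mean
#' is `mu.. = sum f_kh mu_kh`, row means `mu_k. = mean_h mu_kh`, column
#' means `mu_.h = sum_k f_k. mu_kh`.  Then
#' `V_A = sum_k f_k. (mu_k. - mu..)^2 = 4 f_1. f_2. abar^2` and
#' `V_AE = sum_kh f_kh (mu_kh - mu_k. - mu_.h + mu..)^2
#'       = (4/e) f_1. f_2. sum_h (a_h - abar)^2`.
#' PVEs are percentages of `V_P = mean_h V_P,h` (raw per-environment
#' phenotypic variances, 1/n denominator).
#'
#' @param means 2 x e matrix of genotype means (rows QQ, qq), or a
#'   `mixture_fit` from [fit_h1()] (then `freq` defaults to its posterior
#'   frequencies).
#' @param freq length-2 marginal genotype frequencies (sum to 1).
#' @param vp_env per-environment phenotypic variances, or an n x e
#'   phenotype matrix from which the 1/n variances are taken.
#' @return list with `V_A`, `V_AE`, `V_P`, `PVE_A`, `PVE_AE`, `PVE` (in %).
#' @export
#' @examples
#' # two genotypes in four environments
#' m <- rbind(QQ = c(14, 10, 12, 16), qq = c(12, 10, 17, 11))
#' pve_decomposition(m, freq = c(0.4, 0.6), vp_env = c(30, 20, 10, 40))
pve_decomposition <- function(means, freq = NULL, vp_env) {
  if (inherits(means, "mixture_fit")) {
    if (is.null(freq)) freq <- c(means$f1, 1 - means$f1)
    means <- rbind(means$mu1, means$mu2)
  }
  means <- as.matrix(means)
  stopifnot(nrow(means) == 2L, length(freq) == 2L,
            abs(sum(freq) - 1) < 1e-8)
  e <- ncol(means)
  if (is.matrix(vp_env) && nrow(vp_env) > 1) {
    n_obs <- colSums(!is.na(vp_env))
    vp_env <- colSums(sweep(vp_env, 2, colMeans(vp_env, na.rm = TRUE))^2,
                      na.rm = TRUE) / n_obs
  }
  stopifnot(length(vp_env) == e)
  vp <- mean(vp_env)
  if (vp <= 0) stop("phenotypic variance must be positive")

  f_kh <- matrix(freq / e, 2L, e)
  mu_gg <- sum(f_kh * means)
  mu_k <- rowMeans(means)
  mu_h <- colSums(freq * means)
  v_a <- sum(freq * (mu_k - mu_gg)^2)
  qei <- sweep(sweep(means, 1, mu_k), 2, mu_h) + mu_gg
  v_ae <- sum(f_kh * qei^2)
  list(V_A = v_a, V_AE = v_ae, V_P = vp,
       PVE_A = 100 * v_a / vp, PVE_AE = 100 * v_ae / vp,
       PVE = 100 * (v_a + v_ae) / vp)
}

#' One-dimensional QEI genome scan
#'
#' Runs the full background-controlled scan: for every marker interval the
#' phenotypes are adjusted once for all selected cofactors except the two
#' flanking markers, then the three hypothesis fits (H0 closed form, H1 and
#' H2 by ECM) are computed at every grid position.  The grid steps through
#' each interval from its left to its right marker; a marker shared by two
#' intervals is reported once, from the interval on its left.
#'
#' @param genotypes a `sim_genotypes` object or an n x m marker matrix.
#' @param phenotypes n x e phenotype matrix.
#' @param map the [genetic_map()] (taken from `genotypes` if available).
#' @param population population kind.
#' @param cofactors optional precomputed `cofactor_model`; by default
#'   [stepwise_select()] runs with `p_in`/`p_out`.
#' @param step scan step in cM (default 1).
#' @param p_in,p_out stepwise entry/removal probabilities.
#' @param tol,maxit ECM convergence settings.
#' @param likelihood mixture likelihood form, see [fit_h1()].
#' @return data.frame of class `qei_scan` with one row per scan position:
#'   `chromosome`, `position_cM`, `LOD`, `LOD_A`, `LOD_AE`, `PVE`, `PVE_A`,
#'   `PVE_AE`, `avg_effect`, `a_1..a_e`, `ae_1..ae_e`, `converged`.
#' @export
qei_scan <- function(genotypes, phenotypes, map = NULL, population = "DH",
                     cofactors = NULL, step = 1,
                     p_in = 0.001, p_out = 0.002,
                     tol = 1e-6, maxit = 200,
                     likelihood = c("product", "sum")) {
  likelihood <- match.arg(likelihood)
  if (inherits(genotypes, "sim_genotypes")) {
    if (is.null(map)) map <- genotypes$map
    population <- genotypes$population
    geno <- genotypes$markers
  } else geno <- as.matrix(genotypes)
  stopifnot(inherits(map, "genetic_map"), ncol(geno) == nrow(map))
  phenotypes <- as.matrix(phenotypes)
  if (nrow(phenotypes) != nrow(geno))
    stop("genotypes and phenotypes disagree on the number of individuals")
  e <- ncol(phenotypes)
  if (is.null(cofactors))
    cofactors <- stepwise_select(geno, phenotypes, map, p_in, p_out,
                                 population)

  # raw per-environment phenotypic variances (1/n) for the PVE denominators
  vp_env <- colSums(sweep(phenotypes, 2,
                          colMeans(phenotypes, na.rm = TRUE))^2,
                    na.rm = TRUE) / colSums(!is.na(phenotypes))

  chr_idx <- split(seq_len(nrow(map)), map$chromosome)
  rows <- list()
  for (ch in names(chr_idx)) {
    cols <- chr_idx[[ch]]
    pos <- map$position_cM[cols]
    gchr <- geno[, cols, drop = FALSE]
    m <- length(cols)
    for (k in seq_len(m - 1L)) {
      dy <- adjust_phenotypes(phenotypes, cofactors,
                              flank = cols[c(k, k + 1L)])
      h0 <- fit_h0(dy)
      grid <- seq(pos[k], pos[k + 1L], by = step)
      if (grid[length(grid)] < pos[k + 1L] - 1e-9)
        grid <- c(grid, pos[k + 1L])
      if (k > 1L) grid <- grid[-1L]            # marker reported from the left
      if (!length(grid)) next
      pim <- vapply(grid, function(sp)
        individual_pi1(gchr, pos, k, sp, population),
        numeric(nrow(gchr)))
      pim <- matrix(pim, nrow = nrow(gchr))
      # initialize from the two double-homozygote flanking groups
      xl <- gchr[, k]; xr <- gchr[, k + 1L]
      grp1 <- !is.na(xl) & !is.na(xr) & xl > 0 & xr > 0
      grp4 <- !is.na(xl) & !is.na(xr) & xl < 0 & xr < 0
      init <- em_init(dy, ifelse(grp1, 1, ifelse(grp4, 0, 0.5)))
      sc <- cpp_scan_interval(dy, pim, init$mu1, init$mu2, init$sigma2,
                              tol, maxit, likelihood == "sum")
      a <- (sc$mu1 - sc$mu2) / 2
      avg <- rowMeans(a)
      ae <- a - avg
      pveA <- pveAE <- numeric(length(grid))
      for (p in seq_along(grid)) {
        f1 <- sc$f1[p]
        dec <- pve_decomposition(rbind(sc$mu1[p, ], sc$mu2[p, ]),
                                 freq = c(f1, 1 - f1), vp_env = vp_env)
        pveA[p] <- dec$PVE_A; pveAE[p] <- dec$PVE_AE
      }
      lod1 <- (sc$ll1 - h0$loglik) / log(10)
      lod2 <- (sc$ll2 - h0$loglik) / log(10)
      df <- data.frame(chromosome = ch, position_cM = grid,
                       LOD = lod1, LOD_A = lod1 - lod2, LOD_AE = lod2,
                       PVE = pveA + pveAE, PVE_A = pveA, PVE_AE = pveAE,
                       avg_effect = avg)
      colnames(a) <- paste0("a_", seq_len(e))
      colnames(ae) <- paste0("ae_", seq_len(e))
      df <- cbind(df, a, ae)
      df$converged <- sc$converged1 & sc$converged2
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qei_scan", "data.frame")
  attr(out, "cofactors") <- cofactors
  out
}

#' @export
print.qei_scan <- function(x, ...) {
  cat("QEI scan:", nrow(x), "positions on",
      length(unique(x$chromosome)), "chromosome(s); max LOD =",
      format(max(x$LOD), digits = 4), "\n")
  invisible(as.data.frame(x))
}
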