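test_that("simulated genotype frequencies and recombination match theory", {
  map <- genetic_map(c("m1", "m2"), c(1, 1), c(0, 10))
  arch <- qtl_architecture(character(0), numeric(0), matrix(numeric(0), 0, 2))
  n <- 10000
  g <- simulate_genotypes(map, arch,
                          trial_design("DH", n, 2, 0.5, seed = 11))$markers
  # Mendelian 1/2 per locus
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(g[, 1] == 1) - 0.5), 3 * se)
  # DH recombinant fraction over 10 cM
  r <- haldane_r(10)
  rec <- mean(g[, 1] != g[, 2])
  expect_lt(abs(rec - r), 3 * sqrt(r * (1 - r) / n))
  # RIL accumulates recombination
  gr <- simulate_genotypes(map, arch,
                           trial_design("RIL", n, 2, 0.5, seed = 12))$markers
  R <- ril_accumulated_R(r)
  recR <- mean(gr[, 1] != gr[, 2])
  expect_lt(abs(recR - R), 3 * sqrt(R * (1 - R) / n))
})

test_that("QTL outside the map span is rejected", {
  map <- genetic_map(c("m1", "m2"), c(1, 1), c(0, 10))
  arch <- qtl_architecture("1", 40, cbind(0.5, 0.5))
  expect_error(
    simulate_genotypes(map, arch, trial_design("DH", 10, 2, 0.5, 1)),
    "outside the map span")
})

test_that("closed-form genetic variance", {
  # unlinked benchmark: unit variance in both environments
  expect_equal(genetic_variance(arch_unlinked()), c(1, 1))
  # two linked QTL in repulsion, 30 cM apart
  expect_equal(genetic_variance(arch_linked("L7")),
               rep(0.5 - 2 * 0.25 * exp(-0.6), 2), tolerance = 1e-12)
  expect_equal(round(genetic_variance(arch_linked("L7"))[1], 5), 0.22559)
  # single QTL
  expect_equal(genetic_variance(qtl_architecture("1", 5, cbind(0.5, 0.5))),
               c(0.25, 0.25))
})

test_that("expected PVE oracle reproduces the benchmark designs", {
  pve <- expected_pve(arch_unlinked(), H2 = 0.5)
  expect_equal(pve$PVE, c(12.5, 12.5, 6.25, 6.25, 12.5))
  expect_equal(pve$PVE_A, c(12.5, 0, 3.125, 3.125, 12.5))
  expect_equal(pve$PVE_AE, c(0, 12.5, 3.125, 3.125, 0))
  expect_equal(round(expected_pve(arch_linked("L7"), H2 = 0.1)$PVE, 2),
               c(11.08, 11.08))
  expect_equal(round(expected_pve(arch_linked("L2"), H2 = 0.5)$PVE, 2),
               c(25, 25))
  # zero architecture
  z <- expected_pve(qtl_architecture("1", 5, cbind(0, 0)), H2 = 0.5)
  expect_equal(z$PVE, 0)
  expect_error(expected_pve(arch_unlinked(), H2 = 0), "H2")
  # unlinked architectures: per-QTL PVEs sum to 100 * H2
  for (h2 in c(0.1, 0.5, 0.8))
    expect_equal(sum(expected_pve(arch_unlinked(), H2 = h2)$PVE), 100 * h2)
})

test_that("phenotype simulation realizes the target heritability", {
  map <- standard_map()
  arch <- arch_unlinked()
  des <- trial_design("DH", n = 5000, e = 2, H2 = 0.5, seed = 21)
  tr <- simulate_trial(map, arch, des)
  gv <- attr(tr$phenotypes, "genotypic_value")
  for (h in 1:2) {
    vp <- var(tr$phenotypes[, h])
    # V_P = V_G / H2 = 2.0; allow 3 SE of a variance estimate
    expect_lt(abs(vp - 2), 3 * 2 * sqrt(2 / 5000))
    h2 <- var(gv[, h]) / vp
    expect_lt(abs(h2 - 0.5), 0.04)
  }
  # regression of phenotype on a true QTL genotype recovers its effect
  fit <- lm(tr$phenotypes[, 1] ~ tr$genotypes$qtl[, 1])
  expect_lt(abs(coef(fit)[2] - 0.5), 3 * summary(fit)$coefficients[2, 2])
})

test_that("heritability one gives noiseless phenotypes", {
  map <- standard_map()
  arch <- arch_unlinked()
  tr <- simulate_trial(map, arch, trial_design("DH", 50, 2, H2 = 1, seed = 3))
  expect_equal(tr$phenotypes[, 1],
               attr(tr$phenotypes, "genotypic_value")[, 1],
               ignore_attr = TRUE)
})

test_that("residual variances handle zero-variance environments", {
  # environment 2 has no genetic variance -> borrows the mean noise level
  arch <- qtl_architecture("1", 5, cbind(0.5, 0))
  s2 <- residual_variances(arch, "DH", 0.5)
  expect_equal(s2, c(0.25, 0.25))
  arch0 <- qtl_architecture("1", 5, cbind(0, 0))
  expect_error(residual_variances(arch0, "DH", 0.5), "floor_sigma2")
  expect_equal(residual_variances(arch0, "DH", 0.5, floor_sigma2 = 2),
               c(2, 2))
})

test_that("simulation is reproducible and null model is pure noise", {
  map <- standard_map()
  a <- simulate_null(map, "DH", 100, 2, sigma2 = 1, seed = 7)
  b <- simulate_null(map, "DH", 100, 2, sigma2 = 1, seed = 7)
  expect_identical(a$genotypes$markers, b$genotypes$markers)
  expect_identical(a$phenotypes, b$phenotypes)
  # phenotype-marker correlations center on zero
  cors <- cor(a$phenotypes[, 1], a$genotypes$markers)
  expect_lt(abs(mean(cors)), 0.05)
  expect_error(simulate_null(map, "DH", 0, 2, 1, 1), "n must be")
})
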