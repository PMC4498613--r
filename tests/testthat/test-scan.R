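test_that("H0 fit is the closed-form single-normal MLE", {
  dy <- cbind(c(1, 2, 3, 4, 5), c(0, 1, 0, -1, 2))
  f0 <- fit_h0(dy)
  expect_equal(f0$mu, colMeans(dy), ignore_attr = TRUE)
  expect_equal(f0$sigma2, colMeans(sweep(dy, 2, colMeans(dy))^2),
               ignore_attr = TRUE)
  # brute-force log-density sum
  ll <- sum(dnorm(dy[, 1], f0$mu[1], sqrt(f0$sigma2[1]), log = TRUE)) +
    sum(dnorm(dy[, 2], f0$mu[2], sqrt(f0$sigma2[2]), log = TRUE))
  expect_equal(f0$loglik, ll, tolerance = 1e-12)
  expect_error(fit_h0(cbind(rep(1, 5), 1:5)), "zero")
  expect_error(fit_h0(cbind(c(1, NA, NA, NA, NA), 1:5)), "non-missing")
})

test_that("with indicator priors the H1 means are the class means", {
  set.seed(31)
  n <- 60
  g <- sample(c(1, 0), n, replace = TRUE)   # pi1 in {1, 0}: QTL at a marker
  dy <- cbind(rnorm(n, ifelse(g == 1, 2, -2)),
              rnorm(n, ifelse(g == 1, 1, -1)))
  f1 <- fit_h1(dy, pi1 = g)
  expect_equal(f1$mu1, colMeans(dy[g == 1, ]), tolerance = 1e-8)
  expect_equal(f1$mu2, colMeans(dy[g == 0, ]), tolerance = 1e-8)
  expect_true(all(f1$weights[g == 1, "QQ"] == 1))
})

test_that("likelihoods nest: l0 <= l2 <= l1, and LOD adds up", {
  for (s in 1:5) {
    inst <- toy_instance(600 + s, n = 40, e = 2)
    f0 <- fit_h0(inst$dy)
    f1 <- fit_h1(inst$dy, inst$pi1)
    f2 <- fit_h2(inst$dy, inst$pi1)
    expect_gte(f1$loglik, f2$loglik - 1e-6)
    expect_gte(f2$loglik, f0$loglik - 1e-6)
    lod <- lod_scores(f0, f1, f2)
    expect_equal(lod[["LOD"]], lod[["LOD_A"]] + lod[["LOD_AE"]],
                 tolerance = 1e-12)
    # H2 satisfies the zero-average-effect constraint
    expect_lt(abs(sum(f2$mu1 - f2$mu2)), 1e-5)
    # posterior weights are proper
    w <- f2$weights
    expect_true(all(w >= 0 & w <= 1, na.rm = TRUE))
    expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-12)
  }
})

test_that("null data give near-zero LOD; crossover QEI makes H2 binding-free", {
  set.seed(77)
  n <- 400
  inst <- toy_instance(777, n = n, e = 2, a = c(0, 0))
  f0 <- fit_h0(inst$dy); f1 <- fit_h1(inst$dy, inst$pi1)
  f2 <- fit_h2(inst$dy, inst$pi1)
  expect_lt(lod_scores(f0, f1, f2)[["LOD"]], 2)
  # pure crossover interaction: average effect is zero, so l2 ~ l1
  inst2 <- toy_instance(778, n = n, e = 2, a = c(0.8, -0.8))
  f1b <- fit_h1(inst2$dy, inst2$pi1)
  f2b <- fit_h2(inst2$dy, inst2$pi1)
  # under a true zero average effect, 2 (l1 - l2) ~ chi-square(1)
  expect_lt(f1b$loglik - f2b$loglik, qchisq(0.999, 1) / 2)
})

test_that("effect estimates decompose fitted means", {
  fit <- structure(list(mu1 = c(14, 10, 12, 16), mu2 = c(12, 10, 17, 11)),
                   class = "mixture_fit")
  eff <- estimate_effects(fit)
  expect_equal(eff$a, c(1, 0, -2.5, 2.5))
  expect_equal(eff$avg, 0.25)
  expect_equal(sum(eff$qei), 0)
  fit0 <- structure(list(mu1 = c(1, 2), mu2 = c(1, 2)),
                    class = "mixture_fit")
  expect_equal(estimate_effects(fit0)$a, c(0, 0))
})

test_that("variance decomposition: worked example and orthogonality", {
  m <- rbind(c(14, 10, 12, 16), c(12, 10, 17, 11))
  dec <- pve_decomposition(m, freq = c(0.4, 0.6), vp_env = c(30, 20, 10, 40))
  expect_equal(dec$V_A, 0.06)
  expect_equal(dec$V_AE, 3.18)
  expect_equal(dec$PVE_A, 0.24)
  expect_equal(dec$PVE_AE, 12.72)
  # closed forms: V_A = 4 f1 f2 abar^2, V_AE = (4/e) f1 f2 sum (a_h - abar)^2
  a <- (m[1, ] - m[2, ]) / 2
  expect_equal(dec$V_A, 4 * 0.4 * 0.6 * mean(a)^2, tolerance = 1e-12)
  expect_equal(dec$V_AE, 4 / 4 * 0.4 * 0.6 * sum((a - mean(a))^2),
               tolerance = 1e-12)
  # orthogonality of the two-way decomposition
  f_kh <- matrix(c(0.4, 0.6) / 4, 2, 4)
  mu_gg <- sum(f_kh * m); mu_k <- rowMeans(m)
  mu_h <- colSums(c(0.4, 0.6) * m)
  qei <- sweep(sweep(m, 1, mu_k), 2, mu_h) + mu_gg
  expect_lt(abs(sum(f_kh * (mu_k - mu_gg) * qei)), 1e-10)
  expect_lt(abs(sum(f_kh * rep(mu_h - mu_gg, each = 2) * qei)), 1e-10)
  # degenerate cases
  flat <- rbind(c(3, 3), c(3, 3))
  d0 <- pve_decomposition(flat, freq = c(0.5, 0.5), vp_env = c(1, 1))
  expect_equal(d0$V_A + d0$V_AE, 0)
  # perfectly additive table has no interaction variance
  add <- rbind(c(1, 2, 3), c(0, 1, 2))
  da <- pve_decomposition(add, freq = c(0.5, 0.5), vp_env = c(1, 1, 1))
  expect_equal(da$V_AE, 0, tolerance = 1e-12)
  expect_error(pve_decomposition(flat, c(0.5, 0.5), vp_env = c(0, 0)),
               "positive")
})

test_that("ECM matches generic numerical maximization on toy instances", {
  for (s in 1:6) {
    inst <- toy_instance(900 + s)
    f1 <- fit_h1(inst$dy, inst$pi1)
    f2 <- fit_h2(inst$dy, inst$pi1)
    e <- ncol(inst$dy)
    start1 <- list(c(f1$mu1, f1$mu2, log(f1$sigma2)),
                   c(colMeans(inst$dy) + 0.3, colMeans(inst$dy) - 0.3,
                     log(apply(inst$dy, 2, var))))
    best1 <- oracle_max_h1(inst$dy, inst$pi1, start1)
    expect_equal(f1$loglik, best1, tolerance = 1e-4)
    d2 <- (f2$mu1 - f2$mu2)[seq_len(e - 1)]
    start2 <- list(c(f2$mu2, d2, log(f2$sigma2)),
                   c(colMeans(inst$dy), rep(0.1, e - 1),
                     log(apply(inst$dy, 2, var))))
    best2 <- oracle_max_h2(inst$dy, inst$pi1, start2)
    expect_equal(f2$loglik, best2, tolerance = 1e-4)
  }
})

test_that("the sum-form likelihood variant gives comparable fits", {
  inst <- toy_instance(4242, n = 60, e = 2, a = c(0.7, 0.4))
  fp <- fit_h1(inst$dy, inst$pi1)
  fs <- fit_h1(inst$dy, inst$pi1, likelihood = "sum")
  # same genetics, different weighting: effects agree to first order
  expect_lt(max(abs((fp$mu1 - fp$mu2) - (fs$mu1 - fs$mu2))), 0.25)
  expect_false(isTRUE(all.equal(fp$loglik, fs$loglik)))
  # the H2 constraint holds under either form
  fs2 <- fit_h2(inst$dy, inst$pi1, likelihood = "sum")
  expect_lt(abs(sum(fs2$mu1 - fs2$mu2)), 1e-5)
})

test_that("a full scan has the expected grid and internal identities", {
  map <- standard_map(n_chr = 2)
  arch <- qtl_architecture("1", 16, cbind(0.6, 0.6))
  tr <- simulate_trial(map, arch, trial_design("DH", 150, 2, 0.5, seed = 55))
  prof <- qei_scan(tr$genotypes, tr$phenotypes)
  # grid: per chromosome 15 intervals x 10 new positions + 1 = 151
  expect_equal(nrow(prof), 2 * 151)
  expect_equal(prof$LOD, prof$LOD_A + prof$LOD_AE, tolerance = 1e-10)
  expect_true(all(prof$LOD_A > -1e-6 & prof$LOD_AE > -1e-6))
  expect_true(all(diff(prof$position_cM[prof$chromosome == "1"]) > 0))
  # effects decompose
  expect_equal(prof$avg_effect, (prof$a_1 + prof$a_2) / 2, tolerance = 1e-12)
  expect_equal(prof$ae_1 + prof$ae_2, rep(0, nrow(prof)), tolerance = 1e-12)
  # the peak is near the planted QTL
  top <- prof[which.max(prof$LOD), ]
  expect_equal(top$chromosome, "1")
  expect_lt(abs(top$position_cM - 16), 6)
})

test_that("missing genotype and phenotype cells are tolerated in the scan", {
  map <- standard_map(n_chr = 1)
  arch <- qtl_architecture("1", 16, cbind(0.8, 0.8))
  tr <- simulate_trial(map, arch, trial_design("DH", 120, 2, 0.5, seed = 66))
  g <- tr$genotypes$markers
  set.seed(1); g[sample(length(g), length(g) %/% 20)] <- NA
  y <- tr$phenotypes
  y[sample(length(y), 10)] <- NA
  prof <- qei_scan(g, y, map = map)
  expect_true(all(is.finite(prof$LOD)))
  expect_gt(max(prof$LOD), 3)
  expect_lt(abs(prof$position_cM[which.max(prof$LOD)] - 16), 8)
})
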