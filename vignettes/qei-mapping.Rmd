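---
title: "Mapping QTL-by-environment interactions with qeimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL-by-environment interactions with qeimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeimap)
```

## The problem

A quantitative trait locus (QTL) segregating in a biparental population
often has effects that change across trial environments: a locus may be
strong in one location-year and absent, or even reversed, in another.
For breeders this distinction matters — a *stable* QTL (large average
effect, small interaction) is useful everywhere, while an
*environment-specific* QTL is only useful in its target environments.
`qeimap` implements inclusive composite interval mapping (ICIM) of these
QTL-by-environment interactions (QEI) for populations with two genotype
classes per locus: doubled haploids (DH), first backcrosses (BC1) and
selfed recombinant inbred lines (RIL), phenotyped in `e` environments.

## Model

Writing `g_j = ±1` for the two genotypes of the `j`-th QTL and `a_jh` for
its additive effect in environment `h`, the genotypic value of an
individual is

    G_h = mu_h + sum_j a_jh g_j .

Each QTL's effects are decomposed into an average effect
`abar_j = mean_h(a_jh)` and interaction effects `ae_jh = a_jh − abar_j`
(which sum to zero over environments).  Conditioning on the flanking
markers turns this into an *inclusive* linear model of the phenotype on
all markers, `y_ih = b_0h + sum_j b_jh x_ij + e_ih`, in which the
coefficients of two adjacent markers absorb all the position and effect
information of a QTL in the interval between them.  That model justifies
the two-step strategy:

1. **Cofactor selection.** Stepwise regression of each environment's
   phenotype on all markers (entry/removal probabilities `p_in = 0.001`,
   `p_out = 0.002` by default) picks up the significant background.
2. **Interval scan on adjusted phenotypes.** For a testing position in
   interval `k`, the phenotype is adjusted by subtracting the fitted
   contributions of every selected marker *except* the two flanking
   markers `k`, `k+1`.  The adjusted values are constant within the
   interval, so the background correction is computed once per interval.

At each scan position individuals fall into four flanking-marker groups;
within a group the two QTL genotypes occur with probabilities determined
by the recombination fractions between the QTL and the flanking markers
(`interval_probabilities()`).  Since the QTL genotype of an individual is
the same in every environment, the likelihood of an individual is a
two-component mixture whose component densities are *products* of
per-environment normals `N(mu_kh, sigma2_h)`.  Three hypotheses are
fitted at every position:

* **H0** — no QTL: one normal per environment (closed form);
* **H1** — a QTL with any effects: unconstrained ECM fit;
* **H2** — interaction only: the average effect is constrained to zero,
  `sum_h (mu_1h − mu_2h) = 0`, enforced in each conditional-maximization
  step through a single Lagrange multiplier.

The likelihood ratios give an additive LOD decomposition:
`LOD_A = (l1 − l2)/ln 10` tests the average effect,
`LOD_AE = (l2 − l0)/ln 10` tests the interactions, and their sum
`LOD = (l1 − l0)/ln 10` tests any effect.  Effects follow from the
fitted means, `a_h = (mu_1h − mu_2h)/2`, and the percentage of
phenotypic variance explained comes from the orthogonal two-way
decomposition of the genotype-by-environment mean table:
`V_A = 4 f_1 f_2 abar²` and `V_AE = (4/e) f_1 f_2 sum_h (a_h − abar)²`,
each divided by `V_P = mean_h(V_P,h)` of the raw phenotypes.

On the likelihood form: the component weighting in the posterior step is
sometimes written with a *sum* of per-environment densities, but the
genetics (one genotype per line across all environments) and the
variance updates both correspond to the product form, which is the
unique likelihood whose ECM has exactly the mean and variance updates
used here.  `qeimap` therefore uses the product form throughout.

## Worked example

```{r example}
map  <- standard_map()          # 6 chromosomes x 150 cM, 16 markers each
arch <- arch_unlinked()         # 5 QTL with three interaction levels
tr   <- simulate_trial(map, arch,
                       trial_design("DH", n = 200, e = 2, H2 = 0.5,
                                    seed = 42))
prof <- qei_scan(tr$genotypes, tr$phenotypes)
thr  <- lod_threshold(genome_length(map), e = 2)   # 3.11
call_peaks(prof, thr)[, c("chromosome", "position_cM", "LOD",
                          "LOD_A", "LOD_AE", "avg_effect", "ae_1")]
```

## Significance thresholds

The number of effectively independent tests of a 1-D scan grows linearly
with genome length; at 10 cM marker density the built-in coefficients
are 0.072 tests/cM (genome-wide error 0.05) and 0.084 (0.01).  Other
densities need a user-supplied coefficient.  The threshold is the
Bonferroni-corrected chi-square critical value on the LOD scale,

    LOD* = qchisq(1 − alpha_g / M_eff, df) / (2 ln 10),

with `df = e` per testing position for DH/BC1/RIL (twice that for F2,
supported in the calculator only), `df = 1` for the average-effect score
and `df = e − 1` for the interaction score.  `M_eff` is deliberately kept
un-rounded — rounding it to the displayed integer changes the threshold
at short genome lengths.  For RILs the genome length is first multiplied
by 1.9: the accumulated recombination fraction `R = 2r/(1+2r)` stretches
1, 5 and 10 cM by 1.98, 1.91 and 1.83, so about 1.9 at usual densities.
A permutation alternative (`permutation_threshold()`) permutes whole
phenotype rows, keeping an individual's environment vector together, and
reruns the entire pipeline per permutation.

## What the simulator emulates

`simulate_genotypes()` draws each chromosome as a Markov chain over the
merged marker-and-QTL loci with Haldane (no interference) transition
fractions — accumulated fractions for RIL, which is marginally
equivalent to iterating selfing generations and much cheaper.
Phenotypes add independent per-environment Gaussian noise scaled so that
the broad-sense heritability is `H2` in *every* environment:
`sigma2_h = V_G,h (1 − H2)/H2`, with the genetic variance from the
closed form `V_G,h = sum_j a_jh² + 2 sum_{j<j'} a_jh a_j'h (1 − 2 r_jj')`.
This per-environment convention reproduces the expected PVE of the
benchmark architectures (`arch_unlinked()`, `arch_linked()`) through the
oracle `expected_pve()`.  When an environment has zero genetic variance
(environment-specific architectures such as the linked model with
one-environment effects), its noise variance borrows the mean of the
other environments' noise levels so the trait is never noiseless there.

The defaults mirror the benchmark study conditions: DH populations of
n = 200 in 2 environments on a 900 cM genome, scan step 1 cM, stepwise
probabilities 0.001/0.002, genome-wide error 0.05 (LOD 3.11).  What the
simulator does *not* emulate: genotyping errors (only a missing-rate can
be imposed externally), field-plot structure and replicate measurements
within environments, non-Gaussian residuals, dominance and epistasis.
Passing tests on these simulations therefore validate the estimation
machinery, not robustness to those real-data complications.

## Numerical choices

* ECM stops when the log-likelihood changes by less than `1e-6`
  (`maxit = 200`; non-convergence is flagged, never silently accepted).
  Means are initialized from the two double-homozygote flanking groups,
  falling back to the overall mean ± half the pooled SD when a group is
  empty; the constrained fit starts from the centred initialization.
* The H2 constraint is enforced exactly *within* each CM step given the
  current variances; the final residual `sum_h (mu_1h − mu_2h)` is
  checked in the tests (`< 1e-5`).
* Degenerate scan positions on a marker collapse the group probabilities
  to indicators of that marker's genotype; recombinant flanking pairs
  (impossible at `r = 0`) inherit the coincident marker's genotype.
* Missing phenotype cells contribute their product over observed
  environments only; missing flanking genotypes fall back to the nearest
  informative markers of the chromosome (per-individual probabilities),
  and an individual with no informative marker on a chromosome is
  dropped from that chromosome's likelihood.
* Stepwise F-tests use partial (drop-one) sums of squares at removal;
  p-value ties break to the lower marker index, making selection
  deterministic.  Missing marker codes are imputed for the regression
  only, by the conditional expectation from the nearest informative
  flanking markers.
* A scan grid point shared by two intervals (a marker) is reported once,
  from the interval on its left; `Delta y` changes between intervals, so
  profiles are continuous within intervals by construction.
* The per-environment phenotypic variances in the PVE denominator use
  the raw (unadjusted) phenotypes with the 1/n convention.

## Evaluation harness and problem sizes

`call_peaks()` turns a profile into calls (one per maximal
above-threshold run, at its maximum, leftmost on ties).  This one-call-
per-run convention is deliberately conservative for power scoring: when
a broad above-threshold run's maximum drifts a couple of centiMorgans
past the support-interval boundary, the replicate is scored as a miss
*and* a false positive even though the profile exceeds the threshold
inside the interval — counting every local maximum instead would raise
measured power by several points and roughly double the false-discovery
rate on the benchmark.  Comparisons across peak-calling conventions
should therefore fix the convention, not just the threshold.
After calling,
`power_fdr()` scores calls against a true architecture with ±5 cM
support intervals (a call in two overlapping intervals counts for the
nearest truth; several calls in one interval count once), and
`interval_power()` reports detection frequency per marker interval.
The packaged validation runs 200 replicates of the unlinked benchmark
and 500 null replicates for threshold calibration — large enough for
binomial standard errors of 2-3 percentage points on power and 1 point
on the null exceedance rate, and small enough to run on a laptop in
minutes; the original tables use 1000 replicates.

## Known limitations

* Two-genotype populations only; F2 (dominance) scanning and
  two-dimensional epistatic QEI scans are out of scope (only their
  threshold degrees-of-freedom rules are provided).
* The ×1.9 RIL expansion is a constant; strictly it varies with marker
  density (1.98 at 1 cM to 1.83 at 10 cM).
* The closed-form PVE oracle assumes locus frequencies of exactly 1/2
  and no segregation distortion.
* Estimated effects at a detected peak are conditional on detection and
  therefore slightly shrunk/selected relative to the truth — the
  benchmark tables show the same behaviour.
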