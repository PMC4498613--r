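# minimal hand-built profile rows
mk_profile <- function(chromosome, position, lod) {
  data.frame(chromosome = chromosome, position_cM = position, LOD = lod,
             LOD_A = lod / 2, LOD_AE = lod / 2,
             avg_effect = 0.5, ae_1 = 0.1, ae_2 = -0.1)
}

test_that("peak calling splits runs and respects chromosomes", {
  # all below threshold: no calls
  p <- mk_profile("1", 0:10, rep(1, 11))
  expect_equal(nrow(call_peaks(p, 3)), 0)
  # one unimodal hump: one call at the argmax
  p <- mk_profile("1", 0:10, c(0, 1, 3, 5, 7, 8, 7, 5, 3, 1, 0))
  pk <- call_peaks(p, 3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position_cM, 5)
  # two humps separated by a sub-threshold gap: two calls
  lod <- c(1, 4, 6, 4, 1, 1, 4, 7, 4, 1, 1)
  pk2 <- call_peaks(mk_profile("1", 0:10, lod), 3)
  expect_equal(pk2$position_cM, c(2, 7))
  # same shape split across chromosomes never merges
  pk3 <- call_peaks(mk_profile(rep(c("1", "2"), c(5, 6)), c(0:4, 0:5),
                               c(1, 4, 6, 6, 6, 6, 6, 4, 1, 1, 1)), 3)
  expect_equal(nrow(pk3), 2)
  # leftmost tie within a chromosome
  expect_equal(pk3$position_cM[1], 2)
  expect_equal(nrow(call_peaks(p[0, ], 3)), 0)
})

test_that("power and FDR bookkeeping", {
  truth <- qtl_architecture(c("1", "2"), c(20, 50),
                            rbind(c(0.5, 0.5), c(0.5, -0.5)))
  hit <- function(chr, pos, lod = 5)
    mk_profile(chr, pos, lod)
  # perfect calls in every replicate
  calls <- replicate(4, rbind(hit("1", 20), hit("2", 50)),
                     simplify = FALSE)
  rep1 <- power_fdr(calls, truth)
  expect_equal(rep1$per_qtl$power, c(100, 100))
  expect_equal(rep1$FDR, 0)
  expect_equal(rep1$n_calls, 8)
  # an off-interval call is a false positive; counting is conserved
  calls2 <- list(rbind(hit("1", 20), hit("1", 120)),
                 rbind(hit("2", 54)),
                 rbind(hit("2", 56)))   # 56 is outside +/- 5 cM of 50
  rep2 <- power_fdr(calls2, truth)
  expect_equal(rep2$per_qtl$power, c(100 / 3, 100 / 3))
  expect_equal(rep2$n_false, 2)
  expect_equal(rep2$FDR, 100 * 2 / 4)
  expect_equal(rep2$n_calls,
               rep2$n_false + sum(!is.na(rep2$per_qtl$power)) * 0 + 2)
  # no truth: any call is false
  rep3 <- power_fdr(list(hit("1", 10)),
                    qtl_architecture(character(0), numeric(0),
                                     matrix(numeric(0), 0, 2)))
  expect_equal(rep3$FDR, 100)
  expect_null(rep3$per_qtl)
  # estimates averaged over detecting calls only
  calls4 <- list(rbind(hit("1", 19)), rbind(hit("1", 22)))
  rep4 <- power_fdr(calls4, truth)
  expect_equal(rep4$per_qtl$position_cM_mean[1], 20.5)
  expect_true(is.na(rep4$per_qtl$position_cM_mean[2]))
})

test_that("overlapping support intervals assign a call to the nearest truth", {
  truth <- qtl_architecture(c("1", "1"), c(20, 27),
                            rbind(c(0.5, 0.5), c(0.5, 0.5)))
  calls <- list(mk_profile("1", 25, 6))   # within 5 cM of both
  r <- power_fdr(calls, truth)
  expect_equal(r$per_qtl$power, c(0, 100))  # 25 is nearer to 27
  expect_equal(r$FDR, 0)
})

test_that("interval attribution of calls", {
  map <- genetic_map(paste0("m", 1:4), rep(1, 4), c(0, 10, 20, 30))
  calls <- list(mk_profile("1", 5, 6),      # inside interval 1
                mk_profile("1", 10, 6),     # at a marker: right interval
                mk_profile("1", 30, 6))     # chromosome end: last interval
  ip <- interval_power(calls, map)
  expect_equal(nrow(ip), 3)
  expect_equal(ip$frequency, c(100 / 3, 100 / 3, 100 / 3))
  # no calls at all
  ip0 <- interval_power(list(mk_profile("1", 5, 6)[0, ]), map)
  expect_equal(ip0$frequency, c(0, 0, 0))
})
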