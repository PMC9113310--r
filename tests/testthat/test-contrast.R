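test_that("one-tailed Wilcoxon matches exact enumeration and handles degeneracy", {
  # extreme arrangement: 1 of choose(6,3) = 20 equally likely rank splits
  expect_equal(wilcoxon_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  expect_equal(wilcoxon_one_tailed(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
  # identical samples carry no one-sided evidence
  expect_gte(wilcoxon_one_tailed(c(1, 3, 7), c(1, 3, 7), "greater"), 0.5)
  # fully tied data never produces NaN
  expect_equal(wilcoxon_one_tailed(rep(2, 5), rep(2, 7), "greater"), 1)
  # exact and normal-approximation paths agree closely for moderate n
  set.seed(20)
  dis <- replicate(200, {
    a <- rnorm(15); b <- rnorm(15)
    pe <- wilcoxon_one_tailed(a, b, "greater", exact_max_n = 25)
    pn <- wilcoxon_one_tailed(a, b, "greater", exact_max_n = 0)
    (pe < 0.01) != (pn < 0.01)
  })
  expect_lt(mean(dis), 0.05)
})

test_that("rank-biserial correlation has the documented sign convention", {
  expect_equal(rank_biserial(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(rank_biserial(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(rank_biserial(c(1, 2), c(4, 5)),
               -rank_biserial(c(4, 5), c(1, 2)))
  set.seed(21)
  r0 <- replicate(200, rank_biserial(rnorm(30), rnorm(30)))
  expect_lt(abs(mean(r0)), 0.03)
})

test_that("Storey-Tibshirani FDR estimates pi0 and controls the FDP", {
  # overwhelming signal: everything flagged
  s <- storey_fdr(rep(1e-6, 50), q = 0.05)
  expect_true(all(s$significant))
  # uniform null: pi0 near 1 (single draw, loose band)
  set.seed(22)
  s0 <- storey_fdr(runif(1128), q = 0.01)
  expect_gt(s0$pi0, 0.8)
  expect_lte(s0$pi0, 1)
  expect_equal(s0$n_expected_false, 11L)
  # q-values are monotone in p
  o <- order(runif(200))
  p <- sort(rbeta(200, 0.5, 5))
  qv <- storey_fdr(p, q = 0.05)$qvalues
  expect_true(all(diff(qv) >= -1e-12))
  # fallback with too few tests
  expect_equal(storey_fdr(runif(10), q = 0.05)$pi0, 1)
  # realized false-discovery proportion controlled on a 90/10 mixture
  fdp <- replicate(40, {
    p <- c(runif(900), rbeta(100, 0.05, 10))
    truth <- rep(c(TRUE, FALSE), c(900, 100))
    s <- storey_fdr(p, q = 0.05)
    if (!any(s$significant)) 0 else mean(truth[s$significant])
  })
  expect_lt(mean(fdp), 0.05 + 0.03)
})

test_that("edgewise contrast recovers planted shifts with calibrated density", {
  set.seed(23)
  nE <- 200; nB <- 3
  a <- gaussian_tensor(nE, 20, nB, shift_rows = 1:20, shift_bands = 2,
                       shift = 1.8)
  b <- gaussian_tensor(nE, 20, nB)
  ct <- edgewise_contrast(a, b, alpha = 0.01, q = 0.01)
  s <- ct$summary
  kg <- s[s$direction == "greater", ]
  expect_lt(abs(kg$K[2] - 0.10), 0.03)
  expect_lt(mean(kg$K[c(1, 3)]), 0.03)
  expect_equal(s$n_expected_false, rep(floor(0.01 * nE), nrow(s)))
  # the two direction masks are disjoint and K sums below 1
  for (bnd in 1:nB) {
    expect_false(any(ct$sig[, bnd, "greater"] & ct$sig[, bnd, "less"]))
    expect_lte(sum(s$K[s$band == bnd]), 1)
  }
  # effect size over significant edges is strong and in [0, 1]
  expect_gt(kg$effect_size[2], 0.5)
  expect_lte(kg$effect_size[2], 1)
  # monotonicity: a stronger shift never lowers the matching density
  a2 <- gaussian_tensor(nE, 20, nB, shift_rows = 1:20, shift_bands = 2,
                        shift = 0.8)
  ct2 <- edgewise_contrast(a2, b, alpha = 0.01, q = 0.01)
  expect_lte(ct2$summary$K[ct2$summary$direction == "greater"][2], kg$K[2])
  # undefined edges are dropped listwise per edge
  a3 <- a; a3[5, 1:3, 2] <- NA
  ct3 <- edgewise_contrast(a3, b, alpha = 0.01, q = 0.01)
  expect_equal(ct3$summary$n_valid[ct3$summary$band == 2][1], nE)
  a4 <- a; a4[5, , 2] <- NA               # whole edge gone in one band
  ct4 <- edgewise_contrast(a4, b, alpha = 0.01, q = 0.01)
  expect_equal(ct4$summary$n_valid[ct4$summary$band == 2][1], nE - 1)
})

test_that("age-confound check pools states within group before BH", {
  set.seed(24)
  n <- 30
  age <- list(EP = list(AS = rnorm(n, 41, 1.4), QS = rnorm(n, 41, 1.4)))
  # band 1 strength strictly increasing in age -> rho = 1, flagged
  mk <- function(a) cbind(2 * a + 10, rnorm(n))
  strengths <- list(EP = list(AS = mk(age$EP$AS), QS = mk(age$EP$QS)))
  res <- age_confound_check(strengths, age)
  r1 <- res[res$band == 1, ]
  expect_equal(r1$rho, c(1, 1))
  expect_true(all(r1$flagged))
  # BH adjustment pools the two states: 4 tests per group
  expect_equal(sum(res$group == "EP"), 4)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  # constant strength is reported as undefined
  strengths$EP$AS[, 2] <- 1
  res2 <- age_confound_check(strengths, age)
  expect_true(is.na(res2$rho[res2$state == "AS" & res2$band == 2]))
})
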