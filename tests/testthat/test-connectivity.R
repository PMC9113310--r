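test_that("analytic signal has the defining properties", {
  tt <- (1:2000) / 100
  x <- cos(2 * pi * 5 * tt)
  z <- analytic_signal(x)
  expect_equal(Re(z), x, tolerance = 1e-10, ignore_attr = TRUE)
  # argument advances at 2*pi*f per second (away from epoch edges)
  ph <- diff(Arg(z[200:1800]))
  ph <- (ph + pi) %% (2 * pi) - pi
  expect_equal(mean(ph) * 100, 2 * pi * 5, tolerance = 1e-3)
  expect_equal(mean(Mod(z[200:1800])), 1, tolerance = 1e-3)
  # degenerate (constant) rows are flagged
  m <- rbind(x, 0)
  expect_equal(unname(attr(analytic_signal(m), "degenerate")),
               c(FALSE, TRUE))
})

test_that("dwpli equals the brute-force pairwise-product oracle", {
  set.seed(10)
  for (n in c(20, 57, 200)) {
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    y <- complex(real = rnorm(n), imaginary = rnorm(n))
    expect_equal(dwpli(x, y), oracle_dwpli(x, y), tolerance = 1e-10)
    # the Rcpp all-pairs kernel agrees with the scalar path
    M <- neoconn:::dwpli_all_pairs(rbind(x, y))
    expect_equal(M[1, 2], dwpli(x, y), tolerance = 1e-12)
    expect_equal(M[1, 2], M[2, 1])
  }
  expect_error(dwpli(1:3 + 0i, 1:4 + 0i), "equal length")
})

test_that("dwpli is undefined at zero lag and converges to 1 at a constant quarter-cycle lag", {
  set.seed(11)
  x <- analytic_signal(rnorm(500))
  expect_true(is.na(dwpli(x, x)))                      # identical signals
  expect_true(is.na(dwpli(x, 3.7 * x)))                # zero-lag scaled copy
  p <- coupled_pair(30000, noise = 0.15)
  expect_gt(dwpli(p$x, p$y), 0.9)
})

test_that("dwpli invariances: scaling, exchange symmetry, volume conduction", {
  set.seed(12)
  p <- coupled_pair(4000, noise = 0.3)
  v <- dwpli(p$x, p$y)
  expect_equal(dwpli(2.5 * p$x, 0.1 * p$y), v, tolerance = 1e-12)
  # the squared-type debiased estimator is even in the imaginary cross-terms,
  # so exchanging the signals (reversing the lag) leaves it unchanged
  expect_equal(dwpli(p$y, p$x), v, tolerance = 1e-12)
  # independent signals: mean near 0 (the debiased estimator retains only a
  # small finite-sample bias of order correlation-time / N on narrow-band
  # input; the tight +/-0.02 check at full epoch length lives in the
  # acceptance suite)
  null_vals <- replicate(50, {
    a <- analytic_signal(drop(apply_band(matrix(rnorm(4000), 1),
                                         data.frame(f_lo = 4, f_hi = 6), 100)))
    b <- analytic_signal(drop(apply_band(matrix(rnorm(4000), 1),
                                         data.frame(f_lo = 4, f_hi = 6), 100)))
    dwpli(a, b)
  })
  expect_lt(abs(mean(null_vals)), 0.05)
  # zero-lag mixing of independent sources (volume conduction) stays near 0
  mix <- replicate(50, {
    s1 <- drop(apply_band(matrix(rnorm(4000), 1),
                          data.frame(f_lo = 4, f_hi = 6), 100))
    s2 <- drop(apply_band(matrix(rnorm(4000), 1),
                          data.frame(f_lo = 4, f_hi = 6), 100))
    ch1 <- 0.8 * s1 + 0.2 * s2
    ch2 <- 0.3 * s1 + 0.7 * s2
    dwpli(analytic_signal(ch1), analytic_signal(ch2))
  })
  expect_lt(abs(mean(mix)), 0.06)
})

test_that("subject adjacency recovers a planted pair and is relabeling-equivariant", {
  bank <- build_filter_bank()[c(10, 12, 14), ]
  eff <- planted_effect(2, "AS", matrix(c(3, 7), 1))
  spec <- cohort_spec(n_ep = 2, n_hc = 2, n_parcels = 10, duration_s = 40,
                      bank = bank, states = "AS", effects = list(eff),
                      score_models = list(), mask_density = 1, seed = 3)
  subj <- list(subject_id = "S1", group = "EP", ca_weeks = 41)
  ep <- generate_epoch(spec, subj, "AS", couplings = 0.9, seed = 21)
  adj <- subject_adjacency(ep, bank)
  A <- adj$values[, , 2]
  ed <- edge_table(10)
  ev <- A[cbind(ed$i, ed$j)]
  expect_equal(which.max(ev), which(ed$i == 3 & ed$j == 7))
  expect_equal(A, t(A))
  expect_equal(adj$n_edges_total, 45)
  # permuting parcels permutes rows/columns identically
  perm <- c(4, 1, 3, 2, 5, 10, 7, 8, 9, 6)
  ep2 <- ep; ep2$parcels <- ep$parcels[perm, ]
  A2 <- subject_adjacency(ep2, bank)$values[, , 2]
  expect_equal(A2, A[perm, perm], tolerance = 1e-12)
})

test_that("fidelity mask bookkeeping matches the 58-parcel configuration", {
  expect_equal(nrow(edge_table(58)), 1653)
  ones <- matrix(1, 58, 58); diag(ones) <- 0
  expect_equal(fidelity_mask(ones)$n_valid_edges, 1653)
  set.seed(4)
  mk <- random_fidelity_mask(58)
  expect_equal(mk$n_valid_edges, 1128)
  # forced edges always included
  inc <- matrix(c(1, 2, 5, 9), 2, byrow = TRUE)
  mk2 <- random_fidelity_mask(58, include = inc)
  expect_equal(mk2$mask[1, 2], 1)
  expect_equal(mk2$mask[5, 9], 1)
  # asymmetric mask rejected
  bad <- ones; bad[1, 2] <- 0
  expect_error(fidelity_mask(bad), "symmetric")
  # all-zero mask: no valid edges downstream
  z <- fidelity_mask(matrix(0, 6, 6))
  expect_equal(z$n_valid_edges, 0)
  ep <- subject_epoch("a", "EP", "AS", 41, 100,
                      matrix(rnorm(6 * 3000), 6))
  adj <- subject_adjacency(ep, build_filter_bank()[12, , drop = FALSE])
  masked <- apply_fidelity_mask(adj, z)
  expect_true(all(is.na(masked$values)))
})
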