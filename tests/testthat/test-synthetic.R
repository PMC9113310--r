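small_bank <- function(rows = c(10, 12, 14)) build_filter_bank()[rows, ]

test_that("cohort generation is deterministic and respects the requested design", {
  bank <- small_bank()
  eff <- planted_effect(2, "AS", matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
  spec <- cohort_spec(n_ep = 3, n_hc = 4, n_parcels = 8, duration_s = 12,
                      bank = bank, states = c("AS", "QS"),
                      effects = list(eff), score_models = list(),
                      mask_density = 0.8, seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$subjects), 7)
  expect_equal(table(c1$subjects$group)[["EP"]], 3)
  expect_equal(names(c1$epochs), c("AS", "QS"))
  expect_equal(dim(c1$epochs$AS[[1]]$parcels), c(8, 1200))
  # mask density honored and planted edges forced in
  expect_equal(c1$mask$n_valid_edges, round(0.8 * 28))
  expect_equal(c1$mask$mask[1, 2], 1)
  expect_equal(c1$mask$mask[3, 4], 1)
})

test_that("paper-scale metadata comes out at the requested cohort sizes", {
  spec <- cohort_spec(n_ep = 46, n_hc = 67, n_parcels = 8, duration_s = 6,
                      bank = small_bank(), states = "AS",
                      effects = list(planted_effect(1, "AS",
                                                    matrix(c(1, 2), 1))),
                      seed = 2)
  ch <- generate_cohort(spec)
  expect_equal(sum(ch$subjects$group == "EP"), 46)
  expect_equal(sum(ch$subjects$group == "HC"), 67)
  expect_equal(mean(ch$subjects$ca_weeks), 41.4, tolerance = 0.5)
  # clinical table: one row per subject and score model
  expect_equal(nrow(ch$clinical),
               113 * length(spec$score_models))
  expect_true(all(c("C1_motor") %in% ch$clinical$score_name))
})

test_that("planted coupling is band-local and sensitive to the lag", {
  bank <- build_filter_bank()[c(8, 10, 12, 14, 16), ]
  eff <- planted_effect(3, "AS", matrix(c(3, 7), 1))
  spec <- cohort_spec(n_ep = 2, n_hc = 2, n_parcels = 10, duration_s = 60,
                      bank = bank, states = "AS", effects = list(eff),
                      score_models = list(), mask_density = 1, seed = 13)
  subj <- list(subject_id = "S1", group = "EP", ca_weeks = 41)
  vals <- sapply(1:4, function(r) {
    ep <- generate_epoch(spec, subj, "AS", couplings = 0.95, seed = 100 + r)
    subject_adjacency(ep, bank)$values[3, 7, ]
  })
  m <- rowMeans(vals)
  # near-locked coupling: strong at the planted band, absent two bands away
  expect_gt(m[3], 0.8)
  expect_lt(abs(m[1]), 0.15)
  expect_lt(abs(m[5]), 0.15)
  # zero-lag variant: high amplitude covariation but no dwPLI
  eff0 <- planted_effect(3, "AS", matrix(c(3, 7), 1), lag = 0)
  spec0 <- cohort_spec(n_ep = 2, n_hc = 2, n_parcels = 10, duration_s = 60,
                       bank = bank, states = "AS", effects = list(eff0),
                       score_models = list(), mask_density = 1, seed = 13)
  v0 <- replicate(4, {
    ep <- generate_epoch(spec0, subj, "AS", couplings = 0.95)
    subject_adjacency(ep, bank)$values[3, 7, 3]
  })
  v0 <- v0[!is.na(v0)]
  expect_lt(mean(abs(v0)), 0.1)
  # coupling out of the attainable range is rejected at spec construction
  expect_error(cohort_spec(base_coupling = 0.9, n_parcels = 10,
                           bank = small_bank(), states = "AS",
                           effects = list(eff), seed = 1),
               "attainable")
})

test_that("planted-edge mean dwPLI grows monotonically with the coupling delta", {
  bank <- small_bank()
  eff <- function(d) planted_effect(2, "AS", matrix(c(2, 5, 3, 8), 2,
                                                    byrow = TRUE),
                                    coupling_delta = d)
  subj <- list(subject_id = "S1", group = "EP", ca_weeks = 41)
  m <- vapply(c(0, 0.2, 0.4), function(d) {
    spec <- cohort_spec(n_ep = 2, n_hc = 2, n_parcels = 10, duration_s = 40,
                        bank = bank, states = "AS", effects = list(eff(d)),
                        base_coupling = 0.3, coupling_sd = 0.05,
                        score_models = list(), mask_density = 1, seed = 17)
    vals <- replicate(5, {
      ep <- generate_epoch(spec, subj, "AS",
                           couplings = 0.3 + d, seed = NULL)
      subject_adjacency(ep, bank)$values[2, 5, 2]
    })
    mean(vals)
  }, 0)
  expect_true(all(diff(m) > 0))
})

test_that("background noise follows the requested 1/f spectral slope", {
  set.seed(44)
  for (beta in c(1, 2)) {
    sp <- rowMeans(replicate(8, {
      x <- one_over_f_noise(4096, beta)
      Mod(fft(x))[2:400]^2
    }))
    f <- (1:399) / 4096
    fit <- lm(log(sp) ~ log(f))
    expect_equal(unname(coef(fit)[2]), -beta, tolerance = 0.15)
  }
})
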