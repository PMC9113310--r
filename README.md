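# neoconn

Frequency-resolved cortical phase-coupling network analysis for neonatal
sleep EEG.

Preterm birth perturbs the developing brain's functional networks, and
those perturbations are visible in scalp EEG recorded around
term-equivalent age — but only when connectivity is resolved finely in
frequency and tested edge by edge across the cortical network. `neoconn`
implements that analysis end to end for two-group infant cohorts (e.g.
early-preterm vs healthy controls, recorded in active and quiet sleep),
together with a synthetic-cohort generator that plants known effects so
every stage of the pipeline is testable without any recorded data.

## The method

Conditioned signals (0.15–45 Hz zero-phase Butterworth prefilter,
resampled to 100 Hz, average montage) are decomposed into 21 narrow bands
with center frequencies Fc(i) = 1.2 × Fc(i−1) from Fc(1) = 0.5 Hz and
cutoffs 0.85/1.15 × Fc, spanning ≈ 0.4–22 Hz. For each subject, band and
sleep state, phase coupling between all pairs of P = 58 cortical parcels
(1653 pairs) is estimated on the whole epoch with the debiased weighted
phase-lag index computed from the per-sample analytic cross-spectral
terms X_t = x_t · conj(y_t), I_t = Im(X_t):

    dwPLI = [ (Σ I_t)² − Σ I_t² ] / [ (Σ |I_t|)² − Σ I_t² ]

dwPLI is insensitive to zero-lag (volume-conducted) coupling and, after
debiasing, independent signals average to zero. A binary fidelity mask
keeps the 1128 reliably estimable pairs. Group differences are tested
edgewise with two one-tailed Wilcoxon rank-sum scans (α = 0.01) and
summarized as the network density K — the fraction of valid edges crossing
the threshold — with the Storey–Tibshirani adaptive-FDR expected-false
bound (⌊0.01 × 1128⌋ = 11 edges) reported alongside and rank-biserial
effect sizes; a network-based statistic (t > 2.5, max-component-extent
permutation test) cross-checks the findings. Clinical outcome scores are
correlated with edge strengths by rank-based partial Spearman correlation
with conceptional age as covariate (α = 0.05, adaptive FDR at q = 0.05
within each correlation sign).

## Worked example

A reduced synthetic cohort: 12 + 12 subjects, 16 parcels, 60-s epochs, a
5-band sub-bank, and one planted effect — a theta-range network
oscillation coupling two parcel groups (12 edges ≈ 11% of the masked
network) more strongly in the EP group, plus a cognitive score driven by
the same edges.

```r
library(neoconn)

bank <- build_filter_bank()
bank[c(1, 2, 14, 21), ]
#>  index     fc   f_lo   f_hi
#>      1  0.500  0.425  0.575
#>      2  0.600  0.510  0.690
#>     14  5.350  4.547  6.152
#>     21 19.169 16.293 22.044

set.seed(7)
eff <- planted_effect(3, "AS", direction = "greater",
                      groups = bipartite_groups(16, 12))
spec <- cohort_spec(n_ep = 12, n_hc = 12, n_parcels = 16, duration_s = 60,
                    bank = build_filter_bank()[10:14, ], states = "AS",
                    effects = list(eff),
                    score_models = list(list(score = "C2_cognitive",
                      effect = 1L, n_driver = 12L, beta = 1,
                      covariate_weight = 0.1, noise_sd = 0.2)),
                    mask_density = 0.9, seed = 7)
res <- run_pipeline(spec)
res
#> PPC network pipeline: 12 EP + 12 HC, 108 valid edges, 5 bands (10.1 s)
#> Largest group-contrast densities:
#>  state band direction      K n_sig
#>     AS    2   greater 0.1204    13
#>     AS    3   greater 0.1204    13
#>     AS    4   greater 0.1111    12
#>     AS    2      less 0.0185    2
#> Largest clinical-correlation densities:
#>             scan band      K
#>  C2_cognitive_AS    2 0.1574
#>  C2_cognitive_AS    4 0.1481
#>  C2_cognitive_AS    3 0.1389
#>  C2_cognitive_AS    5 0.0370
```

Reading the output: the planted effect sits at band 3 of the sub-bank and
the EP > HC density K peaks at ≈ 11–12% in bands 2–4 — the planted band
and its direct neighbors, which genuinely share a narrow-band effect in a
bank whose bands overlap by ~50% — while the opposite direction stays at
the α level (≈ 2%). The clinical scan shows the same band neighborhood
correlating with the score that was generated from the planted edges.
`plot(res$contrasts$AS, fc = spec$bank$fc)` draws the K-vs-frequency
curves with the FDR band, and `write_results(res, "out/")` exports the
density tables and edge-level statistics as CSV.

Real recordings enter the same way: build a `subject_epoch()` per subject
and state from a channel/parcel matrix (after `condition_broadband()` for
raw multichannel data), then `subject_adjacency()`,
`apply_fidelity_mask()`, and the scan functions, or assemble a cohort list
and call the pipeline stages directly.

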