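---
title: "Frequency-resolved phase-coupling networks in neonatal EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved phase-coupling networks in neonatal EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`neoconn` implements a frequency-resolved functional-connectivity analysis
for multichannel neonatal sleep EEG. Conditioned signals are decomposed by a
geometric filter bank of 21 narrow bands; phase coupling between all pairs
of cortical parcels is estimated with the debiased weighted phase-lag index
(dwPLI); unreliable parcel pairs are removed by a binary fidelity mask; and
the resulting subject-by-band adjacency structure is mined three ways:
edgewise two-group rank-sum contrasts summarized by network density *K*
with Storey–Tibshirani adaptive FDR bounds, a network-based statistic (NBS)
permutation cross-check, and covariate-adjusted Spearman correlation of
edge strengths against clinical outcome scores. Because no compatible
infant EEG is bundled, the package ships a synthetic-cohort generator with
planted, known ground truth against which every stage is tested.

# Signal conditioning

Raw multichannel EEG (typically 19 channels of the 10–20 layout at 250 Hz)
is band-passed 0.15–45 Hz with a 7th-order Butterworth high-/low-pass pair,
resampled to 100 Hz, and re-referenced to the average montage. All IIR
filtering in the package is applied forward–backward, so the net transfer
function is the squared magnitude response with zero phase — a requirement
for phase-coupling analysis, where any residual group delay would
masquerade as lag.

Three numerical choices deserve a note:

* **Second-order sections.** At 250 Hz the 0.15 Hz high-pass corresponds to
  a normalized cutoff of 0.0012. An expanded transfer-function polynomial
  of order 7 is numerically unusable there (the rounded coefficients place
  effective poles outside the unit circle and the output diverges), so all
  filters are designed as analytic Butterworth pole cascades and applied as
  biquads (`butter_sos()`), which is stable at every cutoff the bank needs.
* **Reflection padding.** Forward–backward filtering needs state run-in.
  Each pass works on the signal extended by odd (antisymmetric) reflection
  over 3 cycles of the high-pass cutoff on both ends, then trimmed. Inputs
  shorter than the padding are rejected with an explicit error rather than
  silently truncated, and a test verifies the central 90% of an epoch is
  invariant to doubling the padding.
* **Fourier resampling.** Resampling is done by spectral truncation
  (`fft_resample()`): zero-phase by construction, with an ideal anti-alias
  cutoff. A polyphase FIR resampler was rejected because its group delay
  must be compensated exactly; spectrum truncation needs no compensation
  and is the natural choice for fixed, finite epochs. Periodicity artifacts
  are confined to the epoch ends, which downstream edge-trimming discards.

# The filter bank

Center frequencies follow the recursion Fc(i) = 1.2 × Fc(i−1) from
Fc(1) = 0.5 Hz, for 21 bands; each band spans 0.85 × Fc to 1.15 × Fc.
This yields constant relative bandwidth — bands of equal width on a
logarithmic axis, adjacent bands overlapping — covering approximately
0.4–22 Hz. The implementation follows the exact factor formulas; the
roughly-50%-overlap description is a consequence, not an input.

The per-band filter order is not dictated by the design, so the package
must choose. The default is a 6th-order high/low-pass pair per band:
steep enough that bands two steps apart (whose passbands are separated by
only ~6% in frequency at ratio 1.2) are well isolated after the
forward–backward pass, while remaining stable in SOS form even for band 1
(0.425–0.575 Hz at fs = 100), the numerically hardest case, which a test
exercises directly. The two-pass center gain with these cutoffs is ≈ 0.74;
it is uniform across bands and irrelevant to phase metrics.

# dwPLI estimation

For each band the parcel signals are narrow-band filtered, converted to
analytic signals by FFT Hilbert transform, and trimmed by 2 cycles of the
band center frequency at each end (absorbing both filter and Hilbert edge
effects). The per-sample cross-spectral terms between parcels x and y are
X_t = x_t·conj(y_t) with imaginary parts I_t, and the debiased estimator is

$$\mathrm{dwPLI} = \frac{(\sum_t I_t)^2 - \sum_t I_t^2}
                        {(\sum_t |I_t|)^2 - \sum_t I_t^2},$$

the ratio of sums over all ordered pairs of distinct observations of
I_j·I_k and |I_j·I_k| (a brute-force double-loop oracle verifies this
identity in the tests). Properties that matter here:

* Zero-lag (volume-conducted) coupling has all I_t = 0; the estimator is
  undefined and the edge is recorded as invalid — never ±∞. Edges with a
  near-zero denominator or a degenerate (constant) parcel are handled the
  same way.
* The estimator is a *squared-type* quantity: it is even in I, so
  reversing the lag direction (conjugating one signal) leaves it
  unchanged. Negative values arise only from sampling variability under
  weak coupling, not from lag direction.
* **Observation unit.** The whole-epoch estimate uses per-sample analytic
  cross-terms (the Hilbert framework) rather than short-time spectral
  segments; this maximizes the number of observations at low frequencies
  where a 5-minute epoch holds few cycles. A windowed variant would
  trade bias for variance; it is deliberately not implemented.
* **Finite-sample bias.** Debiasing removes the j = k diagonal, but
  narrow-band analytic signals are autocorrelated over roughly fs/BW
  samples, so near-diagonal terms leave a residual positive bias of order
  (correlation time)/N under independence — about 0.05 at 15 s of data,
  0.003 at 5 minutes for a 2 Hz-wide band. The tests account for this:
  the tight null check (mean within ±0.02 of zero over 200 independent
  pairs) runs at full epoch length.

Signed estimates are kept in storage and used raw (not absolute) in all
statistics.

# Fidelity mask

Parcel pairs whose coupling cannot be reliably estimated from the sensor
layout are excluded by a symmetric binary mask before any statistics; in
the reference 58-parcel configuration 1128 of the 1653 pairs survive. The
mask is an *input* here (or synthetically generated at the matching
density); deriving it by forward/inverse head-model simulation is outside
the package's scope.

# Edgewise group contrast

For every band and sleep state, each valid edge is tested with the
Wilcoxon rank-sum test as two separate one-tailed scans (EP > HC and
EP < HC) at α = 0.01 — not a split two-tailed test. Exact p-values are
used when min(n) ≤ 25 with no ties; otherwise the normal approximation
with mid-rank tie correction. Fully degenerate input returns p = 1. Within
an edge, subjects with an undefined value are dropped; an edge with fewer
than 2 subjects per group is invalid.

The density *K* is the fraction of valid edges with p < α, using raw α
thresholding. The Storey–Tibshirani adaptive FDR at q = 0.01 is reported
*alongside* as the expected-false-discovery bound (⌊q·N⌋ = 11 edges at
N = 1128), mirroring the presentation of K against a q-level band; K is
deliberately not FDR-pruned. π₀ is estimated with the smoother method
(λ grid 0.05–0.95 step 0.05, cubic smoothing spline with 3 df evaluated at
λ = 0.95, clamped to (0, 1]); with fewer than 20 p-values the estimate
falls back conservatively to π₀ = 1. Effect size per contrast is the
modulus of the mean rank-biserial correlation, r = 2U/(n₁n₂) − 1 with ties
counting one half, over the significant edges.

The age-confound check correlates each subject's global mean strength with
conceptional age (two-tailed Spearman) per group, state and band, pools
the two sleep states within each group, and applies Benjamini–Hochberg at
α = 0.05.

# Network-based statistic

The NBS cross-check thresholds per-edge two-sample t-statistics
(pooled-variance form, the classical NBS default) at t = 2.5, finds
connected components of the suprathreshold graph in topological space, and
compares each component's *extent* (edge count) against the permutation
distribution of the maximal extent under group-label shuffling (5000
permutations by default; the permutation p-value carries the +1 correction
so it is always valid). Zero-variance edges are excluded; cohorts with
fewer distinct label assignments than requested permutations are fully
enumerated with a warning. The NBS runs on the fidelity-masked edge set,
consistent with the primary analysis. Observed components are extracted
with igraph and the permutation null uses a union-find kernel; both are
checked against an independent union-find oracle.

A practical caveat the calibration tests made explicit: with few
suprathreshold edges the max-extent null is coarsely discrete and the test
becomes conservative (family-wise error well below nominal). At the full
58-parcel network with t = 2.5 the realized FWER is close to 0.05, which
is where the calibration suite runs.

# Clinical correlation

Edge strengths across subjects are correlated with clinical scores
(two-tailed, α = 0.05) with conceptional age as a covariate. "With CA as a
covariate" is implemented as a rank-based partial correlation: all three
variables are rank-transformed and the first-order partial correlation of
the ranks is computed (equivalently, correlation of rank residuals after
linear removal of the ranked covariate) — this preserves the Spearman
character of the test; a semipartial variant is deliberately not used. The
two-tailed p-value uses the t approximation with n − 3 degrees of freedom.
Missing scores are dropped listwise per score, so per-score n varies.

Significant edges are split by correlation sign. The Storey–Tibshirani FDR
at q = 0.05 is run separately within the positive-ρ and the negative-ρ
test sets: each set is about half the network, so each bounds about 2.5%
of the full network as potential false discoveries. K counts both signs
over valid edges; effect sizes are the mean ρ over each signed significant
set.

Composite neonatal scores are the first two principal components of the
standardized three-item neurological battery, sign-aligned so each
component's loading on the first item is nonnegative (the sign of a
principal component is otherwise arbitrary); C1 is the motor-linked and C2
the cognition-linked composite by post hoc assignment. An
eigendecomposition oracle on a fixed toy table pins the convention down in
the tests.

# The synthetic cohort generator

The generator emulates the *statistical structure* the analysis assumes:
two groups (46 EP, 67 HC by default), two sleep states, conceptional age
41.4 ± 1.4 weeks, 58 parcels × 5 minutes at 100 Hz, a fidelity mask at
density 1128/1653 (planted edges always included), planted frequency- and
state-specific group differences, and clinical scores generated as noisy
increasing functions of planted coupling strength plus a CA term.

Each parcel signal is unit-variance 1/f noise (spectrally shaped white
noise; a log–log regression test confirms the slope). Planted coupling
injects a shared band-limited oscillation — complex Gaussian noise
spectrally confined to the core (0.92–1.08 × Fc) of the effect band — into
both parcels of an edge with a constant quarter-cycle lag and independent,
slowly varying Gaussian phase jitter per parcel. Design choices worth
recording:

* **Jitter → coupling mapping.** The coupling parameter c ∈ (0, 1) maps to
  jitter standard deviation σ = √(−log c), the closed form for which the
  phase-locking of two independently jittered copies equals c. A
  simulation-calibrated lookup table was considered and rejected: the
  closed form is monotone, invertible and needs no stored state. Tests
  only require monotonicity, which holds for the dwPLI readout as well.
* **Spectral confinement.** The jitter is white noise smoothed with a
  *Gaussian* kernel (8 cycles of Fc wide), because kernels with slowly
  decaying spectral tails (e.g. running means) let the phase-modulation
  sidebands bleed into bands two steps away, where the shallow skirts of
  any realistic band-pass re-detect them. With Gaussian-tail confinement
  plus oscillators scaled relative to the *in-band* 1/f background
  (`osc_snr`, default 3), planted effects appear in the planted band and
  its directly overlapping neighbors — which genuinely share a
  narrow-band effect in a 50%-overlapping bank, just as the real analysis
  shows gradual changes across adjacent bands — and nowhere else.
* **Two planting mechanisms.** Sparse edge sets get one oscillator per
  edge; a parcel on several edges then mixes several independent
  oscillators, diluting each pairwise coupling — fine for a handful of
  edges, ruinous for dense sets. Dense sets (e.g. 10% of the network) use
  a *network oscillation*: one oscillation injected into two disjoint
  parcel groups, group b at the quarter-cycle lag, every parcel with its
  own jitter. The planted edges are exactly the between-group pairs;
  within-group pairs are coupled at zero lag, which dwPLI is blind to by
  design. Each parcel hosts one oscillator, so coupling strength does not
  dilute.
* **Group effects and heterogeneity.** The favored group's coupling is
  base + Δ (defaults 0.4 + 0.35) with between-subject SD 0.06, kept
  3 SDs below 1 so the jitter model stays attainable; an error reports
  the attainable range otherwise. The two default effects mirror the
  headline structure of the motivating findings: a theta-band (Fc ≈ 5.3
  Hz) effect in active sleep and a delta-band (Fc ≈ 1.8 Hz) effect in
  quiet sleep, both EP > HC, each ≈ 10% of valid edges.
* **Determinism.** The cohort is a pure function of its spec (including
  the seed); a test asserts byte-identical regeneration.

What the generator does *not* emulate: neonatal EEG morphology (tracé
alternant, delta brushes), true volume-conduction leakage geometry, source
reconstruction, sleep-stage physiology (states differ only in which
planted effects apply), or artifacts. Passing tests therefore demonstrate
that the estimators and statistics do what they claim on signals with the
assumed structure — not that the pipeline is robust to real-world
contamination, which remains the user's responsibility via epoch
selection.

# Problem sizes used by the test suite

The suite exercises reduced configurations chosen to keep the full run in
the minutes range while preserving the relevant regimes: unit tests use
8–16 parcels, 12–60 s epochs and 3–6 bands; the end-to-end recovery check
uses the full 58-parcel network with 20 + 20 subjects, 60-s epochs and a
6-band sub-bank around the planted frequency; statistical calibration uses
10 000 null edges (Wilcoxon), 500 NBS replicates at 1000 permutations on
the full 1653-edge network, and 10 000 partial-Spearman replicates at
n = 36. The dwPLI null check runs 200 pairs at the full 5-minute epoch
length, where the finite-sample bias is negligible.

# Known limitations

* The dwPLI estimate on short epochs carries the positive finite-sample
  bias described above; comparisons between groups are unaffected (both
  carry it equally), but absolute values on epochs much shorter than a
  minute should not be over-interpreted.
* Zero-lag-coupled pairs with group-dependent jitter can show a small
  group difference through that same finite-sample mechanism, although
  their population dwPLI is zero for both groups.
* The NBS is conservative when the suprathreshold graph is very sparse
  (coarse max-extent null).
* EDF ingestion is not included; the pipeline-native input is the
  channel/parcel matrix interface (`subject_epoch()`), and real recordings
  should be converted upstream.
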