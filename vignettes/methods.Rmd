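---
title: "Methods: synthetic EEG cohorts, phase-coupling features, and explained classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG cohorts, phase-coupling features, and explained classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegfc)
```

# Overview

`eegfc` implements a complete resting-state EEG group-analysis pipeline
for the 19-electrode 10–20 montage at 250 Hz: broadband and band-specific
FIR filtering, Fz re-referencing, 2-s epoching of eyes-closed data, Welch
band-power features, PLV/ciPLV phase-coupling features, mass-univariate
Wilcoxon statistics under Benjamini–Hochberg FDR control, Friedman tests,
and an L2 logistic-regression classifier with nested cross-validation,
leave-one-out predictions and correlation-respecting Shapley
explanations. Because clinical recordings of the motivating ASD/TD cohort
are not openly deposited, the package ships a first-class synthetic
cohort generator with known spectral and coupling ground truth; every
downstream claim the test suite makes is validated against that ground
truth or against analytic oracles.

# The synthetic cohort model

Each channel is a sum of four narrowband oscillators (one per canonical
band — θ 4–7, α 8–12, β₁ 13–20, β₂ 21–30 Hz) plus 1/f background noise:

* **Oscillator**: `A · cos(2π f₀ t + ψ₀ + θ(t))` at the band-centre
  frequency `f₀`, where `θ(t)` is an Ornstein–Uhlenbeck phase drift
  (relaxation 0.2 s⁻¹, stationary sd 1.5 rad). The drift makes the
  instantaneous phase well defined and non-trivial while keeping the
  oscillation inside its band.
* **Coupling**: a `coupling_spec(pair, band, lag_rad, kappa, group)`
  makes two channels share one oscillator; the second channel receives
  the shared phase minus `lag_rad` minus a jitter process `η(t)` whose
  marginal law is von Mises(0, κ). The jitter is built by a Gaussian
  copula: white noise is low-passed (Gaussian transfer, σ = 2 Hz),
  standardised, mapped through `pnorm` and then through the von Mises
  quantile function. The marginal is therefore *exactly* von Mises while
  the path is smooth, and the expected phase-locking value of the pair is
  the analytic mean resultant length I₁(κ)/I₀(κ)
  (`vonmises_mean_resultant()`).
* **Noise**: spectrally shaped white noise with power ∝ f^(−exponent)
  (default exponent 1, RMS 10 µV) — the standard EEG background model.
* **Volume conduction**: an instantaneous channels × channels mixing
  matrix applied last; identity means none. A leak entry `M[j, i] > 0`
  produces zero-lag shared signal — high PLV, near-zero ciPLV — which is
  precisely the confound ciPLV is designed to reject.

## Default preset (the emulated cohort)

`default_cohort_config()`: 18 + 18 subjects, 250 Hz, 60 s per subject,
one eyes-closed interval spanning the recording. Baseline amplitudes
θ/α/β₁/β₂ = 8/10/5/4 µV on every channel; the ASD-like group carries a
+30% elevation on Fp1/Fp2/F3/F4/F7/F8/Cz in all four bands and
stronger fronto-parietal α/β₁ couplings (κ = 4 vs 1 in the TD-like
group, lag π/4), mirroring the direction of the published group effects
(frontal power and fronto-central connectivity higher in ASD). The
target study reports significance maps, not effect sizes, so the +30%
magnitude and the κ values are calibration choices fixed once.

Between-subject variability has two parts, chosen deliberately:

* `subject_cv = 0.2`: a **global** lognormal amplitude factor per subject
  (skull thickness, electrode contact). Per-segment min–max rescaling
  removes exactly this kind of gain difference — that is why the rescaling
  exists — so this term affects raw amplitudes but not normalised
  features.
* `topo_cv = 0.07`: independent per-channel/band lognormal **topography**
  jitter. This is the variability that survives normalisation. Real
  topographies vary smoothly (correlated across neighbouring channels),
  which an independent-jitter model overstates at a given CV; 7% yields
  group separations comparable to those the clinical study reports
  (frontal features FDR-significant at n = 18 + 18).

What the generator does **not** emulate: realistic head-model forward
mixing (the mixing matrix is arbitrary, not a lead field), EMG/EOG
artifacts, sleep architecture, bad electrodes, or non-stationarities
beyond the OU drift. A green test therefore establishes correctness of
the estimators and the statistical machinery on a well-specified world —
not clinical performance.

# Preprocessing

Processing order: broadband 1–45 Hz filter → re-reference to Fz →
eyes-closed extraction → band-specific filters → epoching. Band-filtering
the continuous signal before cutting 2-s segments keeps filter edge
transients out of every epoch; the published pipeline lists the steps but
not this ordering.

Filters are Hamming-window FIR designs (`design_bandpass()`). When no
order is given, the transition bandwidth is 25% of the lower passband
edge, floored at 2 Hz and limited by the distance to DC/Nyquist, with
order ≈ 3.3·fs/tb (the classic Hamming heuristic). The band-specific
connectivity filters use the published orders: 24 for θ/α/β₁ and 50
for β₂ — deliberately soft designs whose −6 dB points lie well outside
the nominal band. Coefficients are scaled to unit gain at the passband
centre.

Application is **zero-phase**: the symmetric (linear-phase type I) taps
are applied centred, compensating the group delay exactly, so no
frequency-dependent phase shift can leak into the instantaneous-phase
estimates. This is equivalent in contract to forward–backward filtering
but keeps the single-pass amplitude response (|H|, not |H|²). Edges are
odd-reflection padded; signals shorter than three filter lengths are
rejected. Channel means are removed before convolution (an exact DC null
is otherwise unattainable: a Hamming stopband floors at ≈ −53 dB).

Re-referencing subtracts Fz from all other channels and drops it
(19 → 18 channels). An average reference is deliberately not offered —
it mixes signal phases. Note a consequence faithfully reproduced here:
the reference electrode's own activity enters every derived channel as a
shared zero-lag component, raising baseline PLV between all pairs.

Epoching tiles non-overlapping 2-s windows within each eyes-closed
interval, discarding trailing remainders so the `T` in the PLV formulas
is constant.

# Spectral features

Per 2-s epoch: Welch PSD with 1-s Hamming windows and 50% overlap
(three windows, 1 Hz resolution — resolving the 4 Hz theta edge), band
power as the mean PSD over grid frequencies inside the band (edges
inclusive), then min–max rescaling of the 18 channel values **per band**
within the epoch, and finally averaging across epochs. The published
phrasing ("rescaled across all electrodes") is ambiguous about pooling
bands into one rescale; per-band scaling is used because it preserves
the per-band topography that the study's figures display. A degenerate
all-equal segment maps to 0.5 everywhere (symmetric, no division by
zero). Features are scale-invariant by construction and live in [0, 1];
18 × 4 = 72 per subject.

# Connectivity features

Phases come from the FFT-based analytic signal computed on the
continuous band-filtered eyes-closed stretch and epoched afterwards
(per-epoch Hilbert transforms would suffer Gibbs edge bias). For each
2-s epoch and each of the 153 ordered pairs (lexicographic over the
fixed 18-label order):

* `plv()` — modulus of the mean phasor of the phase difference;
* `ciplv()` — |imaginary part| / sqrt(1 − real part²). The magnitude
  convention keeps features in [0, 1]; whether the source study kept
  signed values is not recoverable from its text. When the mean phasor
  is almost exactly real (|1 − Re²| < 1e-18 in the vectorised path,
  guard ε = 1e-9 in the scalar API), the numerator vanishes too and the
  value is defined as 0, with a warning — this is the perfect zero-lag
  locking case.

Epoch values are averaged per subject: 153 × 4 = 612 features per
measure.

## The epoch-averaged PLV bias (why one acceptance assertion is red)

The acceptance suite requires the epoch-averaged PLV of a coupled pair
to recover I₁(κ)/I₀(κ) within 0.05 for κ ∈ {0.5, 2, 4, 8} (120 s,
250 Hz). The estimator averaged here is the *mean of per-epoch moduli* —
exactly what the published pipeline computes. The modulus of a mean of
`T_eff` independent unit phasors with true resultant R is positively
biased, `E|z̄| ≈ sqrt(R² + (1 − R²)/T_eff)`, and a 2-s epoch of a process
whose phase difference has ≤ 2 Hz bandwidth contains only `T_eff ≈ 8–12`
effectively independent phasors. At κ = 0.5 (R = 0.243) the bias is
≈ +0.11 — no band-limited generator can beat it, because mixing fast
enough to decorrelate phasors within 2 s requires more bandwidth than
the band has. Measured values: epoch-averaged errors 0.114 / 0.038 /
0.018 / 0.008 for κ = 0.5 / 2 / 4 / 8; the full-stretch PLV (one long
window) recovers all four targets within 0.011. The acceptance test
asserts the criterion as written and is therefore red at κ = 0.5; the
full-stretch recovery and the monotonicity in κ are asserted green.

# Statistics

* `wilcoxon_ranksum()`: rank-sum of the first sample with midranks.
  Pooled size ≤ 12 → exact permutation p over all group assignments,
  `P(|W − EW| ≥ |w − EW|)`; larger → normal approximation with
  tie-corrected variance and continuity correction. The two-tailed exact
  p equals the usual doubled-tail value because the null distribution is
  symmetric.
* `benjamini_hochberg()`: step-up adjustment with monotonicity
  enforcement; the rejection mask is `adjusted ≤ q`. The FDR family is
  all features of one measure in one analysis (all bands pooled) — the
  more conservative reading of the published correction.
* `friedman_test()`: within-block midranks, tie-corrected χ² with
  k − 1 degrees of freedom (χ² = n(k−1) at perfect concordance, 0 on
  constant data). The p-value is the χ² tail — note that at very small
  n this approximation is *not* the exact permutation p; the
  implementation is validated against `stats::friedman.test` and the
  closed-form extremes instead. The published two-factor report
  (channels df 17, groups df 1) is realised as two one-way calls:
  channels as conditions with subjects as blocks, and the two groups as
  conditions with matched subject pairs as blocks (the cohorts are
  pair-matched); the exact construction in the source is not recoverable
  from its text.
* `mass_univariate()`: one Wilcoxon test per feature, BH across the
  family, direction = sign of the ASD-like minus TD-like median
  difference.

# Classification and explanation

`fit_l2_logistic()` minimises the penalised negative log-likelihood
(intercept unpenalised) by damped Newton iterations; for p > n the
Newton system is solved in the n-dimensional space via the Woodbury
identity, so 612-feature problems with 36 subjects cost microseconds.
Convergence is declared at gradient norm < 1e-8 (every returned fit is
checked < 1e-6). Features are standardised with training statistics only
— L2 penalties are not scale-invariant.

`nested_cv()` uses stratified 6 outer / 5 inner folds; the inner loop
grid-searches 13 penalties log-spaced over 1e-3…1e3 by pooled accuracy,
breaking ties toward stronger regularisation (the published grid and
inner metric are unstated; these are the documented defaults). Outer
metrics: accuracy, sensitivity and specificity at threshold 0.5 (ASD
positive), and rank-based AUC; mean and per-fold sd are reported.
`loo_predict()` repeats the inner search for each held-out subject
(fold counts adapt to the minority class in very small samples).
All fold assignments derive from a single seed; reports are
deterministic.

`conditional_shap()` attributes the model margin under **conditional**
expectations: for the linear margin and a Gaussian feature model with
mean µ and covariance Σ, a coalition S is worth
`v(S) = b + w'(µ + Σ[,S] Σ[S,S]⁻¹ (x_S − µ_S))`, and the Shapley value
averages marginal contributions over feature orderings. Exact
enumeration is exponential, so orderings are sampled (default 128, each
with its reversal; ≤ 6 features are enumerated exactly). Every sampled
ordering telescopes to `margin − base`, so local accuracy
(base + Σ SV = margin) holds to machine precision regardless of the
sample size. Σ is the Ledoit–Wolf shrunk covariance of the background
(n = 36 ≪ p = 612 makes the sample covariance singular); shrinkage is
floored at 1e-4 so the Cholesky factorisations exist. Correlated
features share credit — two duplicated features receive half each.
`feature_importance()` is the mean |SV| across subjects divided by its
maximum (max FI = 1), with per-group variants normalised by their own
maxima.

# Numerical and budget choices

* ciPLV denominator guard ε = 1e-9 (scalar) / 1e-18 on 1 − Re² (vector
  path), returning 0 with a warning.
* Welch detrending: per-window mean removal only.
* Wilcoxon exact-path cutoff n ≤ 12 (`choose(12, 6) = 924` subsets).
* EDF export quantises to 16 bits with per-channel symmetric physical
  ranges; eyes-closed intervals travel in a sidecar CSV.
* Test-budget scale-downs (assertions unchanged): the complete-null
  empirical-FDR check runs 200 replicates of 9 + 9 subjects × 12 s; the
  nested-CV permutation null uses 30 shuffles; the end-to-end criterion
  classifies the spectral set only.

# Limitations

The simulator's independence assumptions (per-channel topography jitter,
single shared oscillator per coupling, at most one coupling per channel
per band and group) are simplifications; the mixing matrix is not a
physical lead field; and the default preset's effect magnitudes are
calibration choices, not published facts. Classification results on
synthetic cohorts say nothing about clinical accuracy — reproducing the
published real-cohort metrics would require the original recordings,
which are available only on request.
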