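---
title: "Methods: estimating weak-coupling parameters, cross-frequency ratios and information flow between neural rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating weak-coupling parameters, cross-frequency ratios and information flow between neural rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscicouple)
```

## The model

Two narrowband rhythms — a frontal theta (4–8 Hz) and a parietal alpha
(8–14 Hz) — are treated as weakly coupled phase oscillators. The generative
model used throughout the package is the symmetric Kuramoto pair with
additive Wiener phase noise, integrated by Euler–Maruyama at `dt = 1/srate`:

$$d\varphi_1 = 2\pi\omega_1\,dt + \varepsilon \sin(\varphi_2-\varphi_1)\,dt + \sigma\,dW_1,$$

and symmetrically for $\varphi_2$. This is the simplest model whose phase
difference $\psi = \varphi_2 - \varphi_1$ obeys the Adler equation
$\dot\psi = 2\pi\Delta f - 2\varepsilon\sin\psi$, which produces the two
phenomena the analysis layer is built to measure:

* **an Arnold tongue** — the pair phase-locks iff
  $\varepsilon \ge \pi\,|\Delta f|$, so phase locking grows with coupling
  gain and shrinks with detuning;
* **a sinusoidal phase-response curve (PRC)** — outside the tongue, the
  instantaneous frequency difference as a function of the instantaneous
  phase difference is $\Delta f - (2\varepsilon/2\pi)\sin\Delta\varphi$,
  so the curve's mean level estimates the detuning (Hz) and its
  peak-to-trough range estimates $4\varepsilon/2\pi$ (Hz), the coupling
  strength.

The theory specifies no particular generative equations; sinusoidal
symmetric coupling is a deliberate design choice — anything richer (phase
lags, higher harmonics, amplitude dynamics) would add parameters the
downstream estimators do not claim to recover. Amplitudes are constant per
trial (an optional slow sinusoidal envelope is available) because every
estimator in the package works on phase and frequency, not amplitude
dynamics.

## The synthetic study

`study_preset()` fixes the two experimental conditions the pipeline is
exercised on. The parameter choices encode the qualitative physiology the
method family is designed to detect, with values chosen once on physical
grounds:

| parameter | fixation | delay | why |
|---|---|---|---|
| theta natural frequency (Hz) | 7.0 | 5.6 | theta slows in the delay; the alpha:theta ratio moves from ~1.2 toward ~2 |
| alpha natural frequency (Hz) | 8.8 | 10.9 | alpha accelerates in the delay |
| coupling gain ε (rad/s) | 4 | 1.5 | weaker coupling in the delay: lower PLV, MI, TE, coupling strength |
| theta / alpha amplitude | 1.0 / 1.4 | 1.3 / 1.0 | theta amplitude rises, alpha drops |
| phase-diffusion σ (rad/√s) | 1.5 | 1.5 | realistic within-trial frequency wander (~0.3 Hz SD over 1-s windows) |
| trials × duration | 96 × 3 s | 96 × 3 s | matches a ~100-trial session; 3 s accommodates the theta filter (see edge policy) |
| sensors / SNR | 8 ch / 10 dB | — | smooth frontal and parietal mixing profiles, 1/f background |

The fixation gain ε = 4 with detuning 1.8 Hz sits at ~0.7× the locking
threshold (π·1.8 ≈ 5.7): strong but unlocked coupling, so the PRC's phase
coverage stays complete. Between-subject jitter (natural frequencies
N(0, 0.3 Hz), gain ±20%) gives paired statistics realistic variance.
Per-subject seeds derive from the master seed by a splittable integer
hash, so any subject's data are independent of how many subjects are
generated. A real session's fixation period is typically ~1 s; the
generator uses 3-s trials for both conditions because the theta-band
zero-phase filter needs them (below), and the condition contrast is
carried entirely by frequencies, gain and amplitudes.

What the generator does *not* emulate: volume-conducted artifacts, ocular
or cardiac contamination, non-stationary 1/f background, multiple sources
per band, and amplitude–phase interactions. Passing tests therefore show
the estimators are correct *given* narrowband oscillators mixed linearly
into sensors — not that real EEG satisfies those assumptions.

## Numerical choices

**Zero-phase filtering.** Band-pass filters are Hamming-window FIR designs
of order three cycles of the band's low edge (375 samples for 4 Hz at
500 Hz). Because the kernels are symmetric (linear phase, odd length), a
single FFT convolution with exact group-delay compensation has *exactly*
zero phase response — the same property usually obtained by
forward–backward filtering, at half the cost and with a single transient
per edge. Passband gain error is <1% and stopband attenuation >50 dB.

**Edge policy.** Each trial loses `1.5 × filter order` samples plus half a
Savitzky–Golay window at both edges from all phase/frequency statistics
(for the theta band at 500 Hz: 589 samples ≈ 1.2 s per edge, leaving
~0.6 s of a 3-s trial). This is conservative — the single-pass transient
is only half the order — but phase estimates near edges are also bent by
the Hilbert transform's circularity, and the budget is dominated by other
stages.

**Instantaneous frequency.** The Savitzky–Golay derivative of the unwrapped
Hilbert phase (order 3, window 51 samples ≈ 100 ms at 500 Hz) passes
modulations up to ~4 Hz with <1% gain error while suppressing unwrap
jitter; the window is the shortest that keeps pure-tone frequency ripple
below 0.01 Hz at realistic SNR.

**PRC estimation.** Phase differences are pooled across trials into 24
bins of width π/12; the median (not mean) frequency difference per bin
resists heavy-tailed derivative noise. Up to 4 empty bins are interpolated
circularly from their nearest occupied neighbours; more than 4 raise an
insufficient-coverage error (a hard-locked pair simply does not visit most
phase differences, and no curve should be reported). The binned medians are
smoothed with a 3-bin circular moving average (attenuating a sinusoidal
PRC by only ~2.6%) and a smoothing spline is fitted with periodic boundary
handling by tiling the bins across three periods and evaluating the
central one; the penalty defaults to generalized cross-validation.
Detuning is reported both as the mean of the bin medians (the default) and
as the mean of the fitted spline — the two differ by <0.01 Hz in practice,
and both appear in all outputs so the convention is never ambiguous.

**Identifiability of the coupling strength.** Band-pass filtering a
frequency-modulated carrier strips modulation sidebands that fall outside
the band (Carson's rule), biasing the recovered PRC amplitude downward.
Recovery within 15% of $4\varepsilon/2\pi$ requires (i) analysis bands
covering the source frequency ±2.5 Hz, and (ii) gains below ~0.8× the
locking threshold $\pi\Delta f$ — closer to the tongue the precession
becomes strongly anharmonic and spills energy into modulation harmonics
beyond any reasonable band. The recovery experiments in the test suite
(detuning grid {1, 2, 4} Hz at ε = 0; gain grid {1.5, 2, 2.5} rad/s at
1 Hz detuning, 12–20 subjects × 12 trials) respect both conditions and
state them as the estimator's validity envelope.

**Spectral peaks and ratios.** The 0.1-Hz STFT grid comes from
zero-padding 1-s Hamming windows to 10 s, preserving the 1-s temporal
resolution. The 1/f trend is an ordinary least-squares fit of log10
amplitude on log10 frequency over 1–30 Hz, pooled across conditions (one
trend per component), so condition differences in occurrence cannot come
from condition-specific thresholds. Within a band, local maxima at or
below the trend are discarded; among survivors the largest amplitude wins
and exact ties go to the lower frequency, deterministically. A frame
contributes a ratio only when *both* bands have a suprathreshold peak;
ratios are rounded half-away-from-zero to one decimal (so 1.25 → 1.3,
unlike banker's rounding) and occurrence percentages sum to 100 by
construction. Note that on trend-only (pure 1/f) frames the largest local
maximum still clears a mean-level trend in most frames — absence of a
peak is informative, but presence alone is not; the occurrence *histogram*
across conditions, not the raw detection rate, is the meaningful quantity.

**Information theory.** Series are decimated to 250 Hz (anti-aliased FIR)
so the 1–20-sample lag range spans 4–80 ms, then discretized by
uniform-count (quantile) binning with 4 symbols — few enough that plug-in
bias at the pooled sample sizes (~10⁴–10⁵) is negligible against the
effects of interest, and rank-based so any monotone rescaling of the data
leaves the symbols unchanged. Ties share the lower bin. Estimation pools
trials per subject and condition, but the lagged estimators never pair
samples across trial boundaries (runs are tracked through the pooling).
TE conditions on a single destination sample; the embedding is exposed as
configuration but deeper histories cost statistical power quickly at 4
symbols. No bias correction is applied by default — both conditions share
the same sample sizes, so plug-in bias cancels in paired contrasts.
Directionality of TE is only identifiable at small detuning: for a 6
versus 10 Hz pair, the 4–80 ms lags plus the two-to-one ambiguity of a
cosine observable bias TE toward the alpha→theta direction regardless of
the true coupling direction. The directionality experiment therefore uses
8 vs 8.5 Hz oscillators (40-s runs), where both true directions are
recovered reliably; conclusions about direction between rhythms far apart
in frequency should not rest on this estimator.

**SSD.** Covariances are estimated on trial-concatenated data, decimated
so the sampling rate stays ≥5× the top analysis frequency (pure speed; the
spatial structure is unchanged), filtered to the target band and to the
flanking band (±2 Hz beyond the band, 1-Hz transition gaps), with 5%
shrinkage toward the scaled identity, and normalized by each filter
chain's white-noise power gain so the generalized eigenvalues read as
band-to-flank power ratios (white noise → eigenvalues ≈ 1). Filters are
unit-norm with the largest-magnitude entry positive (a reproducible sign
convention); forward patterns are $C W (W^\top C W)^{-1}$. Component
selection replaces anatomical dipole gating — out of scope here — by
absolute correlation of the pattern with a spatial template (threshold
0.7), then highest SNR among survivors; with no template, highest SNR
alone. On synthetic runs the template is the ground-truth mixing vector.

**Statistics.** Paired t tests are two-sided with the a − b sign
convention; both paired-d conventions are reported (d_z on the difference
SD, d_av on the average group SD) since conventions differ across the
literature. Identical inputs return the degenerate but well-defined
t = 0, p = 1, d = 0; zero difference variance with non-zero mean is an
error. Stepwise regression starts at the intercept, examines additions
before removals (a switch flips the order), accepts the single move that
most decreases BIC, and standardizes predictors and response internally so
selection is scale-invariant and coefficients are standardized betas.
Exactly collinear predictors are resolved toward the earlier-listed one.
BIC stepwise with ~9 candidates admits a spurious predictor alongside a
true one in roughly a third of replicates at n = 50 — the χ²₁ > log n
familywise chance — which is a property of the procedure, not a defect of
the implementation; the true predictor is essentially never missed.

## Pipeline and reproducibility

`run_pipeline()` is a pure function of its configuration: every random
draw derives from the master seed, reruns are byte-identical, and the
configuration hash is embedded in the results bundle and its JSON export.
The behavioral stage simulates accuracy as
`intercept + plv_coef · z(PLV_delay) + noise` (defaults 0.75, −0.15, 0.05)
purely so the stepwise stage can be exercised end-to-end with a known
answer. The regression stage is skipped (with a message) below four
subjects. Problem sizes used by the test suite — 20×20 PLV grids at 10
trials per cell, 100-run directionality experiments, a 26-subject study at
96 trials per condition — were chosen as the smallest designs at which the
measured quantities stabilize well inside their acceptance margins.

## Known limitations

* Coupling strength is attenuated near the locking threshold and for
  modulation bandwidths approaching the analysis band — see the validity
  envelope above. Estimates near the tongue boundary are lower bounds.
* The PRC assumes 1:1 phase interaction; the generalized k:1 difference is
  available (`ratio_k`) but is a sensitivity analysis, not a validated
  estimator of cross-frequency coupling.
* Binned TE with single-sample conditioning cannot resolve direction
  between rhythms far apart in frequency (see above).
* No HDF5/EDF/BrainVision I/O: epochs enter as in-memory arrays
  (`trial_epochs()`); readers for acquisition formats are out of scope.
* The synthetic forward model is instantaneous linear mixing; no head
  model, no artifacts, no preprocessing stage.
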