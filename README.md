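# oscicouple

Cross-frequency dynamics and connectivity of weakly coupled neural
oscillators, for EEG researchers studying how a frontal theta rhythm
(4–8 Hz) and a parietal alpha rhythm (8–14 Hz) interact during cognition.
The package asks the question in the language of the theory of weakly
coupled oscillators (TWCO): is a shift toward a harmonic (2:1) alpha:theta
frequency ratio a sign of stronger coupling between the two generators, or
of their segregation?

## What it computes

Two phase oscillators with natural frequencies ω₁, ω₂ and coupling gain ε
(rad/s) evolve as

    dφ₁ = 2π ω₁ dt + ε sin(φ₂ − φ₁) dt + σ dW₁
    dφ₂ = 2π ω₂ dt + ε sin(φ₁ − φ₂) dt + σ dW₂

so their phase difference ψ = φ₂ − φ₁ obeys dψ/dt = 2πΔf − 2ε sin ψ with
detuning Δf = ω₂ − ω₁: the pair locks iff ε ≥ π|Δf| (the Arnold tongue).
The analysis layer estimates, from data alone:

- **Phase-response curve (PRC)** — instantaneous frequency difference
  binned by instantaneous phase difference (24 bins of π/12, median per
  bin, circular smoothing, periodic smoothing spline). Its mean level is
  the **detuning** (Hz); its peak-to-trough range is the **coupling
  strength**, which for the model above equals 4ε/2π Hz.
- **PLV** — sliding-window (300 ms / 50 ms) mean resultant length of the
  phase differences, in [0, 1].
- **Cross-frequency ratio occurrence** — transient spectral peaks above
  the fitted 1/f trend (STFT: 1-s windows, 90% overlap, 0.1-Hz grid), the
  per-frame alpha:theta peak-frequency ratio rounded to one decimal, and
  its percentage histogram over bins 1.0–3.5.
- **Information-theoretic connectivity** — uniform-count discretization,
  plug-in mutual information, and transfer entropy
  I(dst_t ; src_{t−lag} | dst_{t−1}) averaged over lags 1–20 samples at
  250 Hz, in both directions.
- **Statistics** — paired t tests with Cohen's d (d_z and d_av),
  Benjamini–Hochberg FDR, and BIC-driven stepwise regression of behavior
  on the neural metrics.

Components are extracted from multichannel epochs by spatio-spectral
decomposition (SSD): a generalized eigenvalue problem between band-passed
and flank-passed covariances, with component selection by spatial-template
match and band-to-flank SNR. A ground-truth synthetic generator (coupled
stochastic phase oscillators, sensor mixing, 1/f background, two
experimental conditions, between-subject jitter) makes every estimator
testable against known parameters.

## Worked example

Estimate TWCO parameters from a single simulated pair (ω = 6 and 7 Hz,
ε = 2 rad/s, so true detuning 1 Hz and true coupling strength
4·2/2π ≈ 1.27 Hz):

```r
library(oscicouple)

pair  <- simulate_coupled_phases(6, 7, epsilon = 2, phase_noise_sd = 1,
                                 duration = 10, srate = 500, seed = 42)
theta <- analytic_trace(bandpass_zero_phase(component(cos(pair$theta1), 500, c(3.5, 8.5))))
alpha <- analytic_trace(bandpass_zero_phase(component(cos(pair$theta2), 500, c(4.5, 9.5))))

prc <- estimate_prc(theta, alpha)
prc
#> <oc_prc> detuning 1.157 Hz (spline mean 1.158), coupling strength 1.376 Hz, 24/24 bins occupied
compute_plv(theta, alpha)
#> <oc_plv> mean 0.860 over 1 trials (300 ms windows, 50 ms steps)
```

The recovered detuning (1.16 Hz) and coupling strength (1.38 Hz) sit near
the commanded 1 and 1.27 Hz; `autoplot(prc)` draws the binned curve with
its fitted spline. A full synthetic study — simulate, extract components
per subject, compute every metric, group statistics — is one call:

```r
res <- run_pipeline(oc_config(seed = 1, n_subjects = 4,
                              conditions = study_preset(n_trials = 16)),
                    progress = FALSE)
res$group_tests[res$group_tests$metric %in%
                  c("plv", "detuning", "coupling_strength", "mi"),
                c("metric", "estimate", "t", "p", "d_z")]
#> # A tibble: 4 × 5
#>   metric            estimate      t         p    d_z
#>   <chr>                <dbl>  <dbl>     <dbl>  <dbl>
#> 1 coupling_strength -1.54    -7.64  0.00466   -3.82
#> 2 detuning           3.48    38.2   0.0000393 19.1
#> 3 mi                -0.00542 -0.942 0.415     -0.471
#> 4 plv               -0.470   -5.13  0.0143    -2.57
```

Estimates are delay minus fixation: in the delay condition phase locking,
coupling strength and mutual information drop while detuning rises — the
2:1 ratio shift coincides with *segregation*, not integration, of the two
generators. `tidy()`/`glance()` methods cover the PRC, PLV and stepwise
fits; `autoplot()`/`plot_arnold_tongue()`/`plot_condition_metric()` draw
the standard figures.

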