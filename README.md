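# avtrack

Neural tracking of naturalistic audio-visual speech: temporal response
functions, stimulus–brain coherence and phase, and group statistics —
validated end to end on a synthetic cohort with known ground truth.

## The problem

When a viewer watches someone speak, two slow signals carry the rhythm
of the exchange: the **speech envelope** (the amplitude modulation of
the voice, dominated by the 2–8 Hz syllabic rhythm) and the **visual
motion** around wherever the viewer is looking (mouth and face
movement).  Cortical activity tracks both, and their *relative timing*
— which stream's neural response leads, and by what theta-band phase
angle — indexes how well audio-visual speech is integrated.  Typical
development shows a visual response lead of tens of milliseconds and a
~90° theta phase offset between the two neural processes; atypical
audio-visual integration can reverse the lead and push the offset
toward 180° with much broader dispersion across individuals.

`avtrack` implements the full analysis chain used to measure this:

* **Features** — speech envelope via the analytic signal
  (|Hilbert|, 40 Hz zero-phase Butterworth, 1000 Hz), I-VT fixation
  filtering of gaze, and gaze-contingent visual motion (mean
  supra-threshold inter-frame luminance change in a 318 px window
  around fixation), with joint RMS normalization and binned mutual
  information between features.
* **Preprocessing** — zero-phase 0.1–70 Hz band-pass, 50 Hz notch,
  robust bad-channel detection, spherical-spline interpolation, common
  average reference, 30 Hz low-pass, automated artifact masking.
* **TRF models** — forward (encoding) and backward (decoding) ridge
  models over ±300 ms lags at 100 Hz,
  `EEG(t) = Σ_f Σ_ℓ w(f,ℓ,c)·s_f(t−ℓ) + ε`, with subject-level
  leave-one-out "generic" models, λ (and AV trade-off γ) selected by
  cross-validated prediction r, surrogate z-scoring by circular shifts,
  and per-lag decoding profiles for optimal-lag estimation.
* **Spectral** — Welch magnitude-squared coherence (3 s Hamming, 50 %
  overlap, 0.1–30 Hz in 0.33 Hz steps), surrogate-standardized z,
  band peaks in delta (1–4 Hz) and theta (4–8 Hz), and CPSD phase at
  the common band peak; the audio-visual phase shift is
  Δφ = φ_V − φ_A (positive = visual leads).
* **Statistics** — Rayleigh, Watson–Williams and Harrison–Kanji
  circular tests, Kruskal–Wallis + Dunn contrasts, and cluster-based
  permutation comparison of sensor accuracy maps with family-wise error
  control.
* **Synthetic cohort** — audio, video, gaze and EEG generators with
  known response kernels, cross-modal lags, theta phase offsets and von
  Mises subject variability, so every stage is testable without any
  recorded data.

## Worked example

```r
library(avtrack)

# two-group cohort: visual-lead (A) vs auditory-lead (B) presets
co   <- gen_cohort(5, seed = 4, duration_s = 60, n_channels = 16)
prep <- prepare_subjects(co)
grp  <- vapply(prep, `[[`, "", "group_label")

# forward AV-joint model on group A, checked against the generating truth
m <- fit_generic_forward(prep[grp == "A"], "av")
kernel_recovery_correlation(m, co[[1]]$truth)
#> [1] 0.95

# optimal decoding lags per group
pa <- per_lag_decoding(prep[grp == "A"], "envelope"); pa$optimal_lag_ms
#> [1] 200
pv <- per_lag_decoding(prep[grp == "A"], "motion");   pv$optimal_lag_ms
#> [1] 50
pb <- per_lag_decoding(prep[grp == "B"], "envelope"); pb$optimal_lag_ms
#> [1] 50

# theta-band audio-visual phase shift, group level
ps <- cohort_phase_shift(prep[grp == "A"], band = "theta", seed = 7)
ps$group_mean
#> [1] 1.41        # ~ pi/2: the visual process leads by a quarter cycle
```

The auditory response peaks ~200 ms and the visual ~50 ms after the
stimulus in the visual-lead group (the reverse in the auditory-lead
group), and the theta phase shift recovers the imposed π/2.

The numbered scripts under `analysis/` run the study end to end at desk
scale (simulation → features → forward TRFs → decoding and lags →
coherence/phase → full report), each printing its findings and writing
CSV tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_features.R
# ... through
Rscript analysis/06_full_report.R
```

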