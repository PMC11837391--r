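---
title: "Methods: neural tracking of audio-visual speech with avtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural tracking of audio-visual speech with avtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`avtrack` implements an analysis pipeline for quantifying how cortical
activity tracks the two dynamic components of naturalistic audio-visual
speech — the slow amplitude envelope of the voice and the visual motion
around the viewer's fixation point — and how tightly the two neural
processes are coordinated in time.  The pipeline covers gaze-contingent
stimulus feature extraction, EEG preprocessing, forward and backward
temporal response function (TRF) modelling with ridge regularization and
surrogate normalization, stimulus–brain coherence and cross-spectral
phase in the delta (1–4 Hz) and theta (4–8 Hz) bands, circular
statistics on phase angles, and cluster-based permutation comparison of
two groups of subjects.

Because recordings of this kind are rarely shareable, the package is
organized around a synthetic cohort generator with full ground truth:
every downstream stage can be validated by recovery of known kernels,
lags and phase offsets.  The `analysis/` scripts run the stages in
order at desk scale; `run_full()` executes the complete graph.

## The model

### Forward (encoding) model

EEG at channel $c$ is modelled as a lagged linear functional of the
stimulus features,

$$ y_c(t) = \sum_{f} \sum_{\ell} w_{f,\ell,c}\, s_f(t - \ell) + \varepsilon_c(t), $$

with lags $\ell$ spanning $-300$ to $+300$ ms in 10 ms steps (61 lags at
the 100 Hz model rate).  Positive lags capture response following the
stimulus.  Weights are estimated by ridge regression,
$(X^\top X + \lambda I)\,w = X^\top y$, solved exactly; the intercept is
unpenalized via column centring.  Signals are anti-alias downsampled
from 1000 Hz to 100 Hz before lag expansion (zero-phase Butterworth
low-pass at 80% of the target Nyquist, then decimation — a deliberate
choice over polyphase FIR resampling, which would break the zero-phase
contract maintained throughout the pipeline).

Three feature sets are fitted: auditory-only (envelope), visual-only
(motion), and AV-joint.  The joint model balances the two regressors by
a trade-off weight $\gamma$ applied to the visual lag block, selected
from $\{0.25, 0.5, 1, 2, 4\}$ jointly with $\lambda \in
\{10^{-2},\dots,10^{6}\}$ by maximizing the mean cross-validated
prediction $r$.  Cross-validation is subject-level leave-one-out
("generic" models): the held-out subject's EEG is predicted with the
average of the other subjects' TRFs.  Prediction accuracy per channel is
Pearson's $r$, standardized into a $z$ by a surrogate distribution built
from circular shifts of the test EEG (minimum shift 1 s, 100 surrogates
by default); circular shifting preserves autocorrelation, so the null
keeps the temporal structure of the data.

### Backward (decoding) model

Decoders map the lagged multichannel EEG to a stimulus feature over the
same ±300 ms window, with the same generic leave-one-subject-out scheme;
accuracy is the correlation between reconstruction and true feature.
The "AV-joint context" for decoding is not uniquely determined by a
backward formulation — a multi-output backward ridge decouples across
targets and would equal the single-feature decoder exactly — so the
package operationalizes it by residualization: the forward AV-joint
model's prediction of the *other* feature is subtracted from the EEG
before decoding the target.  This expresses the cost that concurrent
encoding of the other stream imposes on the target stream and reduces
to the single model when the other feature explains nothing.

Per-lag decoding fits single-lag decoders across the grid; here a
positive lag means the EEG sample that many milliseconds *after* the
stimulus is used to reconstruct it, so a response kernel peaking at
+100 ms yields an optimal decoding lag of +100 ms.  The optimal lag
maximizes across-subject mean $r$ (ties broken toward the smallest
$|\ell|$, conservative toward zero-lag synchrony); a Kruskal–Wallis test
across lags with Dunn comparisons against the weakest lag identifies
lags with significantly elevated accuracy.  The per-subject difference
between auditory and visual optimal lags (A − V, positive = visual
response leads) is the timing asymmetry statistic compared across
groups.

### Coherence and phase

Stimulus–brain coupling is quantified by magnitude-squared coherence
with Welch averaging: 3 s Hamming windows, 50% overlap (the 0.33 Hz
analysis grid implies a ~3 s resolution; window length and overlap are
configurable), evaluated on 0.1–30 Hz in 0.33 Hz steps.  Contiguous
usable spans of at least 9 s are treated as trials; segments never
straddle a trial boundary.  Significance is surrogate-based: the neural
time course is circularly shifted against the stimulus (50 surrogates)
and coherence is z-scored against that null.  Shifts are realized as
segment re-pairings at multiples of the Welch hop (1.5 s), which
satisfies the ≥1 s minimum while letting surrogate cross-spectra reuse
the cached segment FFTs.

Cross-power spectral density (CPSD) phase is evaluated at one common
band peak per subject: the frequency in the band at which the
*elementwise minimum* of the two conditions' z spectra is maximal —
i.e. where coherence is prominent for **both** streams.  This matters
for the phase difference: the response-kernel phase ($-2\pi f L$ for a
kernel at lag $L$) cancels in $\phi_V - \phi_A$ only when both phases
are taken at the same frequency, and the difference is only defined
where the two streams share coupling.  Phases are stored with the
convention positive = stimulus leads response, so the audio-visual
phase shift $\Delta\phi = \phi_V - \phi_A$ is positive when the visual
stream leads.  Channels whose z at the peak is below 2 in either
condition are flagged unreliable and excluded from the subject-level
circular mean (the electrode set is configurable; the default is the
reliable set, falling back to all channels).

### Circular statistics

Phase angles are compared with the Rayleigh test of uniformity
($z = n\bar r^2$ with the standard small-sample-corrected p), the
Watson–Williams multi-sample test (F with the $1 + 3/(8\hat\kappa)$
concentration correction, flagged unreliable when the pooled resultant
length falls below 0.45), and a Harrison–Kanji two-way decomposition
(group × band) using F ratios against the residual resultant term under
high concentration and $2\hat\kappa\,SS$ chi-squared approximations
otherwise.  The phase-shift *extent* used in the accuracy correlation
is $|\mathrm{wrap}(\Delta\phi)| \in [0, \pi]$ — the absolute deviation
from perfect alignment; distance from the group circular mean is
available as an alternative.  All statistics are invariant to global
rotation, which the tests verify.

### Group comparison on sensor maps

Per-channel accuracy maps are compared between groups with a
cluster-based permutation test: per-electrode two-sample t, parametric
two-sided threshold at α = 0.05, connected supra-threshold sets of at
least two adjacent electrodes per polarity, cluster mass = summed t,
and a permutation null (1000 label permutations) of the maximum
absolute mass.  Sensor adjacency is built by a great-circle distance
threshold (edges below 1.3× the median nearest-neighbour distance, with
each sensor guaranteed its nearest neighbour); a Delaunay triangulation
of projected positions would be the usual alternative, but the distance
graph is dependency-free, symmetric by construction, and yields the
same local neighbourhoods on the quasi-uniform cap layouts used here.

## The synthetic cohort

The generator emulates the study design: two groups whose audio-visual
temporal organization differs.

* **Stimulus pair.**  The envelope is a rectified quasiperiodic series:
  a dense sum of theta-band sinusoids with random phases (frequency-
  domain synthesis, Gaussian amplitude taper centred at 5 Hz with a
  shared delta floor down to 1.5 Hz), multiplied by a slow amplitude
  modulation (0.4 Hz, depth 0.25), plus an independent low-passed
  broadband component and a DC offset before rectification.  The motion
  series shares the rhythmic component: it is time-shifted by the
  stimulus lag and its ≥4 Hz (theta-proper) part is rotated by the
  imposed phase offset — an analytic-signal rotation applied to every
  theta frequency, so the offset is recoverable at any in-band
  frequency.  The delta part stays phase-aligned, confining group phase
  differences to theta.  A configurable fraction (default 60% of theta
  variance) is shared; the rest is independent, as are the broadband
  components.  About 75% of band-limited (0.5–30 Hz) power falls in
  2–8 Hz, satisfying the theta-dominance contract while keeping the
  deconvolution well-conditioned — a near-line theta spectrum would make
  kernel estimation ill-posed, which real (broadband) speech envelopes
  are not.

* **Response kernels.**  Gaussian bumps in lag (σ = 35 ms) with focal
  scalp topographies (Gaussian fall-off, width 0.45 rad): the envelope
  kernel projects fronto-centrally, the motion kernel occipitally.  The
  visual-lead preset peaks the visual kernel at 50 ms and the auditory
  at 200 ms; the auditory-lead preset reverses them.  Timing asymmetry
  is expressed in the *response kernels* and the theta offset in the
  *stimulus pair* (π/2 vs π); coupling both to a stimulus-level lag as
  well would double-count the offset at 5 Hz (a +50 ms lag is itself
  π/2 there).

* **EEG.**  Sum of kernel-convolved features plus 1/f noise, spatially
  correlated through a smooth mixing kernel on the sensor sphere,
  scaled to the preset SNR (0 dB by default, as ratio of mean signal to
  mean noise power across channels).

* **Subject variability.**  Per-subject theta offsets are von Mises
  around the preset value — κ = 8 for the tight (visual-lead) profile,
  κ = 1 for the broad (auditory-lead) profile, echoing a broader phase
  distribution in that group; kernel peaks jitter ±10 ms and SNR ±1 dB.
  The κ defaults are calibration choices, not empirical claims; note
  that at κ = 1 the *population* circular mean of a small cohort is
  itself dispersed by several tenths of a radian, so recovery checks of
  the imposed offset use tightly concentrated cohorts and the dispersion
  regime is validated through the resultant length instead.

* **Rendered streams.**  The audio track is the envelope on a 440 Hz
  carrier, so the analytic-signal extractor recovers it near-exactly.
  The video is a static square whose luminance steps encode the motion
  series (each inter-frame step maps affinely to one motion value,
  always above the extractor's threshold of 10), so the gaze-contingent
  extractor returns the generating series up to an affine map —
  harmless, since features are RMS-normalized and models carry
  intercepts.  Motion values are sampled at frame-interval midpoints
  and held (centred zero-order hold): a leading-edge hold would impose a
  half-frame group delay (~20 ms at 25 fps, 0.6 rad at 5 Hz) on every
  phase estimate.  Gaze is piecewise-stationary fixation with Gaussian
  dispersion and instantaneous saccades.

What the generator does *not* emulate: ocular and muscle artifacts
(the preprocessing hooks are exercised with amplitude spikes instead),
volume-conduction realism beyond smooth mixing, non-stationary
attention, or any content structure of real cartoons.  Passing recovery
tests therefore demonstrates correctness of the estimation machinery,
not robustness to every pathology of infant EEG.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Envelope low-pass | 40 | Hz | standard envelope bandwidth before downsampling to 1000 Hz |
| I-VT velocity threshold | 30 | deg/s | vendor-published default; 75 ms merge window, 0.5 deg merge angle, 60 ms minimum fixation |
| Motion crop window | 318 | px | ~8 deg at the nominal screen geometry; the pixel value is operative |
| Motion difference threshold | 10 | grey levels | supra-threshold mean convention; sum/window alternative configurable |
| EEG band-pass | 0.1–70 | Hz | fourth-order zero-phase Butterworth; 50 Hz notch (Q = 30); final 30 Hz low-pass after re-referencing |
| Bad-channel criterion | robust z > 5 | – | MAD-based with a scale floor at the median amplitude, so only ~6× excess flags; focal topographies must survive |
| Artifact mask | 150 µV, 200 ms pad | – | automated surrogate for visual rejection |
| TRF lags | −300…300, step 10 | ms | 61 lags at 100 Hz |
| λ grid | 10^−2…10^6 | – | decade steps on column-centred designs |
| γ grid | 0.25…4 | – | AV trade-off on the visual block |
| TRF surrogates | 100 | – | minimum shift 1 s |
| Coherence grid | 0.1–30, step 0.33 | Hz | 3 s Hamming, 50% overlap, 50 surrogates |
| Trial length | ≥ 9 | s | minimum usable span for spectral analysis |
| Cluster permutations | 1000 | – | ≥2 adjacent electrodes, cluster p < 0.05 |
| MI | 4 bins | – | equipopulated (rank-quantile) bins; permutation p at α = 0.001 |

## Numerical choices and degenerate inputs

* All filters are zero-phase.  Rather than time-domain forward–backward
  (filtfilt) passes — which are numerically fragile for a 0.1–70 Hz
  band-pass in transfer-function form (poles at the 0.1 Hz edge sit
  almost on the unit circle) and whose edge handling limits stop-band
  depth — the composite response is applied exactly in the frequency
  domain: the spectrum is multiplied by the closed-form Butterworth
  magnitude-squared response (or the biquad |H|² for the notch).  This
  is the steady-state equivalent of filtfilt with exact attenuation
  (> 260 dB at the notch centre) and an impulse response symmetric to
  machine precision; edge effects appear as circular wrap-around,
  confined to about one filter time constant, instead of transients.
  Impulse-response symmetry is asserted to 10⁻⁸ relative.
* Ridge systems are solved exactly; near-singular unregularized systems
  are rejected with a condition diagnostic rather than silently
  pseudo-inverted.
* Optimal-lag ties break toward the smallest |lag|.
* Quantile binning for MI breaks ties by occurrence order
  (deterministic); constant inputs return MI = 0 with a flag rather
  than an arbitrary binning.
* A flat per-lag profile (max − min r < 10⁻⁶) flags the optimal lag as
  undefined; a flat band spectrum returns the band midpoint, flagged.
* Zero-RMS columns in normalization are left at zero and flagged, never
  divided.
* Circular means with vanishing resultant are flagged undefined.
* Spherical-spline interpolation (order 4, regularization 10⁻⁵, 50
  Legendre terms) refuses channels with fewer than three good channels
  within 0.9 rad and leaves them flagged.
* Every generator consumes an integer seed and derives per-subject and
  per-stage streams through a fixed integer hash, so whole runs are
  bit-reproducible.

## Problem sizes

The bundled analyses run at desk scale, chosen so the full suite and
the demo complete on one CPU in minutes: cohorts of 5–8 subjects per
group, 30–120 s of recording, 12–16 channels.  Kernel recovery and
decoding accuracy are validated on 120 s × 10 subjects at 0 dB SNR; the
cluster test's family-wise error on 400 simulated null datasets.  The
montage generalizes to the 110-channel default (`make_montage(110)`)
without code changes; runtimes scale roughly linearly in channels for
the spectral stage and quadratically in design columns for decoders.

## Known limitations

* The AV-joint trade-off (γ) and the joint-context decoding convention
  are package definitions of an underdetermined specification; both are
  logged in the fitted objects so sensitivity checks are one loop away.
* The surrogate-coherence null uses hop-aligned shifts; with very short
  records (few segments) the discrete shift set is small and the z
  estimate coarse — the code enforces at least 20 surrogates and three
  segments.
* Harrison–Kanji's chi-squared regime (moderate concentration) cannot
  separate the interaction from the main effects with the same
  residual term; the F regime is used whenever κ̂ > 2.
* Welch coherence values on the 0.33 Hz analysis grid are linearly
  interpolated from the native FFT grid of the 3 s window; phase is
  always taken at the nearest native bin, never interpolated.
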