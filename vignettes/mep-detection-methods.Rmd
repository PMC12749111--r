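---
title: "Detecting and scoring DBS-evoked motor potentials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring DBS-evoked motor potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepscore)
```

## The measurement problem

Deep brain stimulation of the subthalamic nucleus can spread into the
adjacent internal capsule and recruit corticospinal/corticobulbar fibres.
Each stimulation pulse then evokes a time-locked muscle response — a motor
evoked potential (mEP) — in surface EMG, at a latency set by conduction
path length: roughly 5–18 ms for facial muscles, 11–31 ms for arm and hand
muscles. Detecting these responses automatically is hard for two reasons
that shape the whole design:

* the **amplifier-recovery artifact** after each pulse is an exponentially
  damped oscillation that can persist ~20 ms, overlaps the facial response
  window, and shares its frequency content — it cannot be filtered out,
  only estimated and subtracted; and
* **60 Hz line noise** is periodic in the 100 ms inter-pulse epoch at
  10 Hz stimulation, so pulse-triggered averaging does not attenuate it at
  all, while it does suppress all non-pulse-locked noise by
  $1/\sqrt{n_\text{pulses}}$.

The pipeline (`run_pipeline()`) is therefore: epoch averaging → noisy-trace
exclusion → artifact rejection on facial channels, subtractive 60 Hz notch
on limb channels → baseline z-scoring → latency-windowed peak detection →
score aggregation. Artifact rejection operates on the microvolt-scale
averaged traces, before z-scoring, because the artifact estimate must not
depend on each channel's baseline scale.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| sampling rate | 22 000 | Hz | clinical electrophysiology rig rate assumed by the sample-domain defaults |
| train | 10 Hz × 12 s | — | 100 ms epoch comfortably spans all mEP latencies; 120 pulses give ~11× noise suppression |
| baseline | final 10% of epoch | — | inert: response and artifact have ended |
| exclusion | var(50–100 ms) > 150; mean abs > 25 | µV², µV | signatures of detached or poor-contact electrodes; the variance rule is stated in µV² |
| detection threshold | facial 4, limb 7 | baseline z | facial responses are smaller; limb channels carry more residual structure |
| latency windows | per muscle (e.g. nasalis 5–18, ECR 16.5–30.5) | ms | conduction path length; `derive_latency_windows()` re-derives them from a corpus (P1−0.5 to P99+0.5 ms, clipped to the wide 4–25 / 10–40 ms group windows, rounded to 0.5 ms) |
| peak width gate | 1–15 | ms at half maximum | rejects single-sample noise spikes (≪1 ms at 22 kHz) and slow fluctuations |
| artifact window | 2–20 | ms | support of the recovery artifact |
| Savitzky–Golay | order 2, 51 samples at 22 kHz | — | strips >2 kHz noise from library templates without distorting the artifact |
| score add-back | 7 | z | all muscles share the limb threshold as origin after normalization |

Peak height is measured on the rectified z-trace relative to zero (the
baseline median maps to zero after z-scoring). Ties between equal-height
peaks go to the earliest latency. Width at half maximum is found by linear
interpolation at the first half-height crossings on either side of the
peak.

## Numerical choices that mattered

These were each forced by a measurable failure on synthetic data, and the
behaviour is locked in by tests.

**Robust sinusoid fitting in the notch.** The subtractive notch takes the
60 Hz phase from the epoch's Fourier transform and fits a unit sine's
amplitude by *median-scaling* — the median of the element-wise ratio, which
a temporally sparse response barely moves. Two refinements were necessary.
First, a DC offset divided by a sine produces a bimodal, heavy-tailed ratio
distribution whose median is unstable, so a DC term is fitted (robustly)
alongside. Second, a large sparse response leaks into the 60 Hz Fourier bin
and biases the phase estimate, leaving a residual sinusoid of up to ~30% of
the line amplitude; the fit therefore alternates a few median-based
refinement sweeps over DC, in-phase, and quadrature amplitudes. The
subtracted component is still a single 60 Hz sinusoid. After refinement the
worst case over phases is <3% residual line amplitude and <1% bump-peak
error. Only the fundamental is removed; harmonics are shorter-period and
smaller than any credible response.

**Zero-phase filtering with steady-state initialization.** The optional
second-order Butterworth band filters run forward–backward with
odd-reflection padding and steady-state initial conditions; naive
forward–backward filtering leaves large low-frequency startup transients on
a 100 ms epoch (a DC offset through a 10 Hz high-pass retained ~40% of its
value near the epoch core). The high- and low-pass second-order sections
run in cascade because the combined fourth-order polynomial is numerically
ill-conditioned when a corner sits far below Nyquist. Band filtering is
*off* by default for both groups: the notch and the artifact rejection are
what detection performance depends on, and the band edges here
(`butter_facial`, `butter_limb`) are placeholders for rigs that need them.

**Fitting artifact templates.** All rejection methods fit amplitudes on
baseline-median-corrected waveforms: the slow-drift DC of a raw average
otherwise corrupts the ratio median (same pathology as in the notch). For
the PCA methods the median-scaled fit pairs the uncentred corrected window
with PC1 and ignores samples where the template is below 5% of its peak —
row-centring would smear a sparse response's mean over the whole window,
and ratios against the template's decayed tail are dominated by whatever
rides on top of it. The subtraction is applied exactly on the 2–20 ms
window with no edge taper: the artifact peaks right at the 2 ms edge, so
any taper leaves a residual proportional to the artifact itself, while the
step the untapered edit creates lies outside every detection window.

**PCA rejection needs channels.** Subtracting a PC1-fitted component
removes approximately $1/k$ of any single-channel response (the response
leaks into PC1 with weight $u_1/d_1$), so cross-channel rejection is only
trustworthy with the full facial montage (6 channels ⇒ ~17% worst-case
response attenuation; 3 channels ⇒ ~33%). Template-based rejection has no
such floor and is the default. `remove_pc1` scaling removes each channel's
full PC1 projection — including its response's projection — which is why
median-scaling is the default scale rule.

**Degenerate inputs.** A trace whose baseline has zero standard deviation
(e.g. a flat, disconnected channel) is auto-excluded rather than erroring
the setting; a setting with *all* channels excluded has a missing (NA)
score, which is distinct from the legitimate score 0 of a setting where
muscles were recordable but silent. A constant artifact window matches no
template and is returned unchanged. Muscles absent from a normalization
table get scale 1 with a warning.

## The score's worked examples and two documented quirks

`mep_score()` implements: excluded channels leave the denominator;
responding channels contribute `(peak_z − group_threshold) × iqr_scale + 7`
(floored at 0, a guard that cannot trigger at default thresholds);
non-responders contribute 0; the mean is compressed as `log2(1 + mean)`.
Two quirks of the procedure's published description are reproduced rather
than resolved: (1) the canonical "single minimal response" example feeds a
normalized amplitude of 8 — a facial peak at z = 5 under identity scaling —
although a response at exactly threshold would normalize to 7; the package
reproduces the stated example (score exactly 1). (2) The score scale is
described as independent of how many muscles are recorded, but the
averaging step makes a lone response score differently under different
channel counts; the formula is implemented exactly as specified and this
vignette notes the inconsistency. Calibration (`calibrate_normalization()`)
equalizes per-muscle IQRs against the *pooled* distribution's IQR; the
identity "every muscle's normalized IQR equals the pooled IQR" is exact and
tested to 1e−9.

One further erratum: the evaluation literature for this procedure calls F1
the "geometric mean" of precision and recall; `f1_threshold_sweep()`
implements the standard harmonic-mean F1 and offers
`f1_variant = "geometric"` for comparison.

## What the synthetic generator does and does not emulate

`simulate_recording()` builds each channel as: a seeded evoked-response
kernel after every pulse (2–3 Gaussian lobes, biphasic, fixed per
subject × muscle — reproducing the within-subject waveform stereotypy of
real responses), plus a damped-sinusoid recovery artifact (decay 3–7 ms,
oscillation 100–250 Hz, shared shape across facial channels, peak scaling
with stimulation amplitude), 60 Hz line noise of fixed within-recording
phase, white noise band-limited to 3.5 kHz (the amplifier passband), and a
sub-2 Hz random-walk drift. Recruitment is threshold-like: no response
below a per-muscle threshold amplitude, steeply rising above it.
Line interference defaults to 4 µV on limb channels and 0.4 µV on facial
channels; in the conditions this simulates, line noise was the limiting
factor for limb detection and the recovery artifact for facial detection,
and the defaults are set so an unmitigated pipeline reproduces both failure
modes (facial false positives from artifact; limb misses from
line-inflated baselines).

Not emulated: volume conduction and cross-talk between muscles, cardiac
and movement artifacts with their real spectra, non-stationary line-noise
amplitude, anatomy-driven contact-to-threshold structure, and
amplifier saturation. Passing the synthetic benchmarks therefore
demonstrates the algorithm's correctness under its stated noise model, not
clinical-grade accuracy on patient data.

Benchmark sizes used by the test suite: the detection benchmark runs 20
subjects × 20 settings × 6 channels with response amplitudes injected at
0×, 1.5× and 3× the group detection threshold (in units of the expected
baseline deviation of the average); the duration analysis uses 10 × 12
settings; the stereotypy analysis 5 × 8. The template library is built from
192 artifact-only simulated recordings, matching the reference library
size, and is negation-augmented to 384.

## Known limitations

* Latency windows and thresholds ship as fixed defaults; a new recording
  rig or montage should re-derive windows (`derive_latency_windows()`) and
  re-sweep thresholds (`f1_threshold_sweep()`) on annotated data.
* The subtractive notch removes only the 60 Hz fundamental.
* Template rejection assumes the library spans the artifact shapes of the
  target rig; out-of-distribution artifacts degrade toward the PCA floor.
* The score's IQR normalization requires a calibration corpus with at
  least a handful of detected responses per muscle; until then identity
  scales are used.
* Single-trial (per-pulse) detection is out of scope; everything operates
  on pulse-triggered averages.
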