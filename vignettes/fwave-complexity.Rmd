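---
title: "Methods: f-wave complexity analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: f-wave complexity analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
parameters matter, which choices were genuinely open and how they were
fixed, and what the synthetic-data validation does and does not show.

## 1. The signal model behind the generator

### Fibrillatory wave

`gen_fwave()` uses the standard harmonic ("sawtooth") surface-AF model: a
fundamental $f_0 \in [3,12]$ Hz with `n_harmonics` harmonics whose
amplitudes decay geometrically (`harmonic_decay`, default 0.5), slow
sinusoidal amplitude modulation, and sinusoidal frequency modulation of the
instantaneous fundamental,
$f(t) = f_0\,(1 + d_{fm}\sin 2\pi f_{fm} t)$.
Defaults: $f_0 = 6$ Hz (the observed DF range in nonparoxysmal AF cohorts
centers near 5.5–6 Hz), AM depth 0.15 at 0.45 Hz, FM depth 0.03 at 0.3 Hz —
i.e. a peak instantaneous-frequency excursion of about $\pm 0.18$ Hz, the
conservative end of the sub-Hz DF variability reported for AF. Component
phases are drawn from the seed; everything else is deterministic.

**Amplitude convention.** The wave is rescaled so that the *median
successive peak-to-trough amplitude* equals `peak_to_peak` (per-lead
defaults 45/65/70/57 μV on I/II/V1/V6, reproducing the magnitude ordering
of published per-lead f-wave amplitudes, V1 largest). The FWA estimator
uses the *mean* of the same extrema sequence, so generator and estimator
share one convention and recovery tests are self-consistent.

### Ventricular activity and noise

`gen_ventricular()` places a fixed QRST template — raised-cosine Q, R, S
and T segments, smooth and strictly band-limited in practice, exactly zero
outside its 0.45-s support — at RR intervals drawn i.i.d. from a log-normal
law parameterized by `(mean_rr, rr_cv)` and truncated at the QRST duration.
Log-normal because AF RR histograms are strictly positive and
right-skewed. Defaults `mean_rr = 0.8` s, `rr_cv = 0.15` describe a
rate-controlled nonparoxysmal-AF patient at rest (~75 bpm with the
irregular ventricular response of AF). RR intervals are quantized to whole
samples, so `rr_cv = 0` yields exactly periodic beats — the degenerate case
several oracle tests rely on.

Noise is additive and configurable per component: white noise (default
10 μV RMS), sub-0.5-Hz baseline wander, and a 50/60 Hz powerline tone
(both default 0: the band-pass stage removes them by construction, and the
white-noise default is the condition the headline recovery tests state).

### Cohort generator

`gen_cohort()` draws the two endpoint labels as independent Bernoulli
variables (prevalences 86/130 termination, 71/130 recurrence) and then
draws each metric from the normal law of the patient's group, truncated at
zero. The planted group moments (`af_reference_moments()`) are the
published means and SDs of all twenty lead × metric combinations plus
left-atrial CT volume. Because a patient belongs to *two* group structures
(termination and recurrence), marginal moments can only be matched for one
endpoint at a time; `moments_outcome` selects which (default termination),
and the other label stays an independent coin flip. Metrics are drawn
independently of each other — the source tables report only marginals — and
an optional restriction (`metrics =`) keeps simulations cheap.

## 2. Atrial-signal extraction

### Band-limiting

The 1–32 Hz band-limit is a linear-phase FIR band-pass (Hamming `fir1`
design, 2-s support, −6 dB at the band edges) applied after mean removal,
with symmetric-reflection padding and centered convolution — an exactly
zero-phase implementation. Its measured response (asserted in the tests):
unity ±0.1% at 8 Hz, ≤2.1% at 60 Hz, ≤10% at 50 Hz, exact DC rejection.
An undecimated wavelet reconstruction of the matching detail levels is an
equivalent band-limiter; the FIR realization was chosen because its
response is directly designable and verifiable.

### R detection

Energy-based detection (differentiate → square → 150-ms centered moving
integration → adaptive threshold at 0.3 × a running 98th-percentile,
median-smoothed over ±2 s), refinement of each candidate to the local
absolute-amplitude maximum within ±50 ms, and a 200-ms refractory rule
keeping the larger peak. Detection runs once, on lead II (largest R wave in
both the generator and typical clinical recordings); beat times are
lead-invariant, so the resulting impulse train is reused for every lead.

Detections within 0.15 s of a record edge are discarded and flagged. Near
the edges the reflection padding distorts the filtered waveform and the
refinement window is clipped; one misaligned edge detection measurably
corrupts the shared adaptive kernel for *all* beats (ventricular
suppression collapsed from ~60 dB to 8 dB in the case that motivated the
rule), whereas an uncancelled partial beat at the very edge is excluded
from metrics anyway by the edge guard below.

### Event-synchronous adaptive filtering

The reference is the impulse train advanced by `kernel_pre`, so a causal
FIR kernel of length `(kernel_pre + kernel_post)·fs` spans
$[-0.25, +0.45)$ s around each R peak — Q to T-end with margin at AF
rates. The kernel is initialized with the R-locked mean beat (the classical
average-beat-subtraction estimate, computed from beats with full kernel
support) and refined by normalized LMS (`step_size = 0.05`) over
`n_passes = 3` sweeps; the final sweep adapts at a tenth of the step size
while emitting the residual. Mean-beat initialization matters: a
zero-initialized NLMS at this step size would retain ~16% of the QRST after
the ~36 tap-visits a 10-s epoch provides, while the mean beat is already
the least-squares kernel for non-overlapping beats and the LMS then only
tracks beat-to-beat deviations and overlap splitting. Overlapping beats
(kernel span ≥ RR, common in AF) are handled by the per-sample LMS itself,
which least-squares-splits the overlapped taps; the condition is flagged.

Outside kernel support the reference is zero, so the residual equals the
primary there *exactly* — a structural identity the tests assert.

### What extraction can and cannot achieve on a 10-s epoch

Two error terms are intrinsic, and the package reports rather than hides
them (`scripts/acceptance.R`, `atrial_rms_error_pct`):

- **Template leakage.** Any per-epoch template estimate — adaptive or plain
  averaging — absorbs the R-locked average of the f wave, which for ~12
  beats of a coherent narrowband oscillation is ≳ $1/\sqrt{12} \approx 29\%$
  of its RMS; the subtraction then removes that fraction of atrial signal
  inside every beat window. The average-beat oracle shows the identical
  error, confirming it is a floor of the method class, not of the
  implementation.
- **Band-limiting baseline.** A 1-Hz high-pass maps the QRST train to zero
  mean, leaving a constant negative inter-beat baseline that lies outside
  kernel support and therefore, by the identity above, stays in the
  residual.

Consequently waveform-level RMS recovery of the atrial signal plateaus
around 50–65% of the atrial RMS under the default conditions, while the
*metrics* the method exists for remain accurate: DF recovery is exact to
the 0.1-Hz grid across 4–9 Hz, and FWA recovers planted amplitudes to
within ~8–16% (the residual leakage biases FWA down proportionally, QRST
residue biases it up additively; both are measured in the acceptance
report). This mirrors clinical practice, where f-wave metrics — not
waveform fidelity — are the deliverable.

## 3. Metric conventions

- **FWA**: extrema are located on a 20-ms moving-average smoothed copy,
  alternation enforced, minimum separation 40 ms, then each extremum is
  refined to the raw-signal extremum within ±10 ms so smoothing does not
  attenuate amplitudes; FWA is the mean absolute successive difference.
  Fewer than 4 extrema flags the value unreliable.
- **Spectra**: Welch, 2-s Hann segments, 50% overlap, zero-padded to a
  0.1-Hz grid. The padded grid serves display and fine peak localization
  (DF, SE); *energy accounting* for OI uses the estimator's native 0.5-Hz
  resolution, where a windowed tone's power is not smeared by
  interpolation — on the padded grid the Hann main-lobe skirt would cap a
  pure tone's OI at ~0.948 as an artifact of interpolation, not of signal
  organization.
- **DF**: PSD argmax in [3, 12] Hz, ties toward the lower frequency;
  flagged invalid when a component outside the band (within 0.5–25 Hz)
  exceeds twice the in-band maximum, so an out-of-band tone's leakage skirt
  is not reported as a DF.
- **SE**: natural-log entropy over the 91 bins of [3, 12] Hz at 0.1 Hz.
  The absolute value depends on this binning (maximum ln 91 ≈ 4.51);
  published SampEn/SE magnitudes from other binnings are not comparable by
  construction, which is why the package fixes and documents the grid.
- **SampEn**: anti-aliased decimation to 250 Hz, m = 2, r = 0.2 × SD of
  the resampled signal, Chebyshev distance, self-matches excluded,
  unordered pairs counted once (counts shared between m and m+1 template
  sets). `B = 0` is undefined (flagged); `A = 0` returns the finite upper
  bound ln B, flagged. A constant signal yields 0 by convention. The C++
  counter is validated bit-exactly against a brute-force R implementation.
- **Edge guard**: `analyze_epoch()` trims one kernel span (0.7 s) from each
  end of the residual before computing metrics — filter edge transients and
  beats without full kernel support make those samples unrepresentative.

## 4. Outcome statistics

Per-group normality is screened with the Lilliefors-corrected
Kolmogorov–Smirnov test (the estimated-parameter KS variant used by
mainstream clinical software) at α = 0.05; both groups must pass for the
Student's t-test, otherwise Mann–Whitney. Categorical variables use χ²
without continuity correction, switching to Fisher's exact test when any
expected cell is < 5. Variables passing the screen at p < 0.05 enter a
multivariable logistic model (ML fit, Wald CIs and p-values; separation is
detected and flagged non-reportable instead of printing a fake CI). ROC
curves use the empirical trapezoid (provably the tie-aware Mann–Whitney
statistic), DeLong 95% CIs, and the Youden-maximum cutoff with ties
resolved toward higher sensitivity; orientation is fixed per variable so
the curve predicts the *bad* outcome (termination failure, recurrence) and
AUC ≥ 0.5. The combined predictor dichotomizes at the published cutoffs
(FWA V1 < 60.38 μV, DF I > 5.70 Hz) and fits the two indicators and their
conjunction in parallel models. No multiplicity correction is applied
anywhere — matching the reproduced analysis — and the family-wise behaviour
of the screen is *measured* (type-I error, null-AUC calibration) in the
acceptance suite rather than assumed.

## 5. Validation design and problem sizes

All validation runs on synthetic data at the study conditions: 10-s,
2-kHz, 4-lead epochs (QRS 1000 μV, f-waves 40–80 μV, white noise 10 μV
RMS); cohorts of 130 patients with the published prevalences and moments.
Simulation-based checks use 20 seeds per DF point, 500 replicates for
null-AUC and power, and 1000 replicates for screen calibration — sizes at
which binomial noise on the checked rates is well inside the asserted
bands. The power harness at the published FWA-V1 moments
(75.47 ± 26.18 vs 64.76 ± 29.79, n = 86/44) measures ~48–56% power at
α = 0.05 — consistent with the analytic power of a two-sample t-test at
that effect size, and a useful reminder that the source cohort's marginal
p = .038 sits near the detection boundary.

What passing these tests shows: the implementation is internally correct
(oracle identities), recovers planted ground truth, and is calibrated.
What it does not show: performance on real recordings — the generator's
f wave is smoother and more stationary than real fibrillation, its QRST
template is morphologically fixed (no ectopy, no respiration), and its
noise is stationary. Conclusions about clinical predictive value must come
from real cohorts.

## 6. Known limitations

- Waveform-level atrial recovery is floor-limited on short epochs (see
  §2); longer recordings (more beats) are the only principled remedy.
- SE and SampEn absolute values are convention-dependent (binning,
  m/r/sampling); only within-convention comparisons are meaningful.
- The cohort generator plants marginal group differences for one endpoint
  at a time and no cross-metric correlation by default.
- WFDB support covers the format-16 single-segment records the package
  itself writes, not the full WFDB zoo.
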