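# fibwave

Fibrillatory-wave complexity analysis of the surface ECG in atrial
fibrillation (AF), with outcome statistics for ablation cohorts.

During AF the P wave is replaced by a continuous low-amplitude atrial
oscillation — the fibrillatory (f) wave. Its amplitude and spectral
organization reflect the electrical and structural remodeling of the atria,
and have been proposed as noninvasive predictors of whether catheter
ablation will terminate AF and whether arrhythmia will recur. `fibwave`
implements that analysis chain for the four standard analysis leads
(I, II, V1, V6):

1. **Atrial-signal extraction.** Each lead is band-limited to ~1–32 Hz
   (zero-phase FIR), R peaks are detected with an energy-based detector, and
   an **event-synchronous adaptive filter (ESAF)** cancels the ventricular
   QRST waves: the reference input is a unit impulse train synchronized to
   the R peaks (advanced by the kernel pre-span), so the adapted FIR kernel
   *w* of a normalized-LMS filter converges to the R-locked ventricular
   waveform and the residual

   `a[n] = x[n] − (w ⊛ δ_R)[n]`

   is the atrial (f-wave) signal.

2. **Five per-lead complexity parameters** of the atrial signal:
   - **FWA** (μV) — mean successive peak-to-trough amplitude (time domain);
   - **DF** (Hz) — frequency of the Welch-PSD maximum in the 3–12 Hz
     fibrillatory band;
   - **OI** — organization index: fraction of 3–25 Hz spectral power inside
     ±0.5 Hz windows around DF and its harmonics (k ≤ 4, k·DF ≤ 25 Hz);
   - **SE** (nats) — Shannon entropy of the normalized PSD over 3–12 Hz on a
     0.1 Hz grid (maximum ln 91 ≈ 4.51);
   - **SampEn** — sample entropy (m = 2, r = 0.2 SD, 250 Hz resampling):
     −ln of the conditional probability that runs matching for m points
     match for m + 1.

3. **Outcome statistics** reproducing the clinical pipeline: per-group
   normality check (Lilliefors KS) → Student's t or Mann–Whitney U screen
   (χ²/Fisher for categoricals), multivariable logistic regression with
   Wald CIs for variables passing the screen, ROC curves with DeLong CIs
   and Youden-optimal cutoffs oriented to predict the *bad* outcome, and
   the combined dichotomized predictor
   `low FWA(V1) < 60.38 μV AND high DF(I) > 5.70 Hz`.

Because no patient recordings ship with the package, a first-class
**synthetic data module** generates (a) multi-lead AF ECGs with known
ground truth — a harmonic, amplitude/frequency-modulated f-wave model, a
raised-cosine QRST train at log-normal RR intervals, and configurable
noise — and (b) tabular cohorts whose per-lead metric distributions follow
published group moments (130 patients; 86/44 terminated, 59/71 recurrence).

## Worked example

```r
library(fibwave)

# a 10-s synthetic AF epoch at 2 kHz (f0 = 6 Hz, 60 uV f waves, QRS 1 mV)
sim     <- gen_af_ecg(fwave = fwave_params(f0 = 6, seed = 8))
metrics <- analyze_epoch(sim$epoch)
metrics[, c("lead", "fwa_uV", "df_Hz", "oi", "se_nats", "sampen")]
#>   lead fwa_uV df_Hz    oi se_nats sampen
#> 1    I   58.9     6 0.914    3.20  0.487
#> 2   II   66.5     6 0.804    3.57  0.370
#> 3   V1   62.2     6 0.877    3.28  0.379
#> 4   V6   63.7     6 0.815    3.52  0.392
```

The planted 60 μV, 6 Hz f wave is recovered on every lead; `metrics` also
carries per-lead quality flags (beat count, ventricular suppression in dB).

```r
# a synthetic 130-patient cohort with the published group moments planted,
# analyzed for procedural termination failure
cohort <- gen_cohort(cohort_sim_params(n_patients = 130, seed = 42))
study  <- run_study(cohort, endpoint = "termination_failure")
study$roc$fwa_v1
#> <roc_result> AUC 0.646 (95% CI 0.548-0.745), cutoff 66.77
#>              (lower score = positive), sens 0.600 spec 0.650
```

A low FWA in lead V1 predicts termination failure (AUC ≈ 0.65 at this
seed); `study$screen`, `study$logistic` and `study$combined` hold the
univariate table, the multivariable odds ratios and the combined
dichotomized predictor.

A command-line front end wraps the same functions:

```sh
fibwave simulate --out data/ --n 5 --seed 1
fibwave analyze  --in data/
fibwave study    --cohort data/cohort.csv --out data/report
```

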