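# tfsassay

Individualized assays of auditory temporal-fine-structure (TFS) coding.

## The problem

Auditory-nerve fibers phase-lock to the cycle-by-cycle fine structure of
low-frequency sounds, but whether an *individual* listener codes TFS well or
poorly is hard to measure. The two common behavioral proxies — slow-rate
frequency-modulation (FM) detection and interaural-time-difference (ITD)
detection — are adaptive 2AFC tasks, and in naive listeners their raw
thresholds mix sensory coding with *nonsensory* factors (attention lapses,
motivation). Passive EEG measures have their own confound: the amplitude of
cortical responses scales with anatomy (head size, source geometry), so raw
intertrial-coherence (ITC) amplitudes mostly index anatomy, not TFS coding.

`tfsassay` implements a battery of assays that work around both confounds,
plus a synthetic-cohort generator with known latent parameters so the whole
pipeline can be validated end-to-end without human data:

* **Stimuli** — calibrated stereo synthesis of FM tones, ITD tone-burst
  pairs, 40.8-Hz amplitude-modulated ITD-jump trials (the jump placed at a
  modulation trough so stimulus amplitude is zero at the switch), the
  forward-masked FFR probe–masker–probe sequence, and AM noise with ERB
  flankers. Interaural delays are sub-sample (frequency-domain phase shift).
* **Behavior** — weighted (3:1) one-down-one-up and three-down-one-up
  staircases against a logistic observer
  `P(correct | x) = γ + (1 − γ − λ) F((x − m)/s)`; a *nonsensory score* =
  percent incorrect on easy catch trials (FM depth > 15 Hz, ITD > 80 µs);
  lapse-adjusted "clean" thresholds as OLS residuals of threshold on the
  nonsensory score.
* **Cortical EEG** — Morlet-based ITC spectrograms; the 1–20-Hz jump-evoked
  ITC scalar per condition {20, 60, 180, 540 µs}; 40.8-Hz ASSR quality; N1/P2
  latency (mean of the two, re the jump); and the anatomy-free growth slope
  `(ITC₁₈₀ − ITC₆₀) / ITC₅₄₀`.
* **FFR** — polarity decomposition into difference (500-Hz TFS) and sum
  (1000-Hz rectification) averages; forward-masking residuals `d1 − d2`,
  `s1 − s2` that cancel the preneural (cochlear-microphonic-like) component
  and recover the masked neural fraction `α·A_neural`.
* **Stats** — Pearson correlations, fixed-entry-order incremental-R²
  variance partitioning (nonsensory → EEG latency → EEG slope), and
  Benjamini–Hochberg FDR control.

## Worked example

Simulate a small cohort, run behavior + cortical EEG, and partition the
threshold variance:

```r
library(tfsassay)
cfg <- cohort_config(n_subjects = 8)
study <- simulate_cohort_study(cfg, seed = 1, n_trials_per_cond = 100)
head(study$cohort[, c("subject", "itd_threshold_db", "itd_lapse_rate",
                      "itc_180", "latency_ms", "slope")], 4)
#>   subject itd_threshold_db itd_lapse_rate itc_180 latency_ms slope
#> 1       1           35.444          0.101   0.218    148.438 0.327
#> 2       2           43.806          0.201   0.211    158.203 0.250
#> 3       3           42.083          0.193   0.168    109.375 0.273
#> 4       4           42.250          0.174   0.118    158.203 1.184

stepwise_incremental_r2(study$cohort$itd_threshold_db,
  list(nonsensory  = study$cohort$itd_lapse_rate,
       eeg_latency = study$cohort$latency_ms,
       eeg_slope   = study$cohort$slope))
#> Predictor    Variance explained
#> nonsensory   75.86%
#> eeg_latency  0.61%
#> eeg_slope    5.66%
#> Explained    82.13%
#> Unexplained  17.87%
```

The ITD thresholds are in dB re 1 µs (so 30 dB ≈ 32 µs), the lapse rate is
the catch-trial error fraction, `itc_180` the jump-evoked low-band ITC
scalar for the 180-µs condition, `latency_ms` the mean N1/P2 latency after
the jump, and `slope` the normalized ITD-growth metric. In this small
synthetic cohort most threshold variance is carried by the nonsensory score,
with the EEG metrics adding incremental shares — the partition that motivates
adjusting behavioral thresholds before interpreting them as TFS sensitivity.
`study$ground_truth` holds the latent parameters each subject was generated
from, so recovery can be checked directly (`pearson_r(
study$cohort$itd_threshold_adj_db, study$ground_truth$theta_b)`).

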