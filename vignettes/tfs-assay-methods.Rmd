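---
title: "Methods: individualized assays of temporal-fine-structure coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized assays of temporal-fine-structure coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfsassay)
```

This vignette documents the models, parameter choices and numerical
conventions behind `tfsassay`, and what the synthetic-cohort validation
does and does not demonstrate.

## Scientific setting

Temporal fine structure (TFS) is the cycle-by-cycle phase of a narrowband
sound, as opposed to its slow envelope. Low-frequency TFS carries interaural
time differences (ITDs), and individual differences in TFS coding are of
broad interest — but every practical assay of it is confounded. The package
implements three families of candidate assays and the machinery to
disentangle their confounds:

1. **Behavioral thresholds** (FM depth at 2 Hz on a 500-Hz carrier, in dB re
   1 Hz; ITD of 500-Hz tone bursts, in dB re 1 µs) from adaptive 2AFC
   staircases. Confound: lapses of attention and motivation in naive
   listeners inflate thresholds.
2. **Cortical ITD-jump responses**: a 1.5-s, 500-Hz tone, 100% amplitude
   modulated at 40.8 Hz, whose ITD flips polarity about 1 s in. The evoked
   N1/P2 complex and the low-band intertrial coherence (ITC) grow with jump
   size. Confound: response *amplitude* scales with anatomy (head size,
   source orientation), so raw ITC mostly indexes anatomy. The latency
   metric and the normalized growth slope are designed to cancel that scale.
3. **Forward-masked FFRs**: scalp potentials tracking a 500-Hz probe contain
   both neural and preneural (cochlear microphonic) components. A loud
   forward masker adapts only the (synaptic) neural part, so subtracting the
   second-probe response from the first isolates it.

## Stimulus conventions

* Calibration: a full-scale sinusoid maps to 100 dB SPL by default; levels
  are converted with `10^((level − calibration)/20)` and recorded in each
  waveform's sidecar.
* Sampling rate 48 kHz by default. Interaural delays are applied as
  whole-waveform fractional delays via a frequency-domain phase shift, so
  ITD resolution is not limited by the sample grid. A tone-burst pair with
  ITD `τ` shifts each channel by `±τ/2`.
* AM phase convention for the jump stimulus: envelope
  `e(t) = (1 − cos(2π·40.8·t))/2`, so troughs fall exactly at `k/40.8` s.
  The ITD switch is placed at the trough nearest 1.0 s, i.e. at
  `41/40.8 ≈ 1.005` s (published figures of this paradigm show the
  equivalent trough just before 1 s; the convention, not the exact
  millisecond, is what matters — the envelope at the switch is below 1% of
  its peak, suppressing monaural cues). The jump-size convention is that a
  "540-µs jump" starts at an ITD of 270 µs with one ear leading and ends at
  270 µs with the other leading.
* The FFR sequence is probe (100 ms, 75 dB SPL), 50-ms gap, masker (100 ms,
  85 dB SPL), 1-ms gap, probe; 5-ms raised-cosine ramps everywhere; total
  0.351 s. Polarity −1 is the exact sample-wise negation.

## Observer and staircase model

The simulated observer is
`P(correct | x) = γ + (1 − γ − λ) F((x − m)/s)` with logistic `F`, guess
rate `γ = 0.5` (2AFC), midpoint `m` and spread `s` on the task's dB axis,
and lapse rate `λ`. The upper asymptote is `1 − λ`, so the error rate on
very easy trials estimates `λ` directly — this is what makes the
catch-trial ("nonsensory") score work.

Track rules: the FM task uses a weighted one-down-one-up rule with the up
step three times the down step (equilibrium at 75% correct), 11 reversals,
threshold = median of all reversals. The ITD task uses three-down-one-up
(asymptote at the 79.37% point, `p³ = ½`), 12 reversals, threshold =
geometric mean of the last nine (arithmetic mean on the dB axis). Step
sizes default to 4 dB, halving to 2 dB after three reversals.

Start values are a deliberate choice: the FM track starts at 28 dB re 1 Hz
and the ITD track at 44 dB re 1 µs — *above* the catch-trial bounds
(depth > 15 Hz ⇒ 23.5 dB; ITD > 80 µs ⇒ 38.1 dB) — following the standard
easy-to-hard adaptive practice. This guarantees that every block contains
catch trials, without which the lapse score would be undefined for
well-performing subjects. Catch flags use a strict inequality on the
presented (post-clamping) value.

## Cortical metrics

* **ITC**: complex Morlet decomposition (default 5 cycles, floored at 3 for
  the lowest frequencies), unit phasors averaged across trials,
  `ITC = |mean(e^{iφ})|`. It is a phase-only statistic — exactly invariant
  to any global amplitude rescaling of the epoch tensor. For `N` trials of
  pure noise the expected ITC is `√(π/4N)` (mean resultant length of
  uniform phases), ≈ 0.0886 at `N = 100`; this is the calibration point the
  tests check.
* **Condition scalar**: ITC averaged over 1–20 Hz (below the 40.8-Hz ASSR),
  then peak in `(0, 0.4]` s after the jump minus the mean over
  `(−0.4, 0]` s. The baseline subtraction supplies the noise floor. The
  published analyses plot one value per condition without defining the
  extraction; this rule is declared, not inferred.
* **Epoch window**: `[−0.5, +0.7]` s around the jump, wide enough to hold
  the baseline window, the N1/P2 complex, and the offset response.
* **ASSR quality**: ITC at 40.8 Hz over the pre-jump (stimulus-on) interval
  with a 16-cycle wavelet — long enough that transient energy at nearby
  frequencies (e.g. a coherent 35-Hz component) stays out of the band — and
  a noise floor from per-trial random phase rotations (99th percentile).
* **N1/P2**: most negative extremum in `(0.05, 0.20]` s and most positive in
  `(0.15, 0.35]` s after the jump, P2 constrained to follow N1; the latency
  metric is the mean of the two. Latencies are picked on Cz.
* **Growth slope**: `(ITC₁₈₀ − ITC₆₀)/ITC₅₄₀` — any common amplitude scale
  cancels. The latency metric is computed on the 180-µs condition, which
  avoids both the near-floor 20-µs and the saturated 540-µs conditions.

## FFR decomposition

Difference and sum averages are `(mean₊ ∓ mean₋)/2` after balancing the two
polarity classes by seeded subsampling (unequal counts would leak envelope
components into the difference). Segment windows are 10–90 ms after each
probe onset — identical post-onset alignment is the only hard requirement
for the subtraction to cancel linear components. Spectra use a periodic
Hann taper with amplitude read at the bin nearest the target; at the
default 4-kHz analysis rate the 80-ms window holds exactly 40 cycles of
500 Hz, so the component sits on a bin and an on-bin amplitude `A` is
recovered exactly. The noise floor is the mean magnitude over ±10
neighboring bins excluding ±2 around the target.

With probe-2 neural parts scaled by `(1 − α)`, the residual `|d1 − d2|`
recovers `α·A_neural` — the *masked fraction* of the neural component — and
is exactly invariant to the preneural amplitude. The suppression ratio
`d2/d1` is ≈ 1 for preneural-dominated and `(1 − α)` for neural-dominated
responses. For real data the package reports magnitudes and ratios only;
"purely neural" is an interpretation, not an invariant.

## The synthetic cohort

Each subject carries latents: sensory midpoints `θ_b` (ITD, dB re 1 µs;
mean 29, SD 4.5) and `θ_m` (FM, dB re 1 Hz; mean 14, SD 3.5), psychometric
spread 2 dB, lapse `λ = 0.3·Beta(2, 3)` (mean ≈ 0.12), EEG gain
`g = lognormal(0, 0.4)`, latency shift `τ = 0.010·z(θ_b) + N(0, 0.017)` s,
ITD-response sigmoid midpoint `log(60 µs) + 0.25·z(θ_b) + N(0, 0.43)` with
steepness 0.45 log units, and FFR amplitudes/masking
(`A_neural ~ 0.1 µV`, `A_preneural ~ 0.2 µV`, `α ~ Beta(8, 2)`).

The coupling structure encodes the hypotheses under test: worse behavioral
sensitivity goes with longer cortical latency and a right-shifted response
sigmoid; the EEG gain and the lapse rate are independent of `θ_b`. Cortical
trials are `g·[a(ITD)·(N1+P2 kernels at 100/200 ms + τ) + offset kernel] +
ASSR sinusoid + 1/f noise (6 µV) + white noise (3 µV)`, with opposite-sign
Gaussian kernels (σ = 25 ms, ±5 µV) — crucially the gain multiplies the
signal *before* the fixed-amplitude sensor noise, so anatomy changes
single-trial SNR and hence ITC, reproducing the amplitude confound; a
post-hoc rescaling of the epoch tensor changes nothing. Noise amplitudes
were set so the default ASSR ITC is ≈ 0.2–0.4 at 300 trials, consistent
with a robust steady-state response.

Two calibration choices deserve emphasis:

* The 2-dB ITD spread makes >80-µs catch trials genuinely easy for nearly
  every subject. With a shallow function (4 dB) poor-sensitivity subjects
  make *sensory* errors on catch trials, the nonsensory score becomes
  contaminated with `θ_b`, and lapse adjustment removes sensory variance —
  a failure mode worth knowing about when applying the score to real data.
* The lapse distribution gives the nonsensory score a larger share of raw
  threshold variance (typically 0.6–0.8) than the roughly one-third reported
  for human cohorts. At `n = 32`, a reliably detectable lapse effect is
  needed for the adjustment-recovery property to hold in ≥ 90% of cohorts;
  the generator therefore emphasizes the confound rather than matching any
  particular human cohort. Both the strength of the lapse effect and every
  coupling are `cohort_config()` parameters, so effects can be created or
  destroyed for power analyses.

**What the generator does not emulate**: multichannel spatial structure
(one analysis channel is rendered), non-Gaussian artifact families beyond
amplitude excursions, trial-order effects (fatigue, learning), cochlear
nonlinearities in the FFR (components are additive sinusoids), or
correlated noise across trials. Passing tests therefore demonstrate that
the *analysis machinery* recovers known parameters under the stated forward
model — not that the assays are valid in humans.

## Preprocessing

Earlobe re-referencing subtracts the mean of the two earlobe channels.
Filtering is zero-phase windowed-sinc FIR (Hamming), transition width half
the low edge (≈ 40 dB one octave below), applied forward–backward — zero
phase protects the latency metrics. Blink removal is signal-space
projection: exemplars where the frontal channel exceeds 4 robust SDs for
≥ 50 ms define the leading spatial component(s), and `P = I − UUᵀ` is
applied everywhere. Epoch rejection masks any epoch whose absolute
amplitude on an analysis channel (Fz/Cz) exceeds 150 µV (cortical) or
50 µV (subcortical). Epoch containers round-trip through an RDS-based
store with a schema version and integrity digest.

## Statistics

"Stepwise" regression is implemented as fixed-entry-order hierarchical
regression with sequential (Type-I) variance attribution — the only
convention under which the per-predictor percentages sum to the total
explained; entry order is nonsensory → EEG latency → EEG slope, and the
response is the raw ITD threshold with the nonsensory score as first
predictor (adjusting the response *and* entering the score would remove the
same variance twice). Pearson p-values use the exact t transform;
Benjamini–Hochberg control is the step-up rule via `p.adjust`.

## Validation problem sizes

The test suite exercises: staircase convergence at 200 reversals × 50
seeds (bias < 0.5 dB against the analytic 79.37%/75% points); ITC
calibration at 200 replicates of 100 uniform-phase epochs; latency recovery
on 10 subjects × 300 trials/condition (MAE ≤ 10 ms); FFR recovery noiseless
and at 8000 trials (≤ 5% / ≤ 15%); and the end-to-end recovery property on
100 cohorts of n = 32 with 100 EEG trials per condition — the reduced trial
count keeps the full validation run in the minutes range while leaving all
qualitative behavior intact.

## Known limitations and open choices

* The behavioral ITD bursts are rendered back-to-back (no inter-burst gap);
  the gap is configurable because the original paradigm leaves it unstated.
* Whether catch-trial bounds apply before or after floor/ceiling clamping is
  unspecified in the source paradigm; flags use the presented value.
* The condition-scalar extraction (peak minus pre-jump baseline) and the
  N1/P2 windows are declared defaults, not inferred ones.
* FFR segment windows, tapering, and time- vs frequency-domain subtraction
  are likewise declared; subtraction is done in the time domain.
* No EDF/BDF reader is bundled; recordings enter either as in-memory
  matrices (`eeg_recording`) or through the package's own epoch container.
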