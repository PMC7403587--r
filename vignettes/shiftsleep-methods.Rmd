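---
title: "Models and methods behind shiftsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shiftsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftsleep)
```

`shiftsleep` analyses telemetry from rodent simulated shift-work designs:
rats forced to be active for 8 h either during their circadian rest phase
(rest work, RW; zeitgeber time ZT2–10) or active phase (active work, AW;
ZT14–22), with vigilance states scored in 10-s epochs, per-epoch EEG
slow-wave power and EMG amplitude, and core temperature sampled every 10 s.
This vignette explains the models, the tunable parameters, the synthetic
data generator, and the numerical choices, in the order data flows through
the pipeline.

## Hypnogram metrics

The epoch table is the backbone: one row per 10-s epoch with a state in
{W, N, R} anchored to zeitgeber time. On top of it:

* **Bouts.** A bout of a state is a *maximal* run of at least `min_run`
  consecutive epochs (default 3, i.e. 30 s, the conventional minimum for a
  NREM bout). Shorter runs are excluded entirely, not merged.
* **Latencies.** Latency to a sustained run (REM onset: 3 epochs of REM;
  stable sleep: 6 epochs of NREM *or* REM — "sleep" pools both stages) is
  reported in minutes from an anchor epoch to the *first* epoch of the
  qualifying run (onset convention). A recording that never reaches the run
  yields `NA`; group summaries drop censored values and report how many.
* **Quiet wakefulness (QW).** Wake epochs whose EMG peak-to-peak amplitude
  is at or below the 33rd percentile of EMG over *all wake epochs of the
  analysed segment*. The percentile estimator is linear interpolation
  between order statistics (`stats::quantile` type 7), configurable via
  `type`; the `<=` comparison means ties are included. Scoping the
  percentile to the analysed segment (baseline and work summarised
  separately, per animal) was a genuinely open choice — a per-condition or
  whole-study window is equally defensible — and the threshold is exposed in
  the output so either can be audited.
* **Binned time-in-state.** Minutes per state per bin (2 h default) with
  cumulative curves; bins are aligned to the series start (ZT0 in all
  generated data) and a partial trailing bin is dropped rather than
  extrapolated.

## EEG slow-wave activity and energy

SWA is the spectral power of the unfiltered EEG in 1–4 Hz (both edges
inclusive), computed per 10-s epoch by FFT without tapering — a Hann taper
exists behind a flag but is off by default, since epoch-mean power of broad
slow waves does not need leakage control at 0.1 Hz resolution. The
periodogram is scaled so the positive-frequency ordinates sum to the epoch
variance; SWA is the sum of in-band ordinates (31 bins at 250 Hz sampling).

Artifact epochs are flagged when SWA exceeds the segment mean by 5 standard
deviations, in a single non-iterative pass per animal and segment; the
visual-inspection step used alongside such filters in practice is out of
scope. With a zero SD (constant SWA) nothing is flagged.

Normalization divides each epoch's SWA by the mean baseline SWA of the same
state at the corresponding circadian time. "Corresponding circadian time"
is operationalised as 2-h ZT bins, matching the 2-h reporting granularity
used throughout; the bin width is a parameter. A missing baseline cell is a
hard error naming the (state, bin) cell, never silent imputation. Note the
identity this implies: self-normalization gives values averaging exactly 1
*within each cell*, and exactly 1 per epoch only when SWA is constant
within the cell.

Slow-wave energy per 2-h bin is (epoch count in state) × (mean SWA in
state), which algebraically equals the sum of per-epoch SWA in that state —
the tests assert this identity against direct summation. SWE is computed on
raw SWA by default with `normalized = TRUE` available, because published
descriptions are ambiguous about which scale enters the product; both are
supported and clearly labelled.

## Temperature rhythm

The cleaning chain is: moving-window artifact filter → baseline-delta
normalization → 5-min binning → cosinor.

* **Artifact filter.** Windows are non-overlapping blocks of 100
  consecutive samples ("100 data points at a time" read block-wise; a
  sliding centered window is available for sensitivity analysis). A sample
  is flagged when it deviates from its window mean by more than 2 °C *or*
  more than 5 window SDs — OR being the conservative combination. Flagged
  samples are masked, never deleted. Window statistics include the
  candidate sample; with a 5–6 °C spike in a 100-sample window this still
  flags reliably (the spike shifts the mean by ~0.05 °C), and the injected-
  artifact tests confirm ≥ 95 % sensitivity at the default spike magnitude.
* **Baseline normalization** subtracts the mean over the baseline window
  (4 days by default) so the baseline average is 0; re-application is a
  no-op. The normalization window (4 days) and the cosinor span (72 h) are
  deliberately separate parameters rather than reconciled, since they serve
  different purposes (a level shift vs a rhythm fit).
* **5-min bins** average the non-artifact samples per bin; empty bins stay
  missing and are simply omitted from the cosinor design (no imputation).
* **Cosinor.** `y = M + A·cos(2π(t − φ)/24)` is linear in
  (M, β_c, β_s) after expanding the cosine; the fit is ordinary least
  squares, `A = √(β_c² + β_s²) ≥ 0` by construction, and
  `φ = atan2(β_s, β_c)·24/2π mod 24` in zeitgeber hours. The period is
  fixed at 24 h — the design is entrained to a 12:12 light–dark cycle —
  and multi-component cosinor, confidence ellipses and zero-amplitude tests
  are out of scope (the residual sum of squares is reported). On a
  noiseless cosine the fit is exact to numerical precision on the raw 10-s
  series; 5-min binning attenuates a 24-h cosine by a factor
  `sinc(π·5/1440) ≈ 1 − 2×10⁻⁵`, which is negligible against biological
  noise but matters if you assert exact recovery after binning.
* **Amplitude change** is work amplitude minus baseline amplitude, each
  from a 72-h fit (negative = damping).

## Group statistics

Between-group comparisons use the pooled-variance Student t with
`df = n₁ + n₂ − 2` (a Welch option exists behind `welch = TRUE` but is not
the default, matching the df convention of the ledger tables). Both raw
vectors and `list(mean, sd, n)` summaries are accepted and agree exactly,
so published summary statistics can be re-analysed directly.

Cohen's d uses the **root-mean-square of the two group SDs** as
denominator, `d = (m₂ − m₁)/√((s₁² + s₂²)/2)`, not the df-weighted pooled
SD. This choice is evidence-driven: on the latency summaries above it gives
0.72 where the df-weighted pooled SD gives 0.77, and only the former
matches the published value this convention was validated against. For
paired designs no single convention could be reverse-engineered from
published numbers, so `paired_t()` reports both candidates (`d_z =
mean(diff)/sd(diff)` and `d_rm` with the RMS-SD denominator) and asserts
neither. Sign convention throughout: experimental (RW/work) minus reference
(AW/baseline).

## The hierarchical regression ledger

Step *k* regresses the outcome on the union of predictor blocks 1..k —
(1) work condition, (2) amplitude change + REM latency, (3) a sleep block,
(4) serum corticosterone — and reports R², adjusted R²
(`1 − (1 − R²)(n − 1)/(n − p − 1)`, which may be negative), the change in
adjusted R² versus the previous step, and the *cumulative-model* overall F
with (p, n − p − 1) degrees of freedom. The cumulative F (rather than a
block-increment partial F) is the reporting convention of the ledger tables
this reproduces; a partial F per block is available via `partial_f = TRUE`
and is tested against `anova()`. Step 3 has three variants —
`sleep_drive` (NREM bout length + QW SWE; the main model),
`cumulative_sleep`, `nrem_swe` — selectable per run.

Missing data are deleted listwise against the *full* predictor set, so all
steps share one n (per outcome, matching designs where different outcomes
retain different animals). Designs down to n − p − 1 = 1 are permitted with
a logged warning rather than refused: tiny-n ledgers are in scope, and the
adjusted R² is exactly the quantity that penalises them. Rank deficiency
(e.g. a variable in two blocks) is a hard error naming the aliased columns.

## The synthetic-telemetry generator

The generator exists so every stage has realistic, fully deterministic
input. `effect_spec()` holds the planted study conditions; defaults were
chosen once from the study design this emulates and are not tuned per run:

| Parameter | Default | Rationale |
|---|---|---|
| dark-phase wake fraction | 0.729 | nocturnal baseline architecture |
| light-phase sleep fraction | 0.716 | diurnal sleep |
| mean wake bout, dark / light | 5 / 2 min | polyphasic rat sleep; yields ~1.5–3 min NREM bouts |
| mean REM bout | 1 min | typical rat REM episode |
| baseline amplitude | 0.64 ± 0.11 °C | per-animal temperature rhythm |
| RW damping | −0.40 °C, SD 0.10 | work-period amplitude change; the SD reflects stable inter-individual damping only, since published spreads of the change (~0.2 °C) also contain day-to-day and fit noise |
| AW damping | −0.08 °C | small, non-significant change |
| temperature noise | 0.20 °C per 10-s sample | telemetry noise |
| wake increment | 0.05 °C | activity masking of the rhythm |
| artifact spikes | 0.1 % of samples, ≥ 6 °C | telemetry dropouts |
| microsleep probability | 0.02 per epoch in shift | sporadic micro-sleep under forced activity |
| QW SWA gain in RW work | ×1.5 | elevated sleep drive in quiet wake |

**Hypnogram.** A three-state Markov chain at epoch resolution with
phase-specific transition matrices (light vs dark) solved *analytically*
from the target stationary distribution and chosen mean wake/REM bout
lengths; REM is entered only from NREM, and wake exits into NREM. During
shift windows the state is forced to wake except micro-sleep epochs. Because
rates come from the stationary solution, pooled baseline fractions land on
the targets up to Markov-chain relaxation at the two phase transitions
(≈ 0.3 percentage points) and Monte-Carlo error — the calibration test
pools 100 simulated days and checks ±2 percentage points.

**Epoch features.** A latent Process-S-like pressure rises exponentially
towards 1 in wake (τ = 8 h) and decays towards 0.15 in sleep (τ = 2.5 h) —
used purely as a generative heuristic, not a fitted two-process model. SWA
= state gain × S × log-normal noise with gains NREM 300 > QW 120 > active
wake 60; wake EMG is a two-component log-normal mixture with a low
(quiet) component of weight 1/3, so the 33rd-percentile rule recovers the
planted component. In RW animals quiet-wake SWA is multiplied by the QW
gain during the work segment.

**Temperature.** MESOR 37.2 °C + cosine with acrophase ZT18, per-animal
baseline amplitude, damped on work days; optional wake increment when a
hypnogram is supplied; Gaussian noise and artifact spikes.

**Outcomes.** Each outcome is a linear model on condition (0/1) and cohort
z-scores of the continuous predictors plus Gaussian noise. The default
coefficients are generator plumbing, not estimates: they were calibrated
once, by simulation at the design's sample sizes, so that the planted
structure is recoverable — the spatial-memory outcome loads most on the
sleep-drive block, then the rhythm block (so the ledger's step-3 gain
exceeds step-2's in ≥ 80 % of cohorts at n = 30), one protein is
condition-dominated, one carries a corticosterone effect, one is mostly
noise — and then frozen. Corticosterone is higher at ZT12 than ZT0 and
reduced under rest work.

**Determinism.** Every animal draws from a stream seeded by
`(seed, animal index)`, so enlarging a cohort never perturbs existing
animals, and identical calls produce byte-identical exported files.

### What the generator does *not* emulate

Real EEG waveforms (features are synthesised at epoch level; raw signals
exist only for unit-testing the band-power FFT), mechanistic
thermoregulation, scorer disagreement, inter-epoch autocorrelation of SWA
beyond Process-S, seasonal or estrous variation, and the full covariance
structure linking an individual animal's sleep architecture to its outcome
values — outcomes are driven by the planted per-animal predictor values
(the amplitude damping shared with the temperature series; summary-level
sleep metrics), not by re-measuring the generated epochs. Passing tests
therefore demonstrate that the *pipeline* recovers planted parameters and
preserves the planted regression structure under realistic noise — not that
the biological effect sizes themselves generalise.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations sized for a
single-CPU laptop: 100 pooled baseline days for architecture calibration, a
17-animal rest-work cohort through the full temperature pipeline for
damping recovery, 500 replicate ledgers for block-power rates, 200
replicate cohorts for the qualitative ledger pattern, and 1000 random
hypnograms against the brute-force bout oracle. Tolerances follow from the
model: exact identities at 1e-9–1e-12, noiseless fits at 1e-6, calibration
targets at the Monte-Carlo error of the chosen sizes (±2 percentage points
for the dark-wake fraction, ±0.05 °C for mean damping). Ties in the QW
percentile are included by the `<=` rule; degenerate inputs (zero variance,
constant series, empty baseline cells, all-missing bins) raise typed errors
or return the documented zero-flag behaviour rather than NaN.

## Known limitations

Single-component 24-h cosinor only; no population-mean cosinor or rhythm
detection test. The artifact filter's block windows make flags weakly
dependent on block alignment near boundaries. The ledger deliberately
implements no multiple-testing correction (α = 0.05 convention of the
design it mirrors) and no regularised or mixed-effects alternatives; with
n − p − 1 as low as 1 its F tests are fragile, which is exactly why the
adjusted-R²-change reading is emphasised.
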