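# shiftsleep

Analysis toolkit for rodent **simulated shift-work** studies: hypnogram
metrics, EEG slow-wave activity/energy, body-temperature cosinor
rhythmometry, effect-size statistics and a hierarchical regression ledger —
plus a deterministic synthetic-telemetry generator so the whole pipeline is
testable without raw telemetry.

## Who it is for, and what it computes

Chronobiology and sleep labs that expose rats to forced activity either in
the circadian rest phase (simulated night shift, *rest work*, RW; zeitgeber
time ZT2–10) or in the active phase (simulated day shift, *active work*,
AW; ZT14–22), record vigilance states (wake/NREM/REM, 10-s epochs), EEG,
EMG and core body temperature, and then ask which physiological changes
predict cognitive and molecular outcomes.

The package implements that analysis chain:

* **Hypnogram metrics** — state bouts (a NREM bout = ≥ 3 consecutive 10-s
  epochs), latency to a sustained run of target states (REM latency = 3
  consecutive REM epochs; stable-sleep latency = 6 consecutive sleep
  epochs), binned/cumulative time-in-state, and **quiet wakefulness** (wake
  epochs with EMG peak-to-peak amplitude ≤ the 33rd percentile of wake EMG).
* **EEG spectral** — per-epoch slow-wave activity (SWA; spectral power in
  1–4 Hz by FFT over 10-s epochs), automated artifact rejection (power >
  mean + 5 SD), normalization to baseline state × circadian-time means, and
  slow-wave energy, SWE = (epochs in state per 2 h) × (mean SWA in state),
  with cumulative trajectories.
* **Temperature rhythm** — moving-window artifact filter (|x − window mean|
  > 2 °C or > 5 SD over 100-sample windows), baseline-delta normalization,
  5-min binning, and a fixed-period **cosinor fit**

  `y(t) = M + A·cos(2π(t − φ)/τ) + e(t)`, τ = 24 h,

  estimated by least squares on cos/sin regressors; amplitude change from
  baseline is computed by subtraction.
* **Group statistics** — pooled-variance Student t (df = n₁ + n₂ − 2) from
  raw vectors *or* printed summary statistics, Cohen's d with the
  root-mean-square-SD denominator `d = Δm / √((s₁² + s₂²)/2)`, paired t,
  Pearson r.
* **Hierarchical regression ledger** — ordered predictor blocks
  (1 work condition, 2 daily-rhythm dynamics, 3 sleep drive, 4 serum
  corticosterone); step *k* fits the outcome on blocks 1..k and reports R²,
  adjusted R² = 1 − (1 − R²)(n − 1)/(n − p − 1), the change in adjusted R²,
  and the overall F per step — the machinery for asking whether rhythm and
  sleep-drive markers predict Morris Water Maze performance and cortical
  protein expression beyond work condition alone.
* **Synthetic telemetry** — a semi-Markov hypnogram generator calibrated to
  nocturnal rat architecture (≈ 72.9 % wake in the dark phase), forced-wake
  shifts with sporadic micro-sleep, Process-S-like SWA, two-component wake
  EMG, 24-h temperature rhythms with condition-dependent amplitude damping
  (−0.40 °C for rest work) and injected artifacts, and linear outcome
  models; fully deterministic given a seed.

## Worked example

```r
library(shiftsleep)

cohort <- simulate_cohort(n_rw = 5, n_aw = 4, days_baseline = 4,
                          days_work = 3, seed = 11)
report <- run_study(cohort)

dplyr::select(report$comparisons, metric, t, df, p, d)
#>   metric                 t    df       p      d
#> 1 amp_change        -5.26      7 0.00118 -3.38
#> 2 rem_latency_min   -0.692     7 0.511   -0.452
#> 3 sleep_latency_min -2.06      7 0.0778  -1.29
#> ...

report$paired_amplitude
#>       t    df        p   d_z  d_rm mean_diff n
#> 1 -14.2     4 0.000145 -6.33 -6.04    -0.466 5

report$ledgers$mwm_latency
#> Hierarchical regression ledger: mwm_latency (n = 9)
#>  step                 block    r2 adj_r2 delta_adj_r2     f df1 df2 p_value
#>     1        work condition 0.688  0.643           NA 15.43   1   7 0.00569
#>     2 daily rhythm dynamics 0.724  0.559      -0.0845  4.38   3   5 0.07283
#>     3           sleep drive 0.887  0.698       0.1388  4.69   5   3 0.11669
```

The group table compares rest workers against active workers per metric
(positive t/d = higher in rest work); the paired row shows the within-RW
temperature-amplitude damping during work (−0.466 °C here, planted mean
−0.40); the ledger rows show how much each predictor block adds to the
adjusted R² for spatial-memory latency.

Statistics can also be computed straight from published summary
statistics — e.g. stable-sleep latency in rest workers (13.8 ± 9.5 min,
n = 17) vs active workers (32.1 ± 34.6 min, n = 13):

```r
two_sample_t(list(mean = 32.1, sd = 34.6, n = 13),
             list(mean = 13.8, sd = 9.5, n = 17))
#>       t    df      p      d mean1 mean2 n1 n2
#> 1 -2.09    28 0.0458 -0.721  32.1  13.8 13 17
```

A thin command-line wrapper with subcommands `simulate`,
`hypnogram-metrics`, `swe`, `cosinor`, `compare`, `ledger` and `run-study`
ships in `inst/cli/shiftsleep`.

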