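Package: shiftsleep
Title: Sleep, Circadian Rhythm and Regression-Ledger Analysis for Simulated Shift-Work Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for rodent simulated shift-work studies combining
    epoch-scored hypnograms, EEG slow-wave activity and energy, body-temperature
    cosinor rhythmometry, effect-size statistics and hierarchical multiple
    regression. Provides hypnogram bout and latency metrics, quiet-wakefulness
    classification from EMG amplitude, per-epoch slow-wave activity with
    automated artifact rejection and baseline normalization, slow-wave energy
    trajectories, moving-window temperature artifact filtering, fixed-period
    cosinor fits with amplitude-change accounting, summary-statistic t-tests
    with the root-mean-square-SD Cohen's d convention, an ordered-block
    hierarchical regression ledger with adjusted R-squared change, and a
    deterministic synthetic-telemetry generator so that every pipeline stage is
    testable without raw telemetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    withr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
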