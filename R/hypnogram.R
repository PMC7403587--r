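#' Detect state bouts in a hypnogram
#'
#' A bout is a maximal run of consecutive epochs in the target state with at
#' least `min_run` epochs. The canonical use is NREM sleep bouts, defined as
#' three or more consecutive 10-s epochs of NREM sleep; shorter runs are
#' excluded entirely.
#'
#' @param epochs An epoch table (see [epoch_table()]).
#' @param state Target vigilance state (any accepted code, see [as_state()]).
#' @param min_run Minimum run length in epochs (default 3).
#' @return A tibble with one row per bout: `state`, `start_index` (0-based
#'   epoch index), `n_epochs`, `duration_s`, ordered by `start_index`.
#' @examples
#' ep <- epoch_table(c("W", "N", "N", "N", "W", "N", "N", "R",
#'                     "N", "N", "N", "N"))
#' detect_bouts(ep, "N", min_run = 3)
#' @export
detect_bouts <- function(epochs, state, min_run = 3) {
  .check_epochs(epochs)
  if (min_run < 1) abort("`min_run` must be a positive integer.")
  state <- as_state(state)
  r <- rle(epochs$state == state)
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  keep <- r$values & r$lengths >= min_run
  tibble(
    state = state,
    start_index = epochs$epoch_index[1] + start[keep],
    n_epochs = r$lengths[keep],
    duration_s = r$lengths[keep] * 10
  )
}

#' Latency to a sustained run of target states
#'
#' Minutes from the anchor epoch to the first epoch of the first run of at
#' least `run_len` consecutive epochs whose state is in `target_states`.
#' Used for REM-sleep latency (3 consecutive REM epochs) and stable-sleep
#' latency (6 consecutive epochs of sleep, NREM or REM combined). Returns
#' `NA` when no qualifying run exists before the end of the series (a
#' censored latency; callers decide how to handle censoring).
#'
#' @param epochs An epoch table.
#' @param target_states States counting towards the run, e.g. `"R"` or
#'   `c("N", "R")`.
#' @param run_len Required run length in epochs.
#' @param from_index Anchor epoch index (0-based, in `epoch_index` units);
#'   defaults to the first epoch.
#' @return Latency in minutes (0 if the run starts at the anchor), or `NA`.
#' @examples
#' ep <- epoch_table(rep(c("W", "N"), c(30, 10)))
#' latency_to_run(ep, c("N", "R"), run_len = 6)  # 5 minutes
#' @export
latency_to_run <- function(epochs, target_states, run_len, from_index = NULL) {
  .check_epochs(epochs)
  if (run_len < 1) abort("`run_len` must be a positive integer.")
  target_states <- as_state(target_states)
  from_index <- from_index %||% epochs$epoch_index[1]
  sub <- epochs[epochs$epoch_index >= from_index, , drop = FALSE]
  if (nrow(sub) == 0L) abort("`from_index` lies beyond the end of the series.")
  hit <- sub$state %in% target_states
  r <- rle(hit)
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  ok <- r$values & r$lengths >= run_len
  if (!any(ok)) return(NA_real_)
  start[ok][1] * 10 / 60
}

#' Time in state per bin, with cumulative curves
#'
#' Sums minutes spent in each vigilance state per ZT-aligned bin (2 h by
#' default, the reporting granularity for cumulative sleep-wake data) and
#' accumulates the running total per state. Bins are aligned to the start of
#' the series; a partial trailing bin is dropped.
#'
#' @param epochs An epoch table.
#' @param bin_hours Bin width in hours (default 2).
#' @return A tibble with `bin` (0-based), `zt_start`, `state`, `minutes`,
#'   `cum_minutes`; every state appears in every bin (0 if absent).
#' @export
time_in_state_binned <- function(epochs, bin_hours = 2) {
  .check_epochs(epochs)
  if (bin_hours <= 0) abort("`bin_hours` must be positive.")
  per_bin <- as.integer(round(bin_hours * 360))  # 10-s epochs per bin
  n_bins <- nrow(epochs) %/% per_bin
  if (n_bins == 0L) abort("Series shorter than one bin; nothing to summarise.")
  used <- epochs[seq_len(n_bins * per_bin), , drop = FALSE]
  used$bin <- rep(seq_len(n_bins) - 1L, each = per_bin)
  zt0 <- vapply(split(used$zt_hours, used$bin), `[`, numeric(1), 1)
  grid <- tidyr::expand_grid(bin = seq_len(n_bins) - 1L, state = unname(.states))
  used |>
    group_by(.data$bin, .data$state) |>
    summarise(minutes = n() * 10 / 60, .groups = "drop") |>
    dplyr::right_join(grid, by = c("bin", "state")) |>
    mutate(minutes = tidyr::replace_na(.data$minutes, 0)) |>
    arrange(.data$state, .data$bin) |>
    group_by(.data$state) |>
    mutate(cum_minutes = cumsum(.data$minutes)) |>
    ungroup() |>
    mutate(zt_start = zt0[as.character(.data$bin)]) |>
    select("bin", "zt_start", "state", "minutes", "cum_minutes") |>
    arrange(.data$bin, .data$state)
}

#' Classify quiet wakefulness from EMG amplitude
#'
#' Quiet wakefulness (QW) is operationalised as wake epochs whose EMG
#' peak-to-peak amplitude is at or below the 33rd percentile of EMG values
#' across all wake epochs of the analysed segment. The percentile is
#' estimated with linear interpolation between order statistics
#' (`stats::quantile` type 7) by default.
#'
#' @param epochs An epoch table carrying an `emg_ptp` column (or supplied
#'   via `emg_ptp`).
#' @param emg_ptp Optional per-epoch EMG amplitude vector overriding the
#'   table column; must align 1:1 with rows.
#' @param prob Percentile defining the QW threshold (default 0.33).
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return The epoch table with a logical `quiet_wake` column (TRUE only on
#'   wake epochs at or below threshold) and attribute `qw_threshold`.
#' @export
classify_quiet_wake <- function(epochs, emg_ptp = NULL, prob = 0.33, type = 7) {
  .check_epochs(epochs)
  emg <- emg_ptp %||% .col_or(epochs, "emg_ptp", NULL)
  if (is.null(emg)) abort("No `emg_ptp` column or argument supplied.")
  if (length(emg) != nrow(epochs)) {
    abort("`emg_ptp` must align 1:1 with the epoch table.")
  }
  wake <- epochs$state == "W"
  if (!any(wake)) abort("No wake epochs: quiet-wake threshold is undefined.")
  thr <- unname(stats::quantile(emg[wake], prob, type = type, na.rm = TRUE))
  out <- mutate(epochs, quiet_wake = wake & emg <= thr)
  attr(out, "qw_threshold") <- thr
  out
}

#' Quiet-wake threshold of a classified epoch table
#' @param epochs Output of [classify_quiet_wake()].
#' @return The EMG threshold used.
#' @export
qw_threshold <- function(epochs) attr(epochs, "qw_threshold")
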