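#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter group_by ungroup summarise arrange select
#'   bind_rows left_join n across all_of
#' @importFrom tibble tibble as_tibble
NULL

# Canonical vigilance-state codes. Readers are case-insensitive and accept
# long names; everything is stored single-letter.
.states <- c(WAKE = "W", NREM = "N", REM = "R")

#' Normalise vigilance-state codes
#'
#' Accepts `"W"/"N"/"R"` (any case) or the long names `WAKE`, `NREM`, `REM`
#' and returns canonical single-letter codes.
#'
#' @param x Character vector of state labels.
#' @return Character vector over `c("W", "N", "R")`.
#' @export
as_state <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- ifelse(up %in% .states, up, unname(.states[up]))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort(paste0(
      "Unknown vigilance state code(s): ",
      paste(unique(up[bad]), collapse = ", "),
      ". Expected W/N/R or WAKE/NREM/REM."
    ))
  }
  out
}

#' Build an epoch table
#'
#' Constructs the canonical epoch table used throughout the package: one row
#' per 10-s scored epoch, anchored to zeitgeber time (ZT; hours since lights
#' on). This is the hypnogram backbone onto which per-epoch EEG slow-wave
#' activity (`swa`) and EMG peak-to-peak amplitude (`emg_ptp`) are aligned.
#'
#' @param states Character vector of vigilance states (see [as_state()]).
#' @param t0_zt Zeitgeber time of the first epoch, hours in `[0, 24)`.
#' @param epoch_s Epoch length in seconds (fixed at 10 by the scoring design).
#' @param animal_id Identifier recycled across rows.
#' @param swa Optional per-epoch slow-wave activity (1-4 Hz band power).
#' @param emg_ptp Optional per-epoch EMG peak-to-peak amplitude.
#' @param schedule_tag Per-epoch label in `BASELINE`, `WORK`, `OFF_WORK`.
#' @return A tibble with columns `animal_id`, `epoch_index` (0-based),
#'   `zt_hours`, `state`, `swa`, `emg_ptp`, `schedule_tag`.
#' @examples
#' epoch_table(c("W", "W", "N", "N", "N", "R"))
#' @export
epoch_table <- function(states, t0_zt = 0, epoch_s = 10, animal_id = "a1",
                        swa = NA_real_, emg_ptp = NA_real_,
                        schedule_tag = "BASELINE") {
  states <- as_state(states)
  if (length(states) == 0L) abort("Epoch series must be non-empty.")
  if (!identical(as.numeric(epoch_s), 10)) {
    abort("Epoch length is fixed at 10 s by the scoring design.")
  }
  if (t0_zt < 0 || t0_zt >= 24) abort("`t0_zt` must lie in [0, 24).")
  i <- seq_along(states) - 1L
  tibble(
    animal_id = as.character(animal_id),
    epoch_index = i,
    zt_hours = (t0_zt + i * epoch_s / 3600) %% 24,
    state = states,
    swa = as.numeric(swa),
    emg_ptp = as.numeric(emg_ptp),
    schedule_tag = as.character(schedule_tag)
  )
}

.check_epochs <- function(epochs) {
  need <- c("epoch_index", "zt_hours", "state")
  miss <- setdiff(need, names(epochs))
  if (length(miss) > 0) {
    abort(paste0("Epoch table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(epochs) == 0L) abort("Epoch table is empty.")
  invisible(epochs)
}

#' Read and write epoch tables
#'
#' The interchange format is tab-separated text with a header and one row per
#' 10-s epoch: `animal_id, epoch_index, zt_hours, state, swa, emg_ptp,
#' schedule_tag`. State codes are read case-insensitively.
#'
#' @param file Path to a tab-separated epoch table.
#' @return A tibble in canonical epoch-table form.
#' @export
read_epoch_table <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  .check_epochs(x)
  x$state <- as_state(x$state)
  x
}

#' @rdname read_epoch_table
#' @param epochs An epoch table.
#' @export
write_epoch_table <- function(epochs, file) {
  .check_epochs(epochs)
  readr::write_tsv(epochs, file, progress = FALSE)
  invisible(file)
}

# Column if present, else a default (avoids tibble's unknown-column warning).
.col_or <- function(tbl, name, default) {
  if (name %in% names(tbl)) tbl[[name]] else default
}

# ZT bin label for a vector of ZT hours: left-closed bins aligned to ZT0.
zt_bin <- function(zt_hours, bin_hours = 2) {
  floor((zt_hours %% 24) / bin_hours) * bin_hours
}
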