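#' Per-epoch EEG band power (slow-wave activity)
#'
#' Splits a raw EEG trace into consecutive fixed-length epochs, computes the
#' periodogram of each epoch by FFT (no tapering by default, matching
#' analysis of unfiltered signals; a Hann taper is available), and returns
#' the total spectral power within the band for each epoch. With the default
#' 1-4 Hz band this is the slow-wave activity (SWA) used as an index of
#' sleep intensity (NREM) and homeostatic sleep drive (quiet wakefulness).
#'
#' The periodogram is scaled so that the sum over all positive-frequency
#' ordinates equals the epoch variance (Parseval); a unit-amplitude sinusoid
#' at an on-grid frequency contributes power 1/2 at its bin. Band edges are
#' inclusive on both ends.
#'
#' @param signal Numeric vector of raw EEG samples.
#' @param fs Sampling rate in Hz (250 for the telemetry system modelled).
#' @param band Two-element numeric band in Hz, default `c(1, 4)`.
#' @param epoch_s Epoch length in seconds (default 10).
#' @param taper `"none"` (default) or `"hann"`.
#' @return Numeric vector of per-epoch band power, one value per complete
#'   epoch (a trailing partial epoch is an error).
#' @export
epoch_band_power <- function(signal, fs = 250, band = c(1, 4), epoch_s = 10,
                             taper = c("none", "hann")) {
  taper <- match.arg(taper)
  if (length(band) != 2 || band[1] < 0 || band[2] > fs / 2 || band[1] > band[2]) {
    abort("`band` must lie within [0, fs/2] with band[1] <= band[2].")
  }
  n <- as.integer(round(fs * epoch_s))
  if (length(signal) == 0L || length(signal) %% n != 0L) {
    abort("Signal length must be a positive integer multiple of epoch samples.")
  }
  m <- matrix(signal, nrow = n)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    m <- m * (w / sqrt(mean(w^2)))
  }
  m <- sweep(m, 2, colMeans(m))  # remove per-epoch DC
  ft <- stats::mvfft(m)
  freqs <- (seq_len(n %/% 2)) * fs / n       # positive frequencies, excl. DC
  k <- which(freqs >= band[1] & freqs <= band[2])
  # two-sided -> one-sided power: 2|X|^2/n^2 per positive bin (Nyquist bin
  # would need factor 1, but it never falls in a sub-Nyquist band of interest)
  p <- 2 * abs(ft[k + 1L, , drop = FALSE])^2 / n^2
  if (n %% 2 == 0 && length(k) > 0 && max(k) == n %/% 2) {
    p[which(k == n %/% 2), ] <- p[which(k == n %/% 2), ] / 2
  }
  colSums(p)
}

#' Flag artifact epochs from the SWA series
#'
#' Automated spectral artifact detection: an epoch is flagged when its power
#' exceeds the segment mean by at least `k` standard deviations. Mean and SD
#' are computed in a single pass over all epochs of the recording segment;
#' when the SD is zero nothing is flagged.
#'
#' @param swa Numeric vector of per-epoch spectral power.
#' @param k Threshold in standard deviations (default 5).
#' @return Logical vector, `TRUE` where the epoch is an artifact.
#' @export
reject_artifacts <- function(swa, k = 5) {
  if (length(swa) < 2) abort("Need at least 2 epochs to estimate mean and SD.")
  s <- stats::sd(swa, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(FALSE, length(swa)))
  !is.na(swa) & swa > mean(swa, na.rm = TRUE) + k * s
}

#' Add an artifact flag column to an epoch table
#'
#' Convenience wrapper applying [reject_artifacts()] to the `swa` column,
#' per animal and schedule segment.
#'
#' @param epochs An epoch table with an `swa` column.
#' @param k Threshold in standard deviations.
#' @return The epoch table with a logical `artifact` column.
#' @export
flag_swa_artifacts <- function(epochs, k = 5) {
  .check_epochs(epochs)
  epochs |>
    group_by(.data$animal_id, .data$schedule_tag) |>
    mutate(artifact = reject_artifacts(.data$swa, k = k)) |>
    ungroup()
}

#' Normalize SWA to baseline circadian reference
#'
#' Divides each epoch's SWA by the mean baseline SWA of the same vigilance
#' state at the corresponding circadian time (2-h ZT bin by default), per
#' animal. Artifact epochs are excluded from both the normalized values and
#' the reference means. A missing reference cell — a (state, ZT-bin)
#' combination present in `epochs` but absent from the baseline — is an
#' explicit error naming the cell.
#'
#' @param epochs Epoch table to normalise (must carry `swa`; `artifact`
#'   optional).
#' @param baseline Baseline epoch table for the same animal.
#' @param bin_hours ZT bin width defining "corresponding circadian time".
#' @return `epochs` with an added `swa_norm` column (dimensionless;
#'   `NA` on artifact epochs).
#' @export
normalize_to_baseline <- function(epochs, baseline, bin_hours = 2) {
  .check_epochs(epochs); .check_epochs(baseline)
  art_b <- .col_or(baseline, "artifact", rep(FALSE, nrow(baseline)))
  ref <- baseline[!art_b & !is.na(baseline$swa), , drop = FALSE] |>
    mutate(ztb = zt_bin(.data$zt_hours, bin_hours)) |>
    group_by(.data$state, .data$ztb) |>
    summarise(ref_mean = mean(.data$swa), .groups = "drop")
  art_e <- .col_or(epochs, "artifact", rep(FALSE, nrow(epochs)))
  out <- epochs |>
    mutate(ztb = zt_bin(.data$zt_hours, bin_hours)) |>
    left_join(ref, by = c("state", "ztb"))
  need <- !art_e & !is.na(out$swa)
  missing_cell <- need & is.na(out$ref_mean)
  if (any(missing_cell)) {
    cells <- unique(paste0(
      "(", out$state[missing_cell], ", ZT[", out$ztb[missing_cell], ",",
      out$ztb[missing_cell] + bin_hours, "))"
    ))
    abort(paste0(
      "No baseline reference for cell(s): ", paste(cells, collapse = ", ")
    ))
  }
  out$swa_norm <- ifelse(need, out$swa / out$ref_mean, NA_real_)
  out$ztb <- NULL
  out$ref_mean <- NULL
  out
}

#' Slow-wave energy per bin and cumulative trajectory
#'
#' Slow-wave energy (SWE) integrates SWA over time within a state: per bin it
#' is the number of epochs in the state times the mean SWA of those epochs —
#' algebraically the sum of per-epoch SWA, which is the identity the
#' implementation is tested against. Computed per 2-h bin by default with a
#' running cumulative sum. Artifact epochs are excluded from both the count
#' and the mean. Bins with no qualifying epochs contribute 0.
#'
#' @param epochs An epoch table with `swa` (and optionally `artifact`,
#'   `swa_norm`, `quiet_wake`).
#' @param state Either a vigilance state code (e.g. `"N"`) or `"QW"` to use
#'   the quiet-wake flag from [classify_quiet_wake()].
#' @param bin_hours Bin width in hours (default 2).
#' @param normalized Use baseline-normalized SWA (`swa_norm`) instead of raw
#'   SWA. Default `FALSE` (raw units).
#' @return A tibble with `bin`, `zt_start`, `n_epochs`, `mean_swa`, `swe`,
#'   `cum_swe`.
#' @export
swe_per_bin <- function(epochs, state = "N", bin_hours = 2, normalized = FALSE) {
  .check_epochs(epochs)
  if (bin_hours <= 0) abort("`bin_hours` must be positive.")
  val <- if (normalized) {
    if (!"swa_norm" %in% names(epochs)) abort("No `swa_norm` column; run normalize_to_baseline() first.")
    epochs$swa_norm
  } else epochs$swa
  art <- .col_or(epochs, "artifact", rep(FALSE, nrow(epochs)))
  in_state <- if (identical(toupper(state), "QW")) {
    if (!"quiet_wake" %in% names(epochs)) abort("No `quiet_wake` column; run classify_quiet_wake() first.")
    epochs$quiet_wake
  } else epochs$state == as_state(state)
  per_bin <- as.integer(round(bin_hours * 360))
  n_bins <- nrow(epochs) %/% per_bin
  if (n_bins == 0L) abort("Series shorter than one bin.")
  idx <- seq_len(n_bins * per_bin)
  d <- tibble(
    bin = rep(seq_len(n_bins) - 1L, each = per_bin),
    zt = epochs$zt_hours[idx],
    ok = in_state[idx] & !art[idx] & !is.na(val[idx]),
    v = val[idx]
  )
  d |>
    group_by(.data$bin) |>
    summarise(
      zt_start = .data$zt[1],
      n_epochs = sum(.data$ok),
      mean_swa = ifelse(sum(.data$ok) > 0, mean(.data$v[.data$ok]), NA_real_),
      .groups = "drop"
    ) |>
    mutate(
      swe = ifelse(.data$n_epochs > 0, .data$n_epochs * .data$mean_swa, 0),
      cum_swe = cumsum(.data$swe)
    )
}
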