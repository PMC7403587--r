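#' Build a temperature table
#'
#' Canonical body-temperature telemetry table: one row per 10-s sample with
#' time in hours from recording start, matching the interchange format
#' `animal_id, t_hours, temp_c` (comma-separated text).
#'
#' @param temp_c Numeric vector of temperatures in degrees Celsius.
#' @param t_hours Sample times in hours; defaults to a 10-s grid from 0.
#' @param animal_id Identifier recycled across rows.
#' @param t0_zt Zeitgeber time at `t_hours == 0`, stored in `zt_hours`.
#' @return A tibble with `animal_id`, `t_hours`, `zt_hours`, `temp_c`,
#'   `artifact` (all `FALSE` initially).
#' @export
temperature_table <- function(temp_c, t_hours = NULL, animal_id = "a1",
                              t0_zt = 0) {
  if (length(temp_c) == 0L) abort("Temperature series must be non-empty.")
  t_hours <- t_hours %||% ((seq_along(temp_c) - 1) * 10 / 3600)
  tibble(
    animal_id = as.character(animal_id),
    t_hours = as.numeric(t_hours),
    zt_hours = (t0_zt + t_hours) %% 24,
    temp_c = as.numeric(temp_c),
    artifact = FALSE
  )
}

.check_temps <- function(temps) {
  miss <- setdiff(c("t_hours", "temp_c"), names(temps))
  if (length(miss) > 0) {
    abort(paste0("Temperature table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(temps) == 0L) abort("Temperature table is empty.")
  invisible(temps)
}

#' Read and write temperature tables
#'
#' Comma-separated text with header `animal_id, t_hours, temp_c`
#' (plus optional `zt_hours`, `artifact`).
#'
#' @param file Path to a CSV temperature file.
#' @return A tibble; an `artifact` column is added (all `FALSE`) if absent.
#' @export
read_temperature_table <- function(file) {
  x <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  .check_temps(x)
  if (!"artifact" %in% names(x)) x$artifact <- FALSE
  if (!"zt_hours" %in% names(x)) x$zt_hours <- x$t_hours %% 24
  x
}

#' @rdname read_temperature_table
#' @param temps A temperature table.
#' @export
write_temperature_table <- function(temps, file) {
  .check_temps(temps)
  readr::write_csv(temps, file, progress = FALSE)
  invisible(file)
}

#' Moving-window temperature artifact filter
#'
#' Masks telemetry artifacts with a moving window over `window_n` consecutive
#' samples (non-overlapping blocks; the window statistics include the
#' candidate sample). A sample is flagged when it deviates from the window
#' mean by more than `abs_limit_c` degrees OR by more than `sd_limit` window
#' standard deviations — the OR being the conservative exclusion. Flagged
#' samples are masked via the `artifact` column, never deleted. A sliding
#' centered window is available for sensitivity analysis.
#'
#' @param temps A temperature table.
#' @param window_n Window length in samples (default 100).
#' @param abs_limit_c Absolute deviation limit in degrees C (default 2).
#' @param sd_limit Deviation limit in window SDs (default 5).
#' @param method `"block"` (default) or `"sliding"` (centered window).
#' @return The table with `artifact` set `TRUE` on flagged samples (existing
#'   flags are kept).
#' @export
remove_temp_artifacts <- function(temps, window_n = 100, abs_limit_c = 2,
                                  sd_limit = 5, method = c("block", "sliding")) {
  .check_temps(temps)
  method <- match.arg(method)
  x <- temps$temp_c
  n <- length(x)
  if (n < window_n) {
    warn("Series shorter than one window; using whole-series statistics.")
    window_n <- n
  }
  if (method == "block") {
    blk <- (seq_len(n) - 1L) %/% window_n
    # fold a short trailing block into the previous one
    if (n %% window_n != 0L && n > window_n) {
      blk[blk == max(blk)] <- max(blk) - 1L
    }
    mu <- stats::ave(x, blk, FUN = mean)
    sd_w <- stats::ave(x, blk, FUN = stats::sd)
  } else {
    half <- window_n %/% 2
    mu <- sd_w <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      mu[i] <- mean(x[j]); sd_w[i] <- stats::sd(x[j])
    }
  }
  dev <- abs(x - mu)
  sd_w[is.na(sd_w)] <- 0
  flag <- dev > abs_limit_c | (sd_w > 0 & dev > sd_limit * sd_w)
  mutate(temps, artifact = (.col_or(temps, "artifact", FALSE)) | flag)
}

#' Normalize temperature to baseline delta
#'
#' Subtracts the mean non-artifact temperature over the baseline window
#' (4 days by default) so the baseline average is 0. Re-application with the
#' same window is a no-op.
#'
#' @param temps A temperature table.
#' @param baseline_hours Baseline window length in hours from `t_hours == 0`
#'   (default 96 = 4 days).
#' @return The table with `temp_c` replaced by the baseline delta and
#'   attribute `baseline_delta = TRUE`.
#' @export
normalize_baseline_temp <- function(temps, baseline_hours = 96) {
  .check_temps(temps)
  in_base <- temps$t_hours < baseline_hours & !(.col_or(temps, "artifact", FALSE)) &
    !is.na(temps$temp_c)
  if (!any(in_base)) abort("Baseline window is empty; cannot normalize.")
  out <- mutate(temps, temp_c = .data$temp_c - mean(temps$temp_c[in_base]))
  attr(out, "baseline_delta") <- TRUE
  out
}

#' Average temperature into 5-min bins
#'
#' Each bin is the mean of its non-artifact samples; bins with no usable
#' sample are kept with `temp_c = NA` (missing, never imputed).
#'
#' @param temps A temperature table.
#' @param bin_min Bin width in minutes (default 5).
#' @return A temperature table at bin resolution; `t_hours`/`zt_hours` are
#'   bin midpoints.
#' @export
bin_temperature <- function(temps, bin_min = 5) {
  .check_temps(temps)
  bw <- bin_min / 60
  art <- .col_or(temps, "artifact", FALSE)
  zt0 <- if (!"zt_hours" %in% names(temps)) 0 else (temps$zt_hours[1] - temps$t_hours[1]) %% 24
  temps |>
    mutate(
      .bin = floor(.data$t_hours / bw),
      .use = !art & !is.na(.data$temp_c)
    ) |>
    group_by(.data$animal_id, .data$.bin) |>
    summarise(
      mid = (.data$.bin[1] + 0.5) * bw,
      temp_c = ifelse(any(.data$.use), mean(.data$temp_c[.data$.use]), NA_real_),
      n_samples = sum(.data$.use),
      .groups = "drop"
    ) |>
    mutate(
      t_hours = .data$mid,
      zt_hours = (zt0 + .data$mid) %% 24,
      artifact = FALSE
    ) |>
    arrange(.data$animal_id, .data$t_hours) |>
    select("animal_id", "t_hours", "zt_hours", "temp_c", "n_samples", "artifact")
}
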