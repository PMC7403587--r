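#' Per-animal study metrics from epoch and temperature tables
#'
#' Computes, for one animal, the study's per-animal summary metrics:
#' temperature-rhythm amplitude change (cosinor on 5-min bins, baseline vs
#' work span), REM-sleep latency and stable-sleep latency after a chosen
#' work shift, mean NREM bout length across the work period, cumulative
#' slow-wave energy in quiet wakefulness and NREM sleep over the work
#' segment, and time in each vigilance state.
#'
#' @param epochs Epoch table for one animal (baseline + work days).
#' @param temps Temperature table for the same animal (may be `NULL`).
#' @param condition `"RW"` or `"AW"` (sets the shift window).
#' @param days_baseline,days_work Study layout in days.
#' @param rem_after_shift Which shift's end anchors the REM/stable-sleep
#'   latencies (default 2: not all animals enter REM after the final shift).
#' @param bout_min_run Minimum NREM bout length in epochs (default 3).
#' @param rem_run_len,sleep_run_len Run lengths defining REM onset (3 epochs)
#'   and stable sleep (6 epochs of NREM or REM).
#' @param cosinor_span_h Span of each cosinor fit in hours (default 72).
#' @param bin_hours SWE/report bin width in hours (default 2).
#' @return One-row tibble of metrics; censored latencies are `NA`.
#' @export
animal_metrics <- function(epochs, temps = NULL, condition = "RW",
                           days_baseline = 4, days_work = 3,
                           rem_after_shift = 2, bout_min_run = 3,
                           rem_run_len = 3, sleep_run_len = 6,
                           cosinor_span_h = 72, bin_hours = 2) {
  .check_epochs(epochs)
  base_epochs <- days_baseline * 8640L
  work <- epochs[epochs$epoch_index >= base_epochs, , drop = FALSE]
  ww <- work_window_zt(condition)
  anchor <- base_epochs + (rem_after_shift - 1L) * 8640L + as.integer(ww[2] * 360)
  rem_lat <- latency_to_run(epochs, "R", rem_run_len, from_index = anchor)
  sleep_lat <- latency_to_run(epochs, c("N", "R"), sleep_run_len, from_index = anchor)
  bouts <- detect_bouts(work, "N", min_run = bout_min_run)
  qw <- classify_quiet_wake(flag_swa_artifacts(work))
  swe_qw <- swe_per_bin(qw, state = "QW", bin_hours = bin_hours)
  swe_nrem <- swe_per_bin(qw, state = "N", bin_hours = bin_hours)
  tis <- time_in_state_binned(work, bin_hours = bin_hours)
  totals <- tis |>
    group_by(.data$state) |>
    summarise(minutes = sum(.data$minutes), .groups = "drop")
  tot <- function(s) {
    v <- totals$minutes[totals$state == s]
    if (length(v) == 0) 0 else v
  }
  amp <- tibble(baseline_amp = NA_real_, work_amp = NA_real_, delta = NA_real_)
  if (!is.null(temps)) {
    clean <- remove_temp_artifacts(temps)
    clean <- normalize_baseline_temp(clean, baseline_hours = days_baseline * 24)
    bins <- bin_temperature(clean)
    base_start <- max(0, days_baseline * 24 - cosinor_span_h)
    fit_b <- cosinor_fit(bins, span_h = cosinor_span_h, t_start = base_start)
    fit_w <- cosinor_fit(bins, span_h = min(cosinor_span_h, days_work * 24),
                         t_start = days_baseline * 24)
    amp <- amplitude_change(fit_b, fit_w)
  }
  tibble(
    animal_id = epochs$animal_id[1],
    condition_label = condition,
    condition = as.numeric(condition == "RW"),
    amp_baseline = amp$baseline_amp,
    amp_work = amp$work_amp,
    amp_change = amp$delta,
    rem_latency_min = rem_lat,
    sleep_latency_min = sleep_lat,
    nrem_bout_min = if (nrow(bouts) > 0) mean(bouts$n_epochs) * 10 / 60 else NA_real_,
    qw_swe = max(swe_qw$cum_swe),
    nrem_swe = max(swe_nrem$cum_swe),
    qw_threshold = qw_threshold(qw),
    wake_min = tot("W"),
    cum_nrem_min = tot("N"),
    cum_rem_min = tot("R")
  )
}

#' Group comparisons for the per-animal metric table
#'
#' Runs the pooled-variance two-sample t-test with the RMS-SD Cohen's d for
#' each metric, AW as reference and RW as experimental group (so positive t
#' and d mean RW > AW).
#'
#' @param metrics Per-animal metric table (one row per animal with a
#'   `condition_label` column).
#' @param vars Metric columns to compare.
#' @return Tibble `metric, t, df, p, d, mean_aw, mean_rw, n_aw, n_rw,
#'   n_censored`.
#' @export
compare_groups <- function(metrics,
                           vars = c("amp_change", "rem_latency_min",
                                    "sleep_latency_min", "nrem_bout_min",
                                    "qw_swe", "nrem_swe", "wake_min",
                                    "cum_nrem_min", "cum_rem_min")) {
  vars <- intersect(vars, names(metrics))
  purrr::map_dfr(vars, function(v) {
    aw <- metrics[[v]][metrics$condition_label == "AW"]
    rw <- metrics[[v]][metrics$condition_label == "RW"]
    n_cens <- sum(is.na(c(aw, rw)))
    aw <- aw[!is.na(aw)]; rw <- rw[!is.na(rw)]
    if (length(aw) < 2 || length(rw) < 2) {
      return(tibble(metric = v, t = NA_real_, df = NA_real_, p = NA_real_,
                    d = NA_real_, mean_aw = mean(aw), mean_rw = mean(rw),
                    n_aw = length(aw), n_rw = length(rw), n_censored = n_cens))
    }
    res <- two_sample_t(aw, rw)
    tibble(metric = v, t = res$t, df = res$df, p = res$p, d = res$d,
           mean_aw = res$mean1, mean_rw = res$mean2,
           n_aw = res$n1, n_rw = res$n2, n_censored = n_cens)
  })
}

#' Run the end-to-end study analysis
#'
#' Orchestrates the full pipeline on a (synthetic or imported) cohort:
#' per-animal metrics (work segment vs baseline), group comparisons for each
#' metric, a paired within-RW test of the temperature-amplitude change, and
#' hierarchical regression ledgers for spatial-memory latency and each
#' protein outcome with the configured block order. Deterministic for fixed
#' inputs.
#'
#' @param cohort An `sw_cohort` from [simulate_cohort()], or a list with
#'   elements `epochs`, `temperature` (optional), `schedule`, `outcomes`.
#' @param step3_variant Sleep-block variant for the ledgers (see
#'   [default_blocks()]).
#' @param rem_after_shift Shift whose end anchors the latency metrics.
#' @param bin_hours Report bin width in hours.
#' @return A list of class `study_report`: `metrics`, `comparisons`,
#'   `paired_amplitude`, `ledgers` (named list of `sw_ledger`),
#'   `exclusions`.
#' @export
run_study <- function(cohort, step3_variant = "sleep_drive",
                      rem_after_shift = 2, bin_hours = 2) {
  sched <- cohort$schedule
  if (is.null(sched) || is.null(cohort$epochs)) {
    abort("Cohort must carry `epochs` and `schedule` tables.")
  }
  metrics <- purrr::map_dfr(seq_len(nrow(sched)), function(j) {
    id <- sched$animal_id[j]
    ep <- cohort$epochs[cohort$epochs$animal_id == id, , drop = FALSE]
    tt <- if (!is.null(cohort$temperature)) {
      cohort$temperature[cohort$temperature$animal_id == id, , drop = FALSE]
    } else NULL
    if (!is.null(tt) && nrow(tt) == 0) tt <- NULL
    animal_metrics(ep, tt, condition = sched$condition_label[j],
                   days_baseline = sched$days_baseline[j],
                   days_work = sched$days_work[j],
                   rem_after_shift = rem_after_shift, bin_hours = bin_hours)
  })
  comparisons <- compare_groups(metrics)
  rw <- metrics[metrics$condition_label == "RW" & !is.na(metrics$amp_change), ]
  paired_amp <- if (nrow(rw) >= 2) {
    paired_t(rw$amp_baseline, rw$amp_work)
  } else NULL
  exclusions <- metrics |>
    tidyr::pivot_longer(c("rem_latency_min", "sleep_latency_min"),
                        names_to = "metric", values_to = "value") |>
    filter(is.na(.data$value)) |>
    select("animal_id", "metric") |>
    mutate(reason = "censored latency: no qualifying run before end of recording")
  ledgers <- list()
  if (!is.null(cohort$outcomes)) {
    outs_tbl <- cohort$outcomes[, setdiff(names(cohort$outcomes), "condition"),
                                drop = FALSE]
    d <- dplyr::left_join(metrics, outs_tbl, by = "animal_id")
    mwm_blocks <- default_blocks(step3_variant, include_corticosterone = FALSE)
    prot_blocks <- default_blocks(step3_variant, include_corticosterone = TRUE)
    # corticosterone predictor: collection-time serum value if present
    if (!"corticosterone" %in% names(d) && "cort_zt12" %in% names(d)) {
      d$corticosterone <- d$cort_zt12
    }
    outs <- intersect(c("mwm_latency", "p_eif4e", "p_bmal1", "p_s6k1", "arc"),
                      names(d))
    for (o in outs) {
      blocks <- if (o == "mwm_latency") mwm_blocks else prot_blocks
      ledgers[[o]] <- tryCatch(
        suppressWarnings(hierarchical_ledger(d, o, blocks)),
        error = function(e) e
      )
    }
  }
  structure(
    list(metrics = metrics, comparisons = comparisons,
         paired_amplitude = paired_amp, ledgers = ledgers,
         exclusions = exclusions),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n")
  cat(sprintf("Animals: %d (%d censored latency values)\n",
              nrow(x$metrics), nrow(x$exclusions)))
  cat("\nGroup comparisons (RW vs AW):\n")
  print(as.data.frame(x$comparisons), row.names = FALSE, digits = 3)
  if (!is.null(x$paired_amplitude)) {
    cat("\nPaired RW amplitude change (work vs baseline):\n")
    print(as.data.frame(x$paired_amplitude), row.names = FALSE, digits = 3)
  }
  for (nm in names(x$ledgers)) {
    if (inherits(x$ledgers[[nm]], "sw_ledger")) {
      cat("\n"); print(x$ledgers[[nm]])
    }
  }
  invisible(x)
}

#' Write a study report to delimited-text files
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"), progress = FALSE)
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"), progress = FALSE)
  if (!is.null(report$paired_amplitude)) {
    readr::write_csv(report$paired_amplitude, file.path(dir, "paired_amplitude.csv"),
                     progress = FALSE)
  }
  ok <- purrr::keep(report$ledgers, inherits, "sw_ledger")
  if (length(ok) > 0) {
    readr::write_csv(purrr::map_dfr(ok, tidy), file.path(dir, "ledgers.csv"),
                     progress = FALSE)
  }
  readr::write_csv(report$exclusions, file.path(dir, "exclusions.csv"), progress = FALSE)
  invisible(dir)
}

#' Plot cumulative time-in-state or SWE trajectories
#'
#' @param trajectory Output of [time_in_state_binned()] (uses `cum_minutes`)
#'   or [swe_per_bin()] (uses `cum_swe`).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  if ("cum_minutes" %in% names(trajectory)) {
    ggplot2::ggplot(trajectory,
                    ggplot2::aes(x = .data$bin, y = .data$cum_minutes,
                                 colour = .data$state)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Bin", y = "Cumulative minutes") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(trajectory,
                    ggplot2::aes(x = .data$bin, y = .data$cum_swe)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Bin", y = "Cumulative SWE") +
      ggplot2::theme_minimal()
  }
}

#' Plot a hypnogram
#'
#' @param epochs An epoch table.
#' @param max_epochs Downsample cap for display.
#' @return A ggplot object with the state sequence over time.
#' @export
plot_hypnogram <- function(epochs, max_epochs = 20000) {
  .check_epochs(epochs)
  if (nrow(epochs) > max_epochs) {
    epochs <- epochs[seq(1, nrow(epochs), length.out = max_epochs), ]
  }
  lev <- c(W = 3, N = 2, R = 1)
  epochs$level <- lev[epochs$state]
  ggplot2::ggplot(epochs, ggplot2::aes(x = .data$epoch_index * 10 / 3600,
                                       y = .data$level)) +
    ggplot2::geom_step(linewidth = 0.2) +
    ggplot2::scale_y_continuous(breaks = c(1, 2, 3),
                                labels = c("REM", "NREM", "Wake")) +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
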