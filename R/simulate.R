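#' Effect specification for the synthetic-telemetry generator
#'
#' Collects the planted "study conditions" of the simulated shift-work
#' cohort: targets for sleep-wake architecture, temperature-rhythm
#' parameters, quiet-wake sleep-drive effects, and the linear outcome models.
#' Defaults emulate a rat 12:12 light-dark design with simulated night-shift
#' work (rest work, RW; forced activity ZT2-10) versus day-shift work
#' (active work, AW; ZT14-22): nocturnal wake fraction 72.9% in the dark
#' phase, light-phase sleep fraction 71.6%, baseline temperature-rhythm
#' amplitude about 0.64 degrees C with RW work-amplitude damping of
#' -0.40 degrees C.
#'
#' @param dark_wake_frac Target baseline wake fraction during ZT12-24.
#' @param light_sleep_frac Target baseline sleep fraction during ZT0-12.
#' @param mean_wake_bout_dark_min,mean_wake_bout_light_min Mean wake bout
#'   lengths used to set transition rates (minutes).
#' @param rem_frac_dark,rem_frac_light Target REM fractions per phase.
#' @param mean_rem_bout_min Mean REM bout length (minutes).
#' @param mesor_c Temperature MESOR (degrees C).
#' @param acrophase_zt Temperature acrophase (ZT hours).
#' @param amp_baseline_c,amp_baseline_sd_c Per-animal baseline amplitude mean
#'   and SD (degrees C).
#' @param amp_damping_rw_c,amp_damping_aw_c Mean work-period amplitude change
#'   for RW and AW animals (degrees C; negative = damping).
#' @param amp_damping_sd_c Inter-animal SD of the amplitude change.
#' @param temp_noise_sd_c Sample-to-sample temperature noise SD.
#' @param wake_temp_increment_c Temperature increment while awake.
#' @param artifact_rate Fraction of temperature samples hit by telemetry
#'   spikes (magnitude >= `artifact_mag_c`).
#' @param artifact_mag_c Minimum artifact spike magnitude (degrees C).
#' @param microsleep_p Per-epoch probability of a micro-sleep intrusion
#'   during forced-wake shifts.
#' @param qw_swe_gain_rw Multiplicative boost of quiet-wake SWA for RW
#'   animals during the work segment (sleep-drive effect).
#' @param rem_latency_shift_min Shift in mean post-shift REM latency for RW
#'   relative to AW (minutes; negative = earlier REM onset).
#' @param s_tau_rise_h,s_tau_decay_h Time constants of the Process-S-like
#'   latent sleep-pressure used to synthesise SWA (hours).
#' @param swa_gain State gains for SWA synthesis (named: `N`, `QW`, `AW`).
#' @param swa_noise_sdlog Log-normal noise SD of per-epoch SWA.
#' @param eeg_artifact_rate Fraction of epochs with injected SWA artifacts.
#' @param outcome_betas Named list of per-outcome coefficient lists (see
#'   [generate_outcomes()]).
#' @param noise_sds Named residual SDs per outcome.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(dark_wake_frac = 0.729,
                        light_sleep_frac = 0.716,
                        mean_wake_bout_dark_min = 5,
                        mean_wake_bout_light_min = 2,
                        rem_frac_dark = 0.041,
                        rem_frac_light = 0.116,
                        mean_rem_bout_min = 1,
                        mesor_c = 37.2,
                        acrophase_zt = 18,
                        amp_baseline_c = 0.64,
                        amp_baseline_sd_c = 0.11,
                        amp_damping_rw_c = -0.40,
                        amp_damping_aw_c = -0.08,
                        amp_damping_sd_c = 0.10,
                        temp_noise_sd_c = 0.20,
                        wake_temp_increment_c = 0.05,
                        artifact_rate = 0.001,
                        artifact_mag_c = 6,
                        microsleep_p = 0.02,
                        qw_swe_gain_rw = 1.5,
                        rem_latency_shift_min = -18,
                        s_tau_rise_h = 8,
                        s_tau_decay_h = 2.5,
                        swa_gain = c(N = 300, QW = 120, AW = 60),
                        swa_noise_sdlog = 0.3,
                        eeg_artifact_rate = 0.001,
                        outcome_betas = default_outcome_betas(),
                        noise_sds = default_outcome_noise()) {
  spec <- as.list(environment())
  stopifnot(
    dark_wake_frac > 0, dark_wake_frac < 1,
    light_sleep_frac > 0, light_sleep_frac < 1,
    microsleep_p >= 0, microsleep_p <= 1,
    artifact_rate >= 0, artifact_rate <= 1,
    all(unlist(noise_sds) >= 0)
  )
  structure(spec, class = "effect_spec")
}

#' Default outcome coefficient sets
#'
#' Coefficients of the linear models generating the cohort outcomes from the
#' per-animal predictors. Continuous predictors enter as cohort z-scores;
#' `condition` enters as 0 (AW) / 1 (RW). Values are plumbing for the
#' generator, chosen so that the planted structure is recoverable by the
#' hierarchical ledger at realistic sample sizes: MWM latency loads on the
#' sleep-drive block most strongly, then the rhythm block, then condition;
#' p-S6K1 is condition-dominated; p-eIF4E carries a corticosterone effect;
#' Arc is mostly noise.
#'
#' @return Named list of coefficient lists with elements `intercept`,
#'   `condition`, `z_amp_change`, `z_rem_latency`, `z_nrem_bout`, `z_qw_swe`,
#'   `z_corticosterone`.
#' @export
default_outcome_betas <- function() {
  beta <- function(intercept, condition = 0, z_amp_change = 0,
                   z_rem_latency = 0, z_nrem_bout = 0, z_qw_swe = 0,
                   z_corticosterone = 0) {
    list(intercept = intercept, condition = condition,
         z_amp_change = z_amp_change, z_rem_latency = z_rem_latency,
         z_nrem_bout = z_nrem_bout, z_qw_swe = z_qw_swe,
         z_corticosterone = z_corticosterone)
  }
  list(
    mwm_latency = beta(40, condition = 4, z_amp_change = -7,
                       z_rem_latency = 5, z_nrem_bout = -9, z_qw_swe = 10),
    p_eif4e = beta(1, condition = -0.35, z_amp_change = 0.25,
                   z_corticosterone = 0.5),
    p_bmal1 = beta(1, condition = -0.5, z_amp_change = 0.3),
    p_s6k1 = beta(1, condition = -0.9),
    arc = beta(1, condition = 0.15)
  )
}

#' @rdname default_outcome_betas
#' @export
default_outcome_noise <- function() {
  list(mwm_latency = 6, p_eif4e = 0.2, p_bmal1 = 0.2, p_s6k1 = 0.15,
       arc = 0.3)
}

# Seed derived per animal so cohort-size changes do not perturb existing
# animals; kept below 2^31 - 1.
.animal_seed <- function(seed, j, salt = 0L) {
  (abs(as.integer(seed)) + 77777L * as.integer(j) + 131L * as.integer(salt)) %% 2147483647L
}

# Three-state transition matrix (W, N, R) solved from a target stationary
# distribution and chosen mean wake / REM bout lengths. REM is entered only
# from NREM; wake exits to NREM.
.transition_matrix <- function(pi_wnr, wake_exit_p, rem_exit_p, rem_to_wake_frac = 0.8) {
  w <- wake_exit_p
  cc <- rem_to_wake_frac * rem_exit_p
  dd <- (1 - rem_to_wake_frac) * rem_exit_p
  b <- pi_wnr[3] * rem_exit_p / pi_wnr[2]
  a <- (pi_wnr[1] * w - pi_wnr[3] * cc) / pi_wnr[2]
  if (a < 0 || a + b >= 1) {
    abort("Infeasible hypnogram targets: adjust bout lengths or state fractions.")
  }
  m <- rbind(
    c(1 - w, w, 0),
    c(a, 1 - a - b, b),
    c(cc, dd, 1 - rem_exit_p)
  )
  rownames(m) <- colnames(m) <- c("W", "N", "R")
  m
}

.phase_matrices <- function(spec) {
  rem_exit <- 1 / (spec$mean_rem_bout_min * 6)
  dark_pi <- c(spec$dark_wake_frac,
               1 - spec$dark_wake_frac - spec$rem_frac_dark,
               spec$rem_frac_dark)
  light_pi <- c(1 - spec$light_sleep_frac,
                spec$light_sleep_frac - spec$rem_frac_light,
                spec$rem_frac_light)
  list(
    light = .transition_matrix(light_pi, 1 / (spec$mean_wake_bout_light_min * 6), rem_exit),
    dark = .transition_matrix(dark_pi, 1 / (spec$mean_wake_bout_dark_min * 6), rem_exit),
    light_pi = light_pi, dark_pi = dark_pi
  )
}

#' Work-shift window for a condition
#'
#' Rest work (RW, simulated night shift) forces activity at ZT2-10; active
#' work (AW, simulated day shift) at ZT14-22.
#'
#' @param condition `"RW"` or `"AW"`.
#' @return Numeric `c(start, end)` in ZT hours.
#' @export
work_window_zt <- function(condition) {
  switch(match.arg(condition, c("RW", "AW")),
         RW = c(2, 10), AW = c(14, 22))
}

#' Generate a synthetic hypnogram
#'
#' Simulates an epoch-scored vigilance-state sequence (10-s epochs) from a
#' semi-Markov chain with phase-specific transition matrices solved from the
#' target state fractions and bout lengths in the [effect_spec()]. On work
#' days the state is forced to wake inside the condition's shift window,
#' apart from sporadic micro-sleep epochs (probability `microsleep_p`); REM
#' sleep is entered only from NREM sleep.
#'
#' @param condition `"RW"` or `"AW"`.
#' @param days_baseline,days_work Numbers of baseline and work days.
#' @param spec An [effect_spec()].
#' @param seed Integer seed; the same (spec, seed) always regenerates the
#'   identical series.
#' @param animal_id Identifier for the epoch table.
#' @return An epoch table with `schedule_tag` in BASELINE/WORK/OFF_WORK.
#' @export
generate_hypnogram <- function(condition = "RW", days_baseline = 4,
                               days_work = 3, spec = effect_spec(),
                               seed = 1, animal_id = "a1") {
  pm <- .phase_matrices(spec)
  cum_light <- t(apply(pm$light, 1, cumsum))
  cum_dark <- t(apply(pm$dark, 1, cumsum))
  n_days <- days_baseline + days_work
  n <- n_days * 8640L
  zt <- ((seq_len(n) - 1) * 10 / 3600) %% 24
  day <- (seq_len(n) - 1) %/% 8640L + 1L
  is_work_day <- day > days_baseline
  ww <- work_window_zt(condition)
  forced <- is_work_day & zt >= ww[1] & zt < ww[2]
  dark <- zt >= 12
  states <- integer(n)
  withr::with_seed(.animal_seed(seed, 0L, salt = 1L), {
    u <- stats::runif(n)
    um <- stats::runif(n)
    pi0 <- if (dark[1]) pm$dark_pi else pm$light_pi
    s <- findInterval(u[1], cumsum(pi0)) + 1L
    states[1] <- if (forced[1]) (if (um[1] < spec$microsleep_p) 2L else 1L) else s
    s <- states[1]
    for (i in 2:n) {
      if (forced[i]) {
        s <- if (um[i] < spec$microsleep_p) 2L else 1L
      } else {
        row <- if (dark[i]) cum_dark[s, ] else cum_light[s, ]
        ui <- u[i]
        s <- if (ui <= row[1]) 1L else if (ui <= row[2]) 2L else 3L
      }
      states[i] <- s
    }
  })
  out <- epoch_table(c("W", "N", "R")[states], t0_zt = 0, animal_id = animal_id)
  out$schedule_tag <- dplyr::case_when(
    !is_work_day ~ "BASELINE",
    forced ~ "WORK",
    TRUE ~ "OFF_WORK"
  )
  out
}

#' Generate per-epoch SWA and EMG features for a hypnogram
#'
#' Synthesises epoch features from a Process-S-like latent sleep pressure:
#' S rises exponentially towards 1 during wake and decays during sleep.
#' Per-epoch SWA is a state gain (NREM > quiet wake > active wake) times S
#' with log-normal noise; wake EMG peak-to-peak amplitude is drawn from a
#' two-component log-normal mixture in which about one third of wake epochs
#' form a low-amplitude (quiet) component. For RW animals the quiet-wake SWA
#' is multiplied by `qw_swe_gain_rw` during the work segment (epochs not
#' tagged BASELINE). Rare SWA artifact spikes are injected at
#' `eeg_artifact_rate`.
#'
#' @param epochs An epoch table (typically from [generate_hypnogram()]).
#' @param condition `"RW"` or `"AW"`.
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return The epoch table with `swa` and `emg_ptp` filled in.
#' @export
generate_epoch_features <- function(epochs, condition = "RW",
                                    spec = effect_spec(), seed = 1) {
  .check_epochs(epochs)
  n <- nrow(epochs)
  st <- epochs$state
  dt <- 10 / 3600
  a_rise <- exp(-dt / spec$s_tau_rise_h)
  a_decay <- exp(-dt / spec$s_tau_decay_h)
  s_hi <- 1; s_lo <- 0.15
  S <- numeric(n)
  s_cur <- 0.5
  for (i in seq_len(n)) {
    s_cur <- if (st[i] == "W") s_hi + (s_cur - s_hi) * a_rise
             else s_lo + (s_cur - s_lo) * a_decay
    S[i] <- s_cur
  }
  withr::with_seed(.animal_seed(seed, 0L, salt = 2L), {
    wake <- st == "W"
    quiet_latent <- wake & stats::runif(n) < 1 / 3
    emg <- numeric(n)
    emg[quiet_latent] <- stats::rlnorm(sum(quiet_latent), log(30), 0.30)
    act <- wake & !quiet_latent
    emg[act] <- stats::rlnorm(sum(act), log(120), 0.40)
    emg[st == "N"] <- stats::rlnorm(sum(st == "N"), log(15), 0.30)
    emg[st == "R"] <- stats::rlnorm(sum(st == "R"), log(8), 0.30)
    gain <- ifelse(st == "N", spec$swa_gain[["N"]],
                   ifelse(quiet_latent, spec$swa_gain[["QW"]], spec$swa_gain[["AW"]]))
    boost <- quiet_latent & condition == "RW" & epochs$schedule_tag != "BASELINE"
    gain[boost] <- gain[boost] * spec$qw_swe_gain_rw
    swa <- gain * S * stats::rlnorm(n, 0, spec$swa_noise_sdlog)
    spikes <- stats::runif(n) < spec$eeg_artifact_rate
    swa[spikes] <- swa[spikes] + 50 * max(spec$swa_gain)
  })
  epochs$swa <- swa
  epochs$emg_ptp <- emg
  epochs
}

#' Generate a synthetic body-temperature series
#'
#' 10-s samples over the study: MESOR plus a 24-h cosine whose amplitude is
#' the animal's baseline amplitude on baseline days and is changed by the
#' animal's damping on work days, plus an optional activity increment while
#' awake, Gaussian noise, and sporadic telemetry spikes of magnitude at
#' least `artifact_mag_c`.
#'
#' @param condition `"RW"` or `"AW"`.
#' @param days_baseline,days_work Study layout in days.
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @param animal_id Identifier.
#' @param amp_baseline Baseline amplitude for this animal (degrees C);
#'   drawn from the spec when `NULL`.
#' @param amp_delta Work-period amplitude change for this animal; drawn from
#'   the spec (condition-specific mean) when `NULL`.
#' @param wake Optional logical vector on the same 10-s grid; when supplied,
#'   `wake_temp_increment_c` is added while awake.
#' @param noise_sd_c Override the sample noise SD (e.g. 0 for round-trip
#'   tests).
#' @param artifact_rate Override the spike rate.
#' @return A temperature table; the planted `amp_baseline` and `amp_delta`
#'   are attached as attributes `planted`.
#' @export
generate_temperature <- function(condition = "RW", days_baseline = 4,
                                 days_work = 3, spec = effect_spec(),
                                 seed = 1, animal_id = "a1",
                                 amp_baseline = NULL, amp_delta = NULL,
                                 wake = NULL, noise_sd_c = NULL,
                                 artifact_rate = NULL) {
  noise_sd_c <- noise_sd_c %||% spec$temp_noise_sd_c
  artifact_rate <- artifact_rate %||% spec$artifact_rate
  n <- (days_baseline + days_work) * 8640L
  t_hours <- (seq_len(n) - 1) * 10 / 3600
  zt <- t_hours %% 24
  work_day <- t_hours >= days_baseline * 24
  withr::with_seed(.animal_seed(seed, 0L, salt = 3L), {
    amp_baseline <- amp_baseline %||%
      max(0.05, stats::rnorm(1, spec$amp_baseline_c, spec$amp_baseline_sd_c))
    mean_delta <- if (condition == "RW") spec$amp_damping_rw_c else spec$amp_damping_aw_c
    amp_delta <- amp_delta %||% stats::rnorm(1, mean_delta, spec$amp_damping_sd_c)
    amp <- ifelse(work_day, pmax(0.02, amp_baseline + amp_delta), amp_baseline)
    temp <- spec$mesor_c + amp * cos(2 * pi * (zt - spec$acrophase_zt) / 24)
    if (!is.null(wake)) {
      if (length(wake) != n) abort("`wake` must align with the 10-s sample grid.")
      temp <- temp + spec$wake_temp_increment_c * wake
    }
    if (noise_sd_c > 0) temp <- temp + stats::rnorm(n, 0, noise_sd_c)
    spikes <- which(stats::runif(n) < artifact_rate)
    if (length(spikes) > 0) {
      temp[spikes] <- temp[spikes] +
        sample(c(-1, 1), length(spikes), replace = TRUE) *
          (spec$artifact_mag_c + stats::rexp(length(spikes), 1))
    }
  })
  out <- temperature_table(temp, t_hours = t_hours, animal_id = animal_id, t0_zt = 0)
  attr(out, "planted") <- list(amp_baseline = amp_baseline, amp_delta = amp_delta,
                               artifact_idx = spikes)
  out
}

#' Generate per-animal predictor metrics directly
#'
#' Light-weight generator of the per-animal predictor table (the summary
#' metrics the telemetry pipeline would produce), drawn directly from the
#' effect specification. Used for fast power and null simulations of the
#' regression ledger without epoch-level synthesis.
#'
#' @param n_rw,n_aw Animals per condition.
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per animal: `animal_id`, `condition` (1 =
#'   RW, 0 = AW), `condition_label`, `amp_change`, `rem_latency_min`,
#'   `nrem_bout_min`, `qw_swe`, `nrem_swe`, `cum_nrem_min`, `cum_rem_min`,
#'   `corticosterone`.
#' @export
simulate_predictors <- function(n_rw = 17, n_aw = 13, spec = effect_spec(),
                                seed = 1) {
  n <- n_rw + n_aw
  cond <- c(rep(1, n_rw), rep(0, n_aw))
  withr::with_seed(.animal_seed(seed, 0L, salt = 4L), {
    amp_change <- ifelse(cond == 1, spec$amp_damping_rw_c, spec$amp_damping_aw_c) +
      stats::rnorm(n, 0, spec$amp_damping_sd_c)
    rem_lat <- pmax(2, stats::rnorm(n, 55 + spec$rem_latency_shift_min * cond, 15))
    bout <- pmax(0.5, stats::rnorm(n, 1.6 - 0.25 * cond, 0.30))
    qw_swe <- stats::rlnorm(n, log(4000), 0.25) *
      ifelse(cond == 1, spec$qw_swe_gain_rw, 1)
    nrem_swe <- stats::rlnorm(n, log(60000), 0.20)
    sleep_total <- stats::rnorm(n, ifelse(cond == 1, 606, 623), 37)
    rem_share <- pmin(0.25, pmax(0.08, stats::rnorm(n, 0.15, 0.03)))
    cort <- pmax(10, stats::rnorm(n, 150 - 40 * cond, 35))
  })
  tibble(
    animal_id = sprintf("%s%02d", ifelse(cond == 1, "rw", "aw"),
                        c(seq_len(n_rw), seq_len(n_aw))),
    condition = cond,
    condition_label = ifelse(cond == 1, "RW", "AW"),
    amp_change = amp_change,
    rem_latency_min = rem_lat,
    nrem_bout_min = bout,
    qw_swe = qw_swe,
    nrem_swe = nrem_swe,
    cum_nrem_min = sleep_total * (1 - rem_share),
    cum_rem_min = sleep_total * rem_share,
    corticosterone = cort
  )
}

#' Generate cohort outcomes from predictors
#'
#' Applies the linear outcome models of the effect specification to a
#' per-animal predictor table: each outcome is `intercept + b_cond*condition
#' + sum(b_j * z_j) + noise`, where `z_j` are cohort z-scores of the
#' continuous predictors. Serum corticosterone carries a time-of-day
#' structure (higher at ZT12 than ZT0) via `cort_zt`.
#'
#' @param predictors Tibble from [simulate_predictors()] or the analysis
#'   pipeline (needs `condition`, `amp_change`, `rem_latency_min`,
#'   `nrem_bout_min`, `qw_swe`, `corticosterone`).
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return Tibble: `animal_id`, `condition`, outcome columns `mwm_latency`,
#'   `p_eif4e`, `p_bmal1`, `p_s6k1`, `arc`, `cort_zt0`, `cort_zt12`.
#' @export
generate_outcomes <- function(predictors, spec = effect_spec(), seed = 1) {
  need <- c("condition", "amp_change", "rem_latency_min", "nrem_bout_min",
            "qw_swe", "corticosterone")
  miss <- setdiff(need, names(predictors))
  if (length(miss) > 0) {
    abort(paste0("Predictor table missing column(s): ", paste(miss, collapse = ", ")))
  }
  z <- function(x) {
    s <- stats::sd(x)
    if (length(x) > 1 && !is.na(s) && s > 0) (x - mean(x)) / s else x * 0
  }
  zs <- list(
    z_amp_change = z(predictors$amp_change),
    z_rem_latency = z(predictors$rem_latency_min),
    z_nrem_bout = z(predictors$nrem_bout_min),
    z_qw_swe = z(predictors$qw_swe),
    z_corticosterone = z(predictors$corticosterone)
  )
  n <- nrow(predictors)
  out <- tibble(animal_id = predictors$animal_id,
                condition = predictors$condition)
  withr::with_seed(.animal_seed(seed, 0L, salt = 5L), {
    for (nm in names(spec$outcome_betas)) {
      b <- spec$outcome_betas[[nm]]
      mu <- b$intercept + b$condition * predictors$condition
      for (zn in names(zs)) mu <- mu + (b[[zn]] %||% 0) * zs[[zn]]
      out[[nm]] <- mu + stats::rnorm(n, 0, spec$noise_sds[[nm]])
    }
    out$cort_zt0 <- pmax(5, stats::rnorm(n, 80, 25))
    out$cort_zt12 <- pmax(5, predictors$corticosterone + stats::rnorm(n, 0, 10))
  })
  out
}

#' Simulate a complete shift-work cohort at epoch level
#'
#' Generates, per animal, a hypnogram over baseline plus work days, aligned
#' epoch features (SWA, EMG) and a body-temperature series, together with a
#' schedule table and outcome table. Randomness is streamed per animal from
#' `(seed, animal index)`, so enlarging the cohort leaves existing animals
#' unchanged; the same call is fully deterministic.
#'
#' @param n_rw,n_aw Animals per condition.
#' @param days_baseline,days_work Study layout (defaults mirror a 4-day
#'   baseline and 3-day work schedule).
#' @param spec An [effect_spec()].
#' @param seed Integer master seed.
#' @param features Also synthesise SWA/EMG features (slower; default TRUE).
#' @param temperature Also synthesise temperature series (default TRUE).
#' @return A list of class `sw_cohort`: `epochs`, `temperature`, `schedule`,
#'   `planted` (per-animal planted parameters), `outcomes`, plus the call
#'   parameters in `$meta`.
#' @export
simulate_cohort <- function(n_rw = 17, n_aw = 13, days_baseline = 4,
                            days_work = 3, spec = effect_spec(), seed = 1,
                            features = TRUE, temperature = TRUE) {
  ids <- c(sprintf("rw%02d", seq_len(n_rw)), sprintf("aw%02d", seq_len(n_aw)))
  conds <- c(rep("RW", n_rw), rep("AW", n_aw))
  epochs <- vector("list", length(ids))
  temps <- vector("list", length(ids))
  planted <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    sj <- .animal_seed(seed, j)
    ep <- generate_hypnogram(conds[j], days_baseline, days_work, spec,
                             seed = sj, animal_id = ids[j])
    if (features) ep <- generate_epoch_features(ep, conds[j], spec, seed = sj)
    epochs[[j]] <- ep
    if (temperature) {
      tt <- generate_temperature(conds[j], days_baseline, days_work, spec,
                                 seed = sj, animal_id = ids[j],
                                 wake = ep$state == "W")
      planted[[j]] <- tibble(
        animal_id = ids[j], condition_label = conds[j],
        amp_baseline = attr(tt, "planted")$amp_baseline,
        amp_delta = attr(tt, "planted")$amp_delta
      )
      attr(tt, "planted") <- NULL
      temps[[j]] <- tt
    }
  }
  schedule <- tibble(
    animal_id = ids, condition_label = conds,
    condition = as.numeric(conds == "RW"),
    work_start_zt = vapply(conds, function(x) work_window_zt(x)[1], 1),
    work_end_zt = vapply(conds, function(x) work_window_zt(x)[2], 1),
    days_baseline = days_baseline, days_work = days_work
  )
  pred <- simulate_predictors(n_rw, n_aw, spec, seed = seed)
  if (temperature) {
    pl <- bind_rows(planted)
    pred$amp_change <- pl$amp_delta[match(pred$animal_id, pl$animal_id)]
  }
  outcomes <- generate_outcomes(pred, spec, seed = seed)
  structure(
    list(
      epochs = bind_rows(epochs),
      temperature = if (temperature) bind_rows(temps) else NULL,
      schedule = schedule,
      planted = if (temperature) bind_rows(planted) else NULL,
      outcomes = outcomes,
      meta = list(n_rw = n_rw, n_aw = n_aw, days_baseline = days_baseline,
                  days_work = days_work, seed = seed)
    ),
    class = "sw_cohort"
  )
}

#' @export
print.sw_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic shift-work cohort: %d RW + %d AW animals, %d baseline + %d work days (seed %d)\n",
    x$meta$n_rw, x$meta$n_aw, x$meta$days_baseline, x$meta$days_work, x$meta$seed
  ))
  cat(sprintf("  epochs: %d rows; temperature: %s rows\n",
              nrow(x$epochs),
              if (is.null(x$temperature)) "0" else format(nrow(x$temperature))))
  invisible(x)
}

#' Write a cohort to delimited-text files
#'
#' Writes `epochs.tsv`, `temperature.csv`, `schedule.csv`, `outcomes.csv`
#' and a `manifest.csv` recording the generation parameters.
#'
#' @param cohort An `sw_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_epoch_table(cohort$epochs, file.path(dir, "epochs.tsv"))
  if (!is.null(cohort$temperature)) {
    write_temperature_table(cohort$temperature, file.path(dir, "temperature.csv"))
  }
  readr::write_csv(cohort$schedule, file.path(dir, "schedule.csv"), progress = FALSE)
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"), progress = FALSE)
  manifest <- tibble(key = names(cohort$meta),
                     value = unlist(lapply(cohort$meta, as.character)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(dir)
}
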