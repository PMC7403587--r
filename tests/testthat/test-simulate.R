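test_that("hypnogram generation is deterministic and respects forced-wake windows", {
  a <- generate_hypnogram("RW", 1, 1, seed = 5)
  b <- generate_hypnogram("RW", 1, 1, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$state, generate_hypnogram("RW", 1, 1, seed = 6)$state))

  # microsleep_p = 0: no sleep inside the shift window
  spec0 <- effect_spec(microsleep_p = 0)
  ep <- generate_hypnogram("RW", 0, 2, spec = spec0, seed = 7)
  in_shift <- ep$schedule_tag == "WORK"
  expect_true(all(ep$state[in_shift] == "W"))
  expect_true(all(ep$zt_hours[in_shift] >= 2 & ep$zt_hours[in_shift] < 10))

  # AW shift window sits in the dark phase
  ep_aw <- generate_hypnogram("AW", 0, 1, spec = spec0, seed = 7)
  w_aw <- ep_aw$schedule_tag == "WORK"
  expect_true(all(ep_aw$zt_hours[w_aw] >= 14 & ep_aw$zt_hours[w_aw] < 22))

  # schedule tags partition the recording
  ep2 <- generate_hypnogram("RW", 1, 1, seed = 8)
  expect_true(all(ep2$schedule_tag[1:8640] == "BASELINE"))
  expect_true(all(ep2$schedule_tag[8641:17280] %in% c("WORK", "OFF_WORK")))
})

test_that("REM sleep is only entered from NREM sleep", {
  ep <- generate_hypnogram("RW", 2, 2, seed = 9)
  prev <- ep$state[-nrow(ep)]
  cur <- ep$state[-1]
  expect_false(any(cur == "R" & prev == "W"))
})

test_that("baseline architecture hits the planted nocturnal targets", {
  ep <- generate_hypnogram("RW", 10, 0, seed = 10)
  dark <- ep$zt_hours >= 12
  expect_equal(mean(ep$state[dark] == "W"), 0.729, tolerance = 0.05)
  expect_equal(mean(ep$state[!dark] != "W"), 0.716, tolerance = 0.05)
  # binned summary sees the same dark-phase wake fraction
  tis <- time_in_state_binned(ep, bin_hours = 2)
  dark_bins <- tis$zt_start >= 12
  frac <- sum(tis$minutes[dark_bins & tis$state == "W"]) /
    sum(tis$minutes[dark_bins])
  expect_equal(frac, 0.729, tolerance = 0.05 * 0.729 / 0.729)
})

test_that("epoch features carry Process-S structure and a quiet-wake EMG component", {
  spec <- effect_spec()
  ep <- generate_hypnogram("RW", 2, 0, seed = 11)
  ft <- generate_epoch_features(ep, "RW", spec, seed = 11)
  expect_true(all(ft$swa > 0))
  expect_true(all(ft$emg_ptp > 0))

  # long uninterrupted NREM: SWA trend decreases as S dissipates
  long_n <- epoch_table(c(rep("W", 2000), rep("N", 1500)))
  ftn <- generate_epoch_features(long_n, "AW", spec, seed = 12)
  swa_n <- ftn$swa[long_n$state == "N"]
  first_third <- mean(swa_n[1:500]); last_third <- mean(swa_n[1001:1500])
  expect_gt(first_third, last_third)

  # about a third of wake epochs form the low-EMG component
  qw <- classify_quiet_wake(ft)
  frac <- sum(qw$quiet_wake) / sum(ft$state == "W")
  expect_gt(frac, 0.25); expect_lt(frac, 0.45)

  # NREM SWA exceeds wake SWA on average
  expect_gt(mean(ft$swa[ft$state == "N"]), mean(ft$swa[ft$state == "W"]))
})

test_that("a unit quiet-wake gain leaves RW and AW quiet-wake SWA identical in law", {
  spec1 <- effect_spec(qw_swe_gain_rw = 1)
  rejections <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    ep <- generate_hypnogram("RW", 0, 1, spec = spec1, seed = 100 + s)
    rw <- generate_epoch_features(ep, "RW", spec1, seed = 100 + s)
    aw <- generate_epoch_features(ep, "AW", spec1, seed = 200 + s)
    q_rw <- classify_quiet_wake(rw); q_aw <- classify_quiet_wake(aw)
    ks <- suppressWarnings(stats::ks.test(q_rw$swa[q_rw$quiet_wake],
                                          q_aw$swa[q_aw$quiet_wake]))
    if (ks$p.value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections / n_seeds, 0.10)
})

test_that("the planted quiet-wake SWE gain separates the groups", {
  # fixed-seed epoch-level check of the group contrast in cumulative QW SWE
  spec <- effect_spec()  # gain 1.5
  swe_tot <- function(cond, s) {
    ep <- generate_hypnogram(cond, 0, 1, spec = spec, seed = s)
    ft <- generate_epoch_features(ep, cond, spec, seed = s)
    qw <- classify_quiet_wake(ft)
    max(swe_per_bin(qw, "QW")$cum_swe)
  }
  rw <- vapply(1:6, function(s) swe_tot("RW", s), 1)
  aw <- vapply(1:6, function(s) swe_tot("AW", 50 + s), 1)
  res <- two_sample_t(aw, rw)
  expect_gt(res$t, 0)
  expect_lt(res$p, 0.05)
})

test_that("temperature generation is deterministic and round-trips the planted amplitude", {
  t1 <- generate_temperature("RW", 2, 1, seed = 13)
  t2 <- generate_temperature("RW", 2, 1, seed = 13)
  expect_identical(t1$temp_c, t2$temp_c)

  tt <- generate_temperature("RW", 3, 3, seed = 14, noise_sd_c = 0,
                             artifact_rate = 0, amp_baseline = 0.6,
                             amp_delta = -0.4)
  fb <- cosinor_fit(tt, span_h = 72, t_start = 0)
  fw <- cosinor_fit(tt, span_h = 72, t_start = 72)
  expect_equal(fb$amplitude, 0.6, tolerance = 1e-6)
  expect_equal(fw$amplitude, 0.2, tolerance = 1e-6)
  expect_equal(amplitude_change(fb, fw)$delta, -0.4, tolerance = 1e-6)
})

test_that("injected temperature spikes are caught by the artifact filter", {
  hits <- misses <- 0
  for (s in 1:5) {
    tt <- generate_temperature("RW", 2, 1, seed = 20 + s)
    inj <- attr(tt, "planted")$artifact_idx
    fl <- remove_temp_artifacts(tt)
    hits <- hits + sum(fl$artifact[inj])
    misses <- misses + sum(!fl$artifact[inj])
  }
  expect_gte(hits / (hits + misses), 0.95)
})

test_that("outcome generation is deterministic and respects null betas", {
  pred <- simulate_predictors(10, 10, seed = 15)
  o1 <- generate_outcomes(pred, seed = 15)
  o2 <- generate_outcomes(pred, seed = 15)
  expect_identical(o1, o2)
  # corticosterone time-of-day structure: higher at ZT12
  expect_gt(mean(o1$cort_zt12), mean(o1$cort_zt0))

  # all-zero betas: no block beyond step 1 adds adjusted R2 in expectation
  spec0 <- effect_spec()
  spec0$outcome_betas <- lapply(spec0$outcome_betas, function(b) {
    b[setdiff(names(b), "intercept")] <- 0
    b
  })
  withr::with_seed(44, {
    deltas <- replicate(150, {
      s <- sample.int(1e6, 1)
      p <- simulate_predictors(10, 10, spec0, seed = s)
      o <- generate_outcomes(p, spec0, seed = s)
      d <- dplyr::left_join(p, dplyr::select(o, animal_id, mwm_latency),
                            by = "animal_id")
      lg <- suppressWarnings(hierarchical_ledger(d, "mwm_latency"))
      lg$steps$delta_adj_r2[-1]
    })
    expect_lt(mean(deltas), 0.01)
  })
})

test_that("cohort simulation is reproducible and animal streams are stable under cohort growth", {
  c1 <- simulate_cohort(2, 2, days_baseline = 1, days_work = 1, seed = 16,
                        features = FALSE, temperature = FALSE)
  c2 <- simulate_cohort(2, 2, days_baseline = 1, days_work = 1, seed = 16,
                        features = FALSE, temperature = FALSE)
  expect_identical(c1$epochs, c2$epochs)
  # adding animals must not perturb existing ones
  c3 <- simulate_cohort(3, 2, days_baseline = 1, days_work = 1, seed = 16,
                        features = FALSE, temperature = FALSE)
  for (id in c("rw01", "rw02")) {
    expect_identical(c1$epochs$state[c1$epochs$animal_id == id],
                     c3$epochs$state[c3$epochs$animal_id == id])
  }
})

test_that("generated tables round-trip through the text interchange formats", {
  coh <- simulate_cohort(1, 1, days_baseline = 1, days_work = 1, seed = 17)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ep <- read_epoch_table(file.path(dir, "epochs.tsv"))
  expect_equal(nrow(ep), nrow(coh$epochs))
  expect_equal(ep$state, coh$epochs$state)
  expect_equal(ep$swa, coh$epochs$swa, tolerance = 1e-9)
  tt <- read_temperature_table(file.path(dir, "temperature.csv"))
  expect_equal(tt$temp_c, coh$temperature$temp_c, tolerance = 1e-9)
  # writing twice gives byte-identical files
  dir2 <- withr::local_tempdir()
  write_cohort(coh, dir2)
  expect_identical(readLines(file.path(dir, "epochs.tsv")),
                   readLines(file.path(dir2, "epochs.tsv")))
})
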