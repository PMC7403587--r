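test_that("moving-window artifact filter flags spikes and spares clean data", {
  # constant series: nothing flagged
  tt <- temperature_table(rep(37, 500))
  expect_false(any(remove_temp_artifacts(tt)$artifact))

  # one 42-degree sample in a tight window: flagged by both rules
  withr::with_seed(9, {
    x <- stats::rnorm(100, 37, 0.1)
    x[57] <- 42
    tt2 <- temperature_table(x)
    fl <- remove_temp_artifacts(tt2)
    expect_true(fl$artifact[57])
    expect_equal(sum(fl$artifact), 1)
  })

  # slow physiological cosine with no spikes: >= 99% retained
  withr::with_seed(10, {
    h <- seq(0, 96, by = 10 / 3600)
    x <- 37 + 0.6 * cos(2 * pi * (h - 18) / 24) + stats::rnorm(length(h), 0, 0.1)
    keep <- 1 - mean(remove_temp_artifacts(temperature_table(x, t_hours = h))$artifact)
    expect_gte(keep, 0.99)
  })

  # short series falls back to whole-series stats with a warning
  expect_warning(remove_temp_artifacts(temperature_table(rep(37, 10))), "window")
})

test_that("block filter flags no more than the same rule applied per window", {
  withr::with_seed(29, {
    x <- 37 + stats::rnorm(1000, 0, 0.2)
    x[c(100, 600)] <- c(45, 30)
    fl <- remove_temp_artifacts(temperature_table(x))$artifact
    # bound check: every flagged point genuinely violates its block rule
    blk <- (seq_along(x) - 1) %/% 100
    viol <- vapply(seq_along(x), function(i) {
      xs <- x[blk == blk[i]]
      abs(x[i] - mean(xs)) > 2 | abs(x[i] - mean(xs)) > 5 * sd(xs)
    }, logical(1))
    expect_true(all(fl == viol))
  })
})

test_that("baseline normalization sets the baseline mean to zero and is idempotent", {
  tt <- temperature_table(rep(37.5, 200))
  norm <- normalize_baseline_temp(tt, baseline_hours = 96)
  expect_equal(norm$temp_c, rep(0, 200))
  expect_equal(normalize_baseline_temp(norm, 96)$temp_c, norm$temp_c)

  # cosine with mesor 37.2 over whole-cycle baseline -> normalized mesor 0
  h <- seq(0, 96 - 1e-9, by = 10 / 3600)
  tt2 <- temperature_table(37.2 + 0.6 * cos(2 * pi * h / 24), t_hours = h)
  norm2 <- normalize_baseline_temp(tt2, 96)
  fit <- cosinor_fit(bin_temperature(norm2))
  expect_equal(fit$mesor, 0, tolerance = 1e-6)

  empty <- temperature_table(c(NA_real_, NA_real_), t_hours = c(0, 1))
  expect_error(normalize_baseline_temp(empty, 96), "empty")
})

test_that("5-min binning averages non-artifact samples and marks empty bins missing", {
  tt <- temperature_table(rep(37, 30))
  b <- bin_temperature(tt)
  expect_equal(nrow(b), 1)
  expect_equal(b$temp_c, 37)

  # all-artifact bin -> missing
  tt2 <- temperature_table(rep(37, 60))
  tt2$artifact[31:60] <- TRUE
  b2 <- bin_temperature(tt2)
  expect_true(is.na(b2$temp_c[2]))
  expect_equal(b2$temp_c[1], 37)

  # linear ramp: bin mean equals midpoint mean
  ramp <- seq(0, 59) * 0.01
  b3 <- bin_temperature(temperature_table(36 + ramp))
  expect_equal(b3$temp_c, c(36 + mean(ramp[1:30]), 36 + mean(ramp[31:60])))
})

test_that("cosinor fit recovers a noiseless cosine exactly", {
  h <- seq(0, 71.9, by = 1 / 12)
  y <- 0 + 1.0 * cos(2 * pi * (h - 18) / 24)
  fit <- cosinor_fit(temperature_table(y, t_hours = h))
  expect_equal(fit$amplitude, 1.0, tolerance = 1e-6)
  expect_equal(fit$mesor, 0, tolerance = 1e-6)
  expect_equal(fit$acrophase_zt, 18.0, tolerance = 1e-6)

  # degenerate constant series
  fit2 <- cosinor_fit(temperature_table(rep(36.8, 8640)))
  expect_equal(fit2$amplitude, 0, tolerance = 1e-9)
  expect_equal(fit2$mesor, 36.8, tolerance = 1e-9)

  expect_error(cosinor_fit(temperature_table(rep(37, 100)), span_h = 12), "period")
})

test_that("cosinor amplitude is invariant to MESOR and time-origin shifts", {
  withr::with_seed(14, {
    for (i in 1:20) {
      a <- runif(1, 0.1, 1)
      phi <- runif(1, 0, 24)
      shift <- runif(1, 0, 24)
      h <- seq(0, 72, by = 1 / 12)
      y <- 37 + a * cos(2 * pi * (h - phi) / 24) + rnorm(length(h), 0, 0.05)
      f1 <- cosinor_fit(temperature_table(y, t_hours = h))
      f2 <- cosinor_fit(temperature_table(y + 5, t_hours = h))      # MESOR shift
      f3 <- cosinor_fit(temperature_table(y, t_hours = h, t0_zt = shift))
      expect_gte(f1$amplitude, 0)
      expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-9)
      expect_equal(f2$mesor - f1$mesor, 5, tolerance = 1e-9)
      expect_equal(f1$amplitude, f3$amplitude, tolerance = 1e-9)
      expect_equal((f3$acrophase_zt - f1$acrophase_zt) %% 24, shift %% 24,
                   tolerance = 1e-6)
    }
  })
})

test_that("linearized cosinor equals the acrophase-grid-search oracle", {
  withr::with_seed(15, {
    for (i in 1:5) {
      h <- seq(0, 72, by = 5 / 60)
      a <- runif(1, 0.2, 0.9)
      phi <- runif(1, 0, 24)
      y <- 37 + a * cos(2 * pi * (h - phi) / 24) + rnorm(length(h), 0, 0.15)
      fit <- cosinor_fit(temperature_table(y, t_hours = h))
      oracle <- oracle_cosinor_grid(h, y, step = 0.01)
      expect_equal(fit$amplitude, oracle$amplitude, tolerance = 1e-3)
      expect_equal(fit$mesor, oracle$mesor, tolerance = 1e-3)
      expect_lt(min(abs(fit$acrophase_zt - oracle$acrophase),
                    24 - abs(fit$acrophase_zt - oracle$acrophase)), 0.011)
      expect_lte(fit$rss, oracle$rss + 1e-6)
    }
  })
})

test_that("noisy amplitude estimates stay within the Monte-Carlo envelope of the truth", {
  # planted baseline-like amplitude 0.64 with 0.2-degree noise on 5-min bins
  withr::with_seed(16, {
    h <- seq(0, 72, by = 5 / 60)
    reps <- replicate(300, {
      y <- 37 + 0.64 * cos(2 * pi * (h - 18) / 24) + rnorm(length(h), 0, 0.2)
      cosinor_fit(temperature_table(y, t_hours = h))$amplitude
    })
    ci <- quantile(reps, c(0.025, 0.975))
    expect_gt(0.64, ci[1]); expect_lt(0.64, ci[2])
    # one more fit must fall inside the Monte-Carlo envelope
    y <- 37 + 0.64 * cos(2 * pi * (h - 18) / 24) + rnorm(length(h), 0, 0.2)
    est <- cosinor_fit(temperature_table(y, t_hours = h))$amplitude
    expect_gte(est, ci[1]); expect_lte(est, ci[2])
  })
})

test_that("amplitude change is the work-minus-baseline subtraction", {
  h <- seq(0, 72, by = 5 / 60)
  mk <- function(a) cosinor_fit(temperature_table(
    37 + a * cos(2 * pi * (h - 18) / 24), t_hours = h))
  expect_equal(amplitude_change(mk(0.5), mk(0.5))$delta, 0, tolerance = 1e-9)
  ch <- amplitude_change(mk(0.63), mk(0.23))
  expect_equal(ch$delta, -0.40, tolerance = 1e-6)
  f24 <- cosinor_fit(temperature_table(
    37 + 0.5 * cos(2 * pi * h / 24), t_hours = h), period_h = 12)
  expect_error(amplitude_change(mk(0.5), f24), "period")
})
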