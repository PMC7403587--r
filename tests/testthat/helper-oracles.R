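# Independent oracles and fixture builders shared across tests.

# Brute-force run-length oracle for bout detection: walks the sequence
# epoch by epoch, no rle().
oracle_bouts <- function(states, target, min_run) {
  out <- list()
  i <- 1
  n <- length(states)
  while (i <= n) {
    if (states[i] == target) {
      j <- i
      while (j < n && states[j + 1] == target) j <- j + 1
      len <- j - i + 1
      if (len >= min_run) out[[length(out) + 1]] <- c(start = i - 1, len = len)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    data.frame(start = integer(0), len = integer(0))
  } else {
    as.data.frame(do.call(rbind, out))
  }
}

# Grid-search cosinor oracle: for each candidate acrophase on a fine grid,
# solve the 2-parameter (MESOR, amplitude) least squares in closed form and
# keep the best. Independent of the linearized cos/sin implementation.
oracle_cosinor_grid <- function(t_hours, y, period_h = 24, step = 0.01) {
  phis <- seq(0, period_h - step, by = step)
  w <- 2 * pi / period_h
  best <- list(rss = Inf)
  for (phi in phis) {
    x <- cos(w * (t_hours - phi))
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    a <- sum((x - mean(x)) * (y - mean(y))) / sxx
    m <- mean(y) - a * mean(x)
    rss <- sum((y - m - a * x)^2)
    if (a >= 0 && rss < best$rss) {
      best <- list(mesor = m, amplitude = a, acrophase = phi, rss = rss)
    }
  }
  best
}

# Random hypnogram state vector (not via the package generator).
random_states <- function(n, p = c(0.5, 0.35, 0.15)) {
  sample(c("W", "N", "R"), n, replace = TRUE, prob = p)
}

# Epoch table with planted SWA/EMG columns for SWE tests.
fixture_epochs <- function(n = 720, seed = 1, t0_zt = 0) {
  withr::with_seed(seed, {
    ep <- epoch_table(random_states(n), t0_zt = t0_zt)
    ep$swa <- stats::rlnorm(n, log(100), 0.4)
    ep$emg_ptp <- stats::rlnorm(n, log(50), 0.6)
    ep
  })
}

# ZT bin label used by the normalization tests (2-h bins aligned to ZT0).
zt_bin_of <- function(zt_hours, bin_hours = 2) {
  floor((zt_hours %% 24) / bin_hours) * bin_hours
}
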