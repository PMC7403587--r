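#' Fixed-period cosinor fit
#'
#' Least-squares fit of a single-component cosine of fixed period to a
#' (binned) temperature series:
#' \deqn{y(t) = M + A \cos(2\pi (t - \phi)/\tau) + e(t)}
#' estimated by linearization on cosine/sine regressors, giving the MESOR
#' \eqn{M} (rhythm-adjusted mean), amplitude \eqn{A = \sqrt{\beta_c^2 +
#' \beta_s^2} \ge 0} and acrophase \eqn{\phi} (peak time) mapped to
#' zeitgeber hours in `[0, 24)`. The period \eqn{\tau} is fixed at 24 h for
#' the entrained light-dark design. Missing and artifact-masked bins are
#' omitted from the design (no imputation).
#'
#' @param temps A temperature table (typically 5-min bins over 72 h).
#' @param period_h Rhythm period in hours (default 24).
#' @param span_h Optional analysis span: only samples with
#'   `t_hours < span_h` after `t_start` enter the fit.
#' @param t_start Start of the analysis span in `t_hours` (default 0).
#' @return An object of class `cosinor_fit` with elements `mesor`,
#'   `amplitude`, `acrophase_zt`, `period_h`, `rss`, `n`.
#' @examples
#' zt <- seq(0, 71.9, by = 1 / 12)
#' tt <- temperature_table(37 + 0.6 * cos(2 * pi * (zt - 18) / 24), t_hours = zt)
#' cosinor_fit(tt)
#' @export
cosinor_fit <- function(temps, period_h = 24, span_h = NULL, t_start = 0) {
  .check_temps(temps)
  keep <- !(.col_or(temps, "artifact", FALSE)) & !is.na(temps$temp_c) &
    temps$t_hours >= t_start
  if (!is.null(span_h)) {
    if (span_h < period_h) abort("Analysis span must cover at least one full period.")
    keep <- keep & temps$t_hours < t_start + span_h
  }
  d <- temps[keep, , drop = FALSE]
  if (nrow(d) < 3) abort("Too few usable samples for a cosinor fit.")
  if (diff(range(d$t_hours)) < period_h * 0.5) {
    abort("Usable samples span less than half a period; fit would be unstable.")
  }
  # regress on ZT so the acrophase comes out directly in zeitgeber hours
  zt <- if ("zt_hours" %in% names(d)) {
    (d$zt_hours[1] - d$t_hours[1]) + d$t_hours
  } else d$t_hours
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * zt), sin(w * zt))
  fit <- stats::lm.fit(X, d$temp_c)
  b <- fit$coefficients
  amp <- sqrt(b[2]^2 + b[3]^2)
  phi <- (atan2(b[3], b[2]) / w) %% period_h
  structure(
    list(
      mesor = unname(b[1]),
      amplitude = unname(amp),
      acrophase_zt = unname(phi),
      period_h = period_h,
      rss = sum(fit$residuals^2),
      n = nrow(d)
    ),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (period %.1f h, n = %d)\n  MESOR %.4f  amplitude %.4f  acrophase ZT %.2f  RSS %.4g\n",
    x$period_h, x$n, x$mesor, x$amplitude, x$acrophase_zt, x$rss
  ))
  invisible(x)
}

#' Tidy a cosinor fit
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @return One-row tibble with `mesor`, `amplitude`, `acrophase_zt`,
#'   `period_h`, `rss`, `n`.
#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble(
    mesor = x$mesor, amplitude = x$amplitude, acrophase_zt = x$acrophase_zt,
    period_h = x$period_h, rss = x$rss, n = x$n
  )
}

#' @rdname tidy.cosinor_fit
#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) tidy.cosinor_fit(x, ...)

#' Amplitude change between two cosinor fits
#'
#' Rhythm-strength change from baseline, computed by subtraction:
#' `delta = work amplitude - baseline amplitude` (negative values indicate
#' damping of the rhythm).
#'
#' @param baseline,work `cosinor_fit` objects sharing a period.
#' @return One-row tibble with `baseline_amp`, `work_amp`, `delta`.
#' @export
amplitude_change <- function(baseline, work) {
  if (!inherits(baseline, "cosinor_fit") || !inherits(work, "cosinor_fit")) {
    abort("Both arguments must be cosinor_fit objects.")
  }
  if (!isTRUE(all.equal(baseline$period_h, work$period_h))) {
    abort("Fits must share the same period.")
  }
  tibble(
    baseline_amp = baseline$amplitude,
    work_amp = work$amplitude,
    delta = work$amplitude - baseline$amplitude
  )
}

#' Plot a cosinor fit over the binned data
#'
#' @param temps The temperature table the fit was computed from.
#' @param fit A `cosinor_fit`.
#' @return A ggplot object.
#' @export
plot_cosinor <- function(temps, fit) {
  .check_temps(temps)
  zt0 <- if ("zt_hours" %in% names(temps)) (temps$zt_hours[1] - temps$t_hours[1]) else 0
  grid <- tibble(t_hours = seq(min(temps$t_hours), max(temps$t_hours), length.out = 500))
  grid$pred <- fit$mesor + fit$amplitude *
    cos(2 * pi * ((zt0 + grid$t_hours) - fit$acrophase_zt) / fit$period_h)
  ggplot2::ggplot(temps, ggplot2::aes(x = .data$t_hours, y = .data$temp_c)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$pred),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "Temperature (°C)",
                  title = sprintf("Cosinor fit: A = %.2f, acrophase ZT %.1f",
                                  fit$amplitude, fit$acrophase_zt)) +
    ggplot2::theme_minimal()
}
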