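#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Coerce a group argument to summary statistics. Accepts a numeric vector or
# a list/one-row data frame with mean, sd, n.
.as_summary <- function(g, arg = "group") {
  if (is.numeric(g)) {
    if (length(g) < 2) abort(paste0("`", arg, "` needs n >= 2."))
    return(list(mean = mean(g), sd = stats::sd(g), n = length(g)))
  }
  g <- as.list(g)
  if (!all(c("mean", "sd", "n") %in% names(g))) {
    abort(paste0("`", arg, "` must be a numeric vector or have mean, sd, n."))
  }
  if (g$n < 2) abort(paste0("`", arg, "` needs n >= 2."))
  if (g$sd < 0) abort("SD must be non-negative.")
  g[c("mean", "sd", "n")]
}

#' Two-sample Student t-test from vectors or summary statistics
#'
#' Pooled-variance (equal-variance) Student t-test with
#' `df = n1 + n2 - 2`, as used for all between-group comparisons here
#' (a Welch option is available behind a flag). Groups may be given as raw
#' numeric vectors or as summary statistics `list(mean, sd, n)`; both entry
#' points agree exactly. The sign convention is `group2 - group1`: pass the
#' reference group first and the experimental group second.
#'
#' @param g1 Reference group (vector or `list(mean=, sd=, n=)`).
#' @param g2 Experimental group.
#' @param welch Use the Welch-Satterthwaite correction instead of pooling.
#' @return One-row tibble: `t`, `df`, `p`, `d` (Cohen's d per
#'   [cohens_d_independent()]), `mean1`, `mean2`, `n1`, `n2`.
#' @examples
#' two_sample_t(list(mean = 32.1, sd = 34.6, n = 13),
#'              list(mean = 13.8, sd = 9.5, n = 17))
#' @export
two_sample_t <- function(g1, g2, welch = FALSE) {
  s1 <- .as_summary(g1, "g1"); s2 <- .as_summary(g2, "g2")
  delta <- s2$mean - s1$mean
  if (welch) {
    se2 <- s1$sd^2 / s1$n + s2$sd^2 / s2$n
    if (se2 == 0) {
      if (delta == 0) { t <- 0; df <- s1$n + s2$n - 2 }
      else abort("Zero variance with unequal means: t is undefined.")
    } else {
      t <- delta / sqrt(se2)
      df <- se2^2 / ((s1$sd^2 / s1$n)^2 / (s1$n - 1) + (s2$sd^2 / s2$n)^2 / (s2$n - 1))
    }
  } else {
    df <- s1$n + s2$n - 2
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
    if (sp2 == 0) {
      if (delta == 0) t <- 0
      else abort("Zero pooled variance with unequal means: t is undefined.")
    } else {
      t <- delta / sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    }
  }
  d <- tryCatch(cohens_d_independent(s1, s2), error = function(e) NA_real_)
  tibble(
    t = t, df = df, p = 2 * stats::pt(-abs(t), df), d = d,
    mean1 = s1$mean, mean2 = s2$mean, n1 = s1$n, n2 = s2$n
  )
}

#' Cohen's d for independent groups (RMS-SD convention)
#'
#' Effect size `d = (m2 - m1) / sqrt((s1^2 + s2^2) / 2)`: the denominator is
#' the root mean square of the two group SDs, not the df-weighted pooled SD.
#' With equal SDs it reduces to the classical d. Sign follows the
#' `group2 - group1` convention of [two_sample_t()].
#'
#' @param g1,g2 Groups as vectors or `list(mean=, sd=, n=)`.
#' @return Numeric scalar d.
#' @export
cohens_d_independent <- function(g1, g2) {
  s1 <- .as_summary(g1, "g1"); s2 <- .as_summary(g2, "g2")
  denom <- sqrt((s1$sd^2 + s2$sd^2) / 2)
  if (denom == 0) abort("Both SDs are zero: d is undefined.")
  (s2$mean - s1$mean) / denom
}

#' Paired Student t-test
#'
#' `t = mean(diff) / (sd(diff) / sqrt(n))` with `df = n - 1`, where
#' `diff = y - x`. Two candidate paired effect sizes are reported, since the
#' field uses both: `d_z = mean(diff)/sd(diff)` and `d_rm`, the mean
#' difference over the RMS of the two condition SDs.
#'
#' @param x Baseline/reference measurements.
#' @param y Paired experimental measurements.
#' @return One-row tibble: `t`, `df`, `p`, `d_z`, `d_rm`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("Paired vectors must have equal length.")
  if (length(x) < 2) abort("Need at least 2 pairs.")
  d <- y - x
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      t <- 0
    } else {
      abort("Zero-variance nonzero differences: t is undefined.")
    }
  } else {
    t <- mean(d) / (sdd / sqrt(length(d)))
  }
  rms <- sqrt((stats::sd(x)^2 + stats::sd(y)^2) / 2)
  tibble(
    t = t, df = length(d) - 1, p = 2 * stats::pt(-abs(t), length(d) - 1),
    d_z = if (sdd > 0) mean(d) / sdd else NA_real_,
    d_rm = if (rms > 0) mean(d) / rms else NA_real_,
    mean_diff = mean(d), n = length(d)
  )
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with a two-sided p-value from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return One-row tibble: `r`, `n`, `df`, `t`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("Vectors must have equal length.")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in x or y: correlation is undefined.")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, n = n, df = n - 2, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Label an effect size by conventional magnitude thresholds
#'
#' |d| below 0.2 is `"negligible"`, then `"small"` from 0.2, `"medium"` from
#' 0.5 and `"large"` from 0.8 (boundaries inclusive at the larger label).
#'
#' @param d Numeric vector of effect sizes.
#' @return Character vector of labels.
#' @export
label_effect_size <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a >= 0.8 ~ "large",
    a >= 0.5 ~ "medium",
    a >= 0.2 ~ "small",
    TRUE ~ "negligible"
  )
}
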