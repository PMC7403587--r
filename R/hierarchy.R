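#' Ordinary least squares with ledger statistics
#'
#' Fits `y` on the given predictor columns (intercept always included) and
#' returns the fit statistics used by the hierarchical ledger: R-squared,
#' adjusted R-squared, the overall-model F with its degrees of freedom, and
#' the F-test p-value. Rank deficiency is a hard error naming the aliased
#' columns rather than silent dropping.
#'
#' @param data A data frame with one row per animal.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return One-row tibble: `n`, `p`, `r2`, `adj_r2`, `f`, `df1`, `df2`,
#'   `p_value`, plus a list-column `coefficients`.
#' @export
fit_ols <- function(data, outcome, predictors) {
  cols <- c(outcome, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1) {
    abort(sprintf("Insufficient data: n = %d with %d predictors (need n > p + 1).", n, p))
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors), response = sprintf("`%s`", outcome))
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(paste0("Collinear (rank-deficient) predictors: ", paste(bad, collapse = ", ")))
  }
  y <- d[[outcome]]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  df2 <- n - p - 1
  f <- (r2 / p) / ((1 - r2) / df2)
  tibble(
    n = n, p = p, r2 = r2,
    adj_r2 = adjusted_r2(r2, n, p),
    f = f, df1 = p, df2 = df2,
    p_value = stats::pf(f, p, df2, lower.tail = FALSE),
    coefficients = list(stats::coef(fit))
  )
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`. May be negative when the model
#' explains less than its degrees of freedom cost.
#'
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param n Sample size.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p + 1)) abort("Adjusted R-squared requires n > p + 1.")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Define an ordered predictor block
#'
#' @param name Block label (e.g. "work condition", "daily rhythm dynamics").
#' @param variables Character vector of predictor column names.
#' @return A `predictor_block` list.
#' @export
predictor_block <- function(name, variables) {
  if (length(variables) == 0) abort("A block needs at least one variable.")
  structure(list(name = name, variables = as.character(variables)),
            class = "predictor_block")
}

#' Default predictor-block ordering
#'
#' The four blocks of the study design: (1) work condition, (2) daily rhythm
#' dynamics (temperature-amplitude change, REM-sleep latency), (3) a sleep
#' block in one of three variants — `sleep_drive` (mean NREM bout length and
#' cumulated slow-wave energy in quiet wakefulness; the main model),
#' `cumulative_sleep` (total NREM and REM sleep time) or `nrem_swe`
#' (slow-wave energy in NREM sleep) — and (4) serum corticosterone.
#'
#' @param step3_variant One of `"sleep_drive"`, `"cumulative_sleep"`,
#'   `"nrem_swe"`.
#' @param include_corticosterone Include block 4 (default TRUE).
#' @return List of [predictor_block()]s.
#' @export
default_blocks <- function(step3_variant = c("sleep_drive", "cumulative_sleep", "nrem_swe"),
                           include_corticosterone = TRUE) {
  step3_variant <- match.arg(step3_variant)
  step3 <- switch(step3_variant,
    sleep_drive = predictor_block("sleep drive", c("nrem_bout_min", "qw_swe")),
    cumulative_sleep = predictor_block("cumulative sleep", c("cum_nrem_min", "cum_rem_min")),
    nrem_swe = predictor_block("NREM sleep SWE", "nrem_swe")
  )
  blocks <- list(
    predictor_block("work condition", "condition"),
    predictor_block("daily rhythm dynamics", c("amp_change", "rem_latency_min")),
    step3
  )
  if (include_corticosterone) {
    blocks <- c(blocks, list(predictor_block("serum corticosterone", "corticosterone")))
  }
  blocks
}

#' Hierarchical regression ledger
#'
#' Fits an ordered sequence of nested OLS models: step k regresses the
#' outcome on the union of predictor blocks 1..k. Each step reports
#' R-squared, adjusted R-squared, the change in adjusted R-squared versus
#' the previous step, and the cumulative-model overall F with its degrees of
#' freedom (a block-increment partial F is available via
#' `partial_f = TRUE`). Rows with any missing value among the outcome or the
#' full predictor set are dropped listwise, so every step is fitted on the
#' same animals; the retained n is reported. Small samples (n - p - 1 < 3 at
#' the final step) trigger a warning, not an error, since designs with 9-13
#' animals and up to 6 predictors are in scope.
#'
#' @param data Data frame, one row per animal, containing the outcome and
#'   all block variables.
#' @param outcome Name of the outcome column.
#' @param blocks Ordered list of [predictor_block()]s (default
#'   [default_blocks()]).
#' @param partial_f Also report the block-increment partial F per step.
#' @return An object of class `sw_ledger`: a list with `outcome`, `n`,
#'   `steps` (a tibble with one row per step).
#' @export
hierarchical_ledger <- function(data, outcome, blocks = default_blocks(),
                                partial_f = FALSE) {
  vars <- unlist(lapply(blocks, `[[`, "variables"))
  if (anyDuplicated(vars)) {
    abort(paste0("Variable(s) appear in more than one block: ",
                 paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  }
  cols <- c(outcome, vars)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d)
  p_final <- length(vars)
  if (n - p_final - 1 < 3) {
    warn(sprintf(
      "Small sample: n = %d with %d predictors at the final step (residual df = %d).",
      n, p_final, n - p_final - 1
    ))
  }
  steps <- vector("list", length(blocks))
  prev_adj <- NA_real_
  prev_fit <- NULL
  for (k in seq_along(blocks)) {
    preds <- unlist(lapply(blocks[seq_len(k)], `[[`, "variables"))
    fit <- fit_ols(d, outcome, preds)
    row <- tibble(
      step = k,
      block = blocks[[k]]$name,
      variables = paste(blocks[[k]]$variables, collapse = " + "),
      cumulative_predictors = fit$p,
      r2 = fit$r2,
      adj_r2 = fit$adj_r2,
      delta_adj_r2 = if (k == 1) NA_real_ else fit$adj_r2 - prev_adj,
      f = fit$f, df1 = fit$df1, df2 = fit$df2, p_value = fit$p_value
    )
    if (partial_f) {
      if (k == 1) {
        row$partial_f <- fit$f
        row$partial_p <- fit$p_value
      } else {
        q <- length(blocks[[k]]$variables)
        num <- (fit$r2 - prev_fit$r2) / q
        den <- (1 - fit$r2) / fit$df2
        row$partial_f <- num / den
        row$partial_p <- stats::pf(row$partial_f, q, fit$df2, lower.tail = FALSE)
      }
    }
    steps[[k]] <- row
    prev_adj <- fit$adj_r2
    prev_fit <- fit
  }
  structure(
    list(outcome = outcome, n = n, steps = dplyr::bind_rows(steps)),
    class = "sw_ledger"
  )
}

#' @export
print.sw_ledger <- function(x, ...) {
  cat(sprintf("Hierarchical regression ledger: %s (n = %d)\n", x$outcome, x$n))
  print(as.data.frame(x$steps[, c("step", "block", "r2", "adj_r2",
                                  "delta_adj_r2", "f", "df1", "df2", "p_value")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy a hierarchical regression ledger
#' @param x An `sw_ledger`.
#' @param ... Unused.
#' @return The per-step tibble with the outcome name and n attached.
#' @method tidy sw_ledger
#' @export
tidy.sw_ledger <- function(x, ...) {
  mutate(x$steps, outcome = x$outcome, n = x$n, .before = 1)
}

#' @rdname tidy.sw_ledger
#' @method glance sw_ledger
#' @export
glance.sw_ledger <- function(x, ...) {
  last <- x$steps[nrow(x$steps), ]
  tibble(outcome = x$outcome, n = x$n, n_steps = nrow(x$steps),
         r2 = last$r2, adj_r2 = last$adj_r2, f = last$f,
         df1 = last$df1, df2 = last$df2, p_value = last$p_value)
}

#' Plot the adjusted-R-squared trajectory of a ledger
#'
#' @param object An `sw_ledger`.
#' @param ... Unused.
#' @return A ggplot object showing R-squared and adjusted R-squared per step.
#' @method autoplot sw_ledger
#' @export
autoplot.sw_ledger <- function(object, ...) {
  d <- tidyr::pivot_longer(object$steps, c("r2", "adj_r2"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$steps$step,
                                labels = object$steps$block) +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  title = paste("Hierarchical regression:", object$outcome)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
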