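test_that("OLS fit statistics match hand computations and lm on small fixtures", {
  d <- data.frame(y = c(1, 2, 4), x = c(0, 1, 2))
  fit <- fit_ols(d, "y", "x")
  expect_equal(fit$r2, 27 / 28, tolerance = 1e-12)

  # exact linearity and orthogonality
  d2 <- data.frame(y = 2 * (1:6) - 3, x = 1:6)
  expect_equal(fit_ols(d2, "y", "x")$r2, 1)
  expect_equal(fit_ols(d2, "y", "x")$adj_r2, 1)
  d3 <- data.frame(y = c(-1, 1, -1, 1), x = c(1, 1, -1, -1))
  f3 <- fit_ols(d3, "y", "x")
  expect_equal(f3$r2, 0, tolerance = 1e-12)
  expect_equal(f3$f, 0, tolerance = 1e-12)

  withr::with_seed(33, {
    d4 <- data.frame(y = rnorm(20), a = rnorm(20), b = rnorm(20))
    f4 <- fit_ols(d4, "y", c("a", "b"))
    ref <- summary(lm(y ~ a + b, d4))
    expect_equal(f4$r2, ref$r.squared, tolerance = 1e-12)
    expect_equal(f4$adj_r2, ref$adj.r.squared, tolerance = 1e-12)
    expect_equal(f4$f, unname(ref$fstatistic[1]), tolerance = 1e-10)
  })

  expect_error(fit_ols(data.frame(y = 1:3, x = 1:3, z = 4:6), "y", c("x", "z")),
               "Insufficient|Collinear")
  d5 <- data.frame(y = rnorm(10), x = 1:10, z = 2 * (1:10))
  expect_error(fit_ols(d5, "y", c("x", "z")), "Collinear")
})

test_that("adjusted R-squared follows the closed form, including negative values", {
  expect_equal(adjusted_r2(1, 10, 3), 1)
  expect_equal(adjusted_r2(0.5, 13, 2), 0.4, tolerance = 1e-12)
  expect_equal(adjusted_r2(0.20, 10, 6), -1.4, tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
  # identity against residual-based computation on random fixtures
  withr::with_seed(34, {
    for (i in 1:50) {
      n <- sample(8:30, 1); p <- sample(1:3, 1)
      d <- as.data.frame(matrix(rnorm(n * (p + 1)), n))
      names(d) <- c("y", paste0("x", 1:p))
      fit <- lm(y ~ ., d)
      r2 <- 1 - sum(resid(fit)^2) / sum((d$y - mean(d$y))^2)
      expect_equal(adjusted_r2(r2, n, p), summary(fit)$adj.r.squared,
                   tolerance = 1e-10)
    }
  })
})

test_that("ledger steps nest predictors with nondecreasing R2 and correct dfs", {
  withr::with_seed(35, {
    pred <- simulate_predictors(9, 8, seed = 35)
    out <- generate_outcomes(pred, seed = 35)
    d <- dplyr::left_join(pred, dplyr::select(out, animal_id, mwm_latency),
                          by = "animal_id")
    lg <- suppressWarnings(hierarchical_ledger(d, "mwm_latency"))
    st <- lg$steps
    expect_equal(st$cumulative_predictors, c(1, 3, 5, 6))
    expect_true(all(diff(st$r2) >= -1e-12))
    expect_equal(st$df1, st$cumulative_predictors)
    expect_equal(st$df2, lg$n - st$cumulative_predictors - 1)
    expect_equal(st$delta_adj_r2[-1], diff(st$adj_r2), tolerance = 1e-12)
    # step F and p agree with the generic linear-model oracle
    for (k in seq_len(nrow(st))) {
      vars <- unlist(lapply(default_blocks()[1:k], `[[`, "variables"))
      ref <- summary(lm(stats::reformulate(vars, "mwm_latency"), d))
      expect_equal(st$f[k], unname(ref$fstatistic[1]), tolerance = 1e-9)
      expect_equal(st$r2[k], ref$r.squared, tolerance = 1e-12)
    }
  })
})

test_that("duplicate variables across blocks and listwise deletion are handled", {
  pred <- simulate_predictors(9, 8, seed = 36)
  out <- generate_outcomes(pred, seed = 36)
  d <- dplyr::left_join(pred, dplyr::select(out, animal_id, mwm_latency),
                        by = "animal_id")
  dup <- list(predictor_block("a", "condition"),
              predictor_block("b", c("amp_change", "condition")))
  expect_error(hierarchical_ledger(d, "mwm_latency", dup), "more than one block")

  d$amp_change[1:3] <- NA
  lg <- suppressWarnings(hierarchical_ledger(d, "mwm_latency"))
  expect_equal(lg$n, nrow(d) - 3)

  # small residual df triggers a warning, not an error
  expect_warning(hierarchical_ledger(d[1:11, ], "mwm_latency"), "Small sample")
})

test_that("a pure-noise second block does not add adjusted R2 in expectation", {
  withr::with_seed(37, {
    deltas <- replicate(300, {
      n <- 30
      d <- data.frame(y = rnorm(n), x1 = rnorm(n), noise = rnorm(n))
      blocks <- list(predictor_block("signal", "x1"),
                     predictor_block("noise", "noise"))
      hierarchical_ledger(d, "y", blocks)$steps$delta_adj_r2[2]
    })
    expect_lt(mean(deltas), 0.01)
  })
})

test_that("an informative second block raises adjusted R2 in at least 90% of seeds", {
  withr::with_seed(38, {
    hits <- replicate(500, {
      n <- 13
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- 0.3 * x1 + 0.8 * x2 + rnorm(n)  # planted standardized effect 0.8
      d <- data.frame(y = y, x1 = x1, x2 = x2)
      blocks <- list(predictor_block("b1", "x1"), predictor_block("b2", "x2"))
      hierarchical_ledger(d, "y", blocks)$steps$delta_adj_r2[2] > 0
    })
    expect_gte(mean(hits), 0.9)
  })
})

test_that("partial F for a block increment matches anova()", {
  withr::with_seed(39, {
    n <- 25
    d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    blocks <- list(predictor_block("one", "a"), predictor_block("two", c("b", "c")))
    lg <- hierarchical_ledger(d, "y", blocks, partial_f = TRUE)
    ref <- anova(lm(y ~ a, d), lm(y ~ a + b + c, d))
    expect_equal(lg$steps$partial_f[2], ref$F[2], tolerance = 1e-9)
    expect_equal(lg$steps$partial_p[2], ref$`Pr(>F)`[2], tolerance = 1e-9)
  })
})

test_that("tidy and glance expose the ledger as tables", {
  pred <- simulate_predictors(9, 8, seed = 40)
  out <- generate_outcomes(pred, seed = 40)
  d <- dplyr::left_join(pred, dplyr::select(out, animal_id, mwm_latency),
                        by = "animal_id")
  lg <- suppressWarnings(hierarchical_ledger(d, "mwm_latency"))
  td <- tidy(lg)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- glance(lg)
  expect_equal(gl$r2, td$r2[4])
  expect_s3_class(autoplot(lg), "ggplot")
})
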