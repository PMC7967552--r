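flat_series <- function(n, start = "2000-01", value = 0) {
  months <- month_seq(start, format(seq(as_month(start), by = "month",
                                        length.out = n)[n], "%Y-%m"))
  tibble::tibble(month = months, value = rep(value, n))
}

test_that("design-readiness checks count pre/post months and flag short series", {
  s <- flat_series(240)
  spec <- intervention_spec(s$month[97])
  rep1 <- check_design(s, spec)
  expect_equal(rep1$interventions$pre, 96)
  expect_equal(rep1$interventions$post, 144)
  expect_true(rep1$interventions$pass)
  expect_true(is.na(rep1$total_advisory))

  spec2 <- intervention_spec(s$month[231])
  rep2 <- check_design(s, spec2)
  expect_equal(rep2$interventions$post, 10)
  expect_false(rep2$interventions$pass)
  expect_true(rep2$interventions$pass_pre)

  rep3 <- check_design(flat_series(30), intervention_spec("2001-01"))
  expect_match(rep3$total_advisory, "below the advised minimum")
})

test_that("effect columns encode steps and ramps on the monthly grid", {
  s <- flat_series(240)
  k <- 100
  X <- build_design_matrix(s, intervention_spec(s$month[k]))
  step <- X[, ncol(X)]
  expect_equal(sum(step), 240 - k + 1)
  expect_equal(unname(step[k - 1]), 0)
  expect_equal(unname(step[k]), 1)

  # lag 1 ramp degenerates to the abrupt step
  X1 <- build_design_matrix(s, intervention_spec(s$month[k], shape = "lagged",
                                                 lag_months = 1))
  expect_equal(unname(X1[, ncol(X1)]), unname(step))

  # lag 24: linear 1/24 .. 1 over months k .. k+23, then 1
  X24 <- build_design_matrix(s, intervention_spec(s$month[k], shape = "lagged",
                                                  lag_months = 24))
  ramp <- unname(X24[, ncol(X24)])
  expect_equal(ramp[k - 1], 0)
  expect_equal(ramp[k:(k + 23)], (1:24) / 24)
  expect_equal(ramp[(k + 24):240], rep(1, 240 - k - 23))

  # seasonal structure: 11 indicators, December as reference
  expect_equal(sum(grepl("^month_", colnames(X))), 11)
  dec_rows <- which(format(s$month, "%m") == "12")
  expect_true(all(X[dec_rows, grepl("^month_", colnames(X))] == 0))

  # two interventions in the same month are collinear
  expect_error(
    build_design_matrix(s, intervention_spec(c(s$month[k], s$month[k]),
                                             name = c("a", "b"))),
    "collinear|rank deficient"
  )
  expect_error(build_design_matrix(s[-5, ], intervention_spec(s$month[k])),
               "consecutive")
})

test_that("a noise-free series is recovered exactly, including the step effect", {
  cfg <- simulation_config(
    months = month_seq("2000-01", "2019-12"), seed = 2,
    baseline_level = 12, trend_per_month = -0.004, seasonal_amplitude = 0.9,
    interventions = tibble::tibble(date = as.Date("2008-04-01"),
                                   shape = "abrupt", true_effect = -1,
                                   lag_months = NA_integer_)
  )
  s <- simulate_outcome(cfg)
  suppressWarnings(fit <- fit_its(s, intervention_spec("2008-04"),
                                  ar1 = FALSE))
  expect_lt(abs(fit$effects$estimate - (-1)), 1e-8)
  expect_lt(abs(tidy(fit)$estimate[tidy(fit)$term == "time"] - (-0.004)),
            1e-8)
  expect_equal(glance(fit)$n, 240)

  # lagged ground truth, lagged estimator: exact too
  cfg$interventions$shape <- "lagged"
  cfg$interventions$lag_months <- 12L
  s2 <- simulate_outcome(cfg)
  suppressWarnings(fit2 <- fit_its(
    s2, intervention_spec("2008-04", shape = "lagged", lag_months = 12),
    ar1 = FALSE
  ))
  expect_lt(abs(fit2$effects$estimate - (-1)), 1e-8)
})

test_that("shifting the outcome by a constant moves only the intercept", {
  cfg <- simulation_config(months = month_seq("2005-01", "2016-12"), seed = 8,
                           baseline_level = 5, ar1_rho = 0.2, noise_sd = 0.4,
                           interventions = tibble::tibble(
                             date = as.Date("2010-01-01"), shape = "abrupt",
                             true_effect = -0.5, lag_months = NA_integer_))
  s <- simulate_outcome(cfg)
  f1 <- fit_its(s, intervention_spec("2010-01"))
  s2 <- dplyr::mutate(s, value = value + 100)
  f2 <- fit_its(s2, intervention_spec("2010-01"))
  c1 <- tidy(f1)
  c2 <- tidy(f2)
  keep <- c1$term != "(Intercept)"
  expect_equal(c2$estimate[keep], c1$estimate[keep], tolerance = 1e-8)
  expect_equal(unname(c2$estimate[!keep] - c1$estimate[!keep]), 100,
               tolerance = 1e-6)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-6)
})

test_that("the AR(1) iteration converges and reports whitened diagnostics", {
  cfg <- simulation_config(months = month_seq("2000-01", "2019-12"), seed = 4,
                           baseline_level = 10, ar1_rho = 0.5, noise_sd = 0.6,
                           interventions = tibble::tibble(
                             date = as.Date("2009-01-01"), shape = "abrupt",
                             true_effect = -0.8, lag_months = NA_integer_))
  fit <- fit_its(simulate_outcome(cfg), intervention_spec("2009-01"))
  g <- glance(fit)
  expect_true(g$converged)
  expect_gt(g$rho, 0.2)
  expect_lt(abs(g$resid_lag1), 0.15) # whitened residuals near-uncorrelated
  td <- tidy(fit)
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  # covariate entry mode: regressing on an external score series
  w <- lt_window()
  tiers <- classify_tiers(lithuania_timeline(), lithuania_economy(), w)
  sc <- cumulative_score(tiers, w)
  s <- simulate_outcome(simulation_config(months = sc$month, seed = 5,
                                          baseline_level = 10,
                                          noise_sd = 0.3))
  s$value <- s$value - 0.6 * sc$score
  s$policy_score <- sc$score
  fit_sc <- fit_its(s, intervention_spec(character(0))[0, ], ar1 = FALSE)
  est <- tidy(fit_sc)$estimate[tidy(fit_sc)$term == "policy_score"]
  expect_lt(abs(est - (-0.6)), 0.05)
})
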