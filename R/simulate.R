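# Synthetic-data generators. Every stage of the pipeline can be exercised
# on data with known ground truth: an economic series solved to hit
# prescribed affordability changes, a monthly outcome series with known
# trend/seasonality/effects/AR(1) noise, and expert rating matrices with
# controllable agreement. One root seed feeds named child streams in a
# fixed order, so generators are bit-reproducible and mutually independent.

#' Simulate an annual economic series with prescribed affordability changes
#'
#' Constructs income and price index paths whose year-over-year
#' affordability changes reproduce `target_changes` exactly. The income
#' path is a geometric random walk with drift; the price path is solved
#' from the affordability recursion
#' `A_t = A_{t-1} * (1 + change_t / 100)`, `P_t = I_t / A_t`. Both
#' components are then rescaled so that the base year equals 100 (which
#' leaves every affordability change unchanged).
#'
#' @param target_changes A data frame with columns `year` and `change_pct`;
#'   consecutive years, the year *before* the first target anchors the
#'   series and carries no change.
#' @param base_year Year whose components are normalized to 100; defaults
#'   to the anchor year.
#' @param seed Integer seed (economy stream).
#' @param income_drift,income_sd Annual log-scale drift and volatility of
#'   the income path. Defaults 0.04 and 0.02.
#' @return A validated economic series tibble (`year`, `income_index`,
#'   `price_index`).
#' @examples
#' ec <- simulate_economy(
#'   tibble::tibble(year = 2009:2012, change_pct = c(3, -15.3, -10.9, 7.6)),
#'   seed = 1
#' )
#' round(affordability_index(ec, base_year = 2008)$change_pct, 6)
#' @export
simulate_economy <- function(target_changes, base_year = NULL, seed = 1,
                             income_drift = 0.04, income_sd = 0.02) {
  tc <- as_tibble(target_changes)
  if (!all(c("year", "change_pct") %in% names(tc))) {
    abort("target_changes needs columns year and change_pct")
  }
  if (nrow(tc) == 0) abort("no target changes supplied")
  if (any(!is.finite(tc$change_pct))) abort("targets must be finite")
  if (any(diff(tc$year) != 1)) abort("target years must be consecutive")
  if (any(tc$change_pct <= -100)) {
    abort("a change of -100% or lower implies a non-positive index")
  }
  years <- c(tc$year[1] - 1L, tc$year)
  n <- length(years)
  base_year <- base_year %||% years[1]
  if (!(base_year %in% years)) abort("base_year must lie within the series")

  income <- with_stream_seed(seed, "economy", {
    exp(cumsum(c(0, rnorm(n - 1, mean = income_drift, sd = income_sd))))
  })
  afford <- cumprod(c(1, 1 + tc$change_pct / 100))
  price <- income / afford

  b <- match(base_year, years)
  tibble(
    year = as.integer(years),
    income_index = 100 * income / income[b],
    price_index = 100 * price / price[b]
  ) |>
    validate_economic_series(base_year = base_year)
}

#' Configuration for a simulated monthly outcome series
#'
#' Bundles the data-generating parameters of [simulate_outcome()]: a
#' deterministic structure (baseline level, linear trend, cosine
#' seasonality), intervention effects (step or ramp, as the estimator
#' models them), optional covariates with known coefficients, and AR(1)
#' noise.
#'
#' @param months Consecutive months (`Date` vector or output of
#'   [month_seq()]).
#' @param seed Integer root seed.
#' @param baseline_level Outcome level at time 0. Default 10 (a scale like
#'   litres of pure alcohol per adult per year, observed monthly).
#' @param trend_per_month Linear trend per month. Default 0.
#' @param seasonal_amplitude Amplitude of a cosine annual cycle. Default 0.
#' @param ar1_rho AR(1) coefficient of the noise, `|rho| < 1`. Default 0.
#' @param noise_sd Innovation standard deviation, `>= 0`. Default 0.
#' @param interventions Tibble with columns `date`, `shape`
#'   (`abrupt`/`lagged`), `true_effect`, `lag_months`. Default none.
#' @param covariate_effects Named numeric vector of coefficients; a
#'   standardized AR(1) covariate path is generated for each name. Default
#'   none.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(months, seed = 1, baseline_level = 10,
                              trend_per_month = 0, seasonal_amplitude = 0,
                              ar1_rho = 0, noise_sd = 0,
                              interventions = NULL,
                              covariate_effects = NULL) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (abs(ar1_rho) >= 1) abort("|ar1_rho| must be < 1")
  interventions <- interventions %||%
    tibble(date = as.Date(character()), shape = character(),
           true_effect = numeric(), lag_months = integer())
  structure(
    list(months = as_month(months), seed = as.integer(seed),
         baseline_level = baseline_level, trend_per_month = trend_per_month,
         seasonal_amplitude = seasonal_amplitude, ar1_rho = ar1_rho,
         noise_sd = noise_sd, interventions = as_tibble(interventions),
         covariate_effects = covariate_effects),
    class = "simulation_config"
  )
}

#' Simulate a monthly outcome series
#'
#' Generates
#' `value_t = baseline + trend * t + amplitude * cos(2 pi month_t / 12)
#' + sum(effects_t) + sum(beta_j * covariate_jt) + e_t`
#' with `e_t = rho * e_{t-1} + N(0, noise_sd^2)` (stationary start).
#' Intervention effects follow the same step/ramp encodings as
#' [build_design_matrix()]. Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return A tibble: `month`, `value`, one column per covariate.
#' @export
simulate_outcome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  months <- config$months
  n <- length(months)
  t_idx <- seq_len(n)
  moy <- as.integer(format(months, "%m"))

  det <- config$baseline_level + config$trend_per_month * t_idx +
    config$seasonal_amplitude * cos(2 * pi * moy / 12)

  iv <- config$interventions
  if (nrow(iv) > 0) {
    specs <- intervention_spec(iv$date, shape = iv$shape,
                               lag_months = iv$lag_months)
    shapes <- vapply(seq_len(nrow(specs)), function(i) {
      k <- month_index(specs$date[i]) - month_index(months[1]) + 1L
      if (specs$shape[i] == "abrupt" || specs$lag_months[i] == 1L) {
        as.numeric(t_idx >= k)
      } else {
        pmin(pmax((t_idx - k + 1) / specs$lag_months[i], 0), 1)
      }
    }, numeric(n))
    det <- det + as.vector(shapes %*% iv$true_effect)
  }

  out <- tibble(month = months, value = det)

  with_stream_seed(config$seed, "outcome", {
    cov_eff <- config$covariate_effects
    if (!is.null(cov_eff) && length(cov_eff) > 0) {
      for (nm in names(cov_eff)) {
        path <- as.vector(scale(cumsum(rnorm(n))))
        out[[nm]] <- path
        out$value <- out$value + cov_eff[[nm]] * path
      }
    }
    if (config$noise_sd > 0) {
      rho <- config$ar1_rho
      e <- numeric(n)
      e[1] <- rnorm(1, sd = config$noise_sd / sqrt(1 - rho^2))
      if (n > 1) {
        innov <- rnorm(n - 1, sd = config$noise_sd)
        for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
      }
      out$value <- out$value + e
    }
  })
  out
}

#' Simulate an expert rating matrix
#'
#' Each rater's score for an item is
#' `clip(round(true_impact + bias_r + noise), 0, 10)` with a per-rater bias
#' `bias_r ~ N(0, rater_bias_sd^2)` shared across items and independent
#' item-level noise `N(0, rater_sd^2)` -- the integer 0-10 scale of a
#' nominal-group-technique rating exercise. Deterministic given the seed.
#'
#' @param true_impacts Numeric vector of true item impacts in `[0, 10]`.
#' @param n_raters Number of raters (>= 2). Default 5.
#' @param rater_sd Item-level rating noise SD. Default 1.
#' @param rater_bias_sd Between-rater bias SD. Default 0.5.
#' @param seed Integer seed (ratings stream).
#' @param event_ids Optional item identifiers (default `E1..En`).
#' @return A rating tibble: `event_id`, one integer column per rater
#'   (`rater_1`, ...).
#' @export
simulate_ratings <- function(true_impacts, n_raters = 5, rater_sd = 1,
                             rater_bias_sd = 0.5, seed = 1,
                             event_ids = NULL) {
  if (any(true_impacts < 0 | true_impacts > 10)) {
    abort("true_impacts must lie in [0, 10]")
  }
  if (n_raters < 2) abort("need at least 2 raters")
  n <- length(true_impacts)
  out <- tibble(event_id = event_ids %||% paste0("E", seq_len(n)))
  with_stream_seed(seed, "ratings", {
    bias <- rnorm(n_raters, sd = rater_bias_sd)
    for (r in seq_len(n_raters)) {
      raw <- true_impacts + bias[r] + rnorm(n, sd = rater_sd)
      out[[paste0("rater_", r)]] <- pmin(pmax(round(raw), 0), 10)
    }
  })
  out
}
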