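# Interrupted time-series estimation. The outcome (e.g. monthly per-capita
# alcohol consumption or deaths) is regressed on a linear trend,
# month-of-year indicators, optional economic covariates, and one column per
# intervention: a 0/1 step for abrupt effects or a linear 0->1 ramp over
# `lag_months` for lagged effects. Serial correlation is handled by an
# AR(1) Cochrane-Orcutt-style iteration.

#' Specify interventions for an interrupted time-series model
#'
#' @param date Enactment month(s) (`Date` or `"YYYY-MM"`).
#' @param shape `"abrupt"` (step from the enactment month) or `"lagged"`
#'   (linear ramp reaching the full effect after `lag_months`).
#' @param lag_months Ramp length in months; required (>= 1) when
#'   `shape = "lagged"`.
#' @param name Optional term labels; default `eff_YYYY_MM`.
#' @return A tibble with columns `name`, `date`, `shape`, `lag_months`.
#' @examples
#' intervention_spec(c("2008-01", "2017-03"), shape = "abrupt")
#' @export
intervention_spec <- function(date, shape = "abrupt", lag_months = NA_integer_,
                              name = NULL) {
  date <- as_month(date)
  spec <- tibble(date = date, shape = shape,
                 lag_months = as.integer(lag_months))
  if (!all(spec$shape %in% c("abrupt", "lagged"))) {
    abort("shape must be 'abrupt' or 'lagged'")
  }
  lagged <- spec$shape == "lagged"
  if (any(lagged & (is.na(spec$lag_months) | spec$lag_months < 1))) {
    abort("lag_months >= 1 required for lagged interventions")
  }
  spec$name <- name %||% paste0("eff_", format(spec$date, "%Y_%m"))
  spec[c("name", "date", "shape", "lag_months")]
}

#' Check a series and interventions against design power requirements
#'
#' Counts, for every intervention, the months before and after its
#' enactment and compares them with the window's minimums; also flags a
#' total series length outside the commonly advised 50-100 time points.
#'
#' @param series A monthly series tibble with a `month` column
#'   (consecutive calendar months) and a `value` column.
#' @param specs An [intervention_spec()] tibble.
#' @param window A [study_window()] carrying `min_pre`/`min_post`; defaults
#'   to the series' own range with 24/24.
#' @return A list with `interventions` (tibble: `name`, `pre`, `post`,
#'   `pass_pre`, `pass_post`, `pass`), `n`, `total_advisory` (string or
#'   `NA`).
#' @export
check_design <- function(series, specs, window = NULL) {
  months <- as_month(series$month)
  if (is.null(window)) {
    window <- study_window(months[1], months[length(months)])
  }
  n <- length(months)
  res <- specs |>
    mutate(
      pre = month_index(.data$date) - month_index(months[1]),
      post = month_index(months[n]) - month_index(.data$date) + 1L,
      pass_pre = .data$pre >= window$min_pre,
      pass_post = .data$post >= window$min_post,
      pass = .data$pass_pre & .data$pass_post
    ) |>
    select("name", "date", "pre", "post", "pass_pre", "pass_post", "pass")
  advisory <- if (n < window$recommended_total[1]) {
    sprintf("series has %d time points, below the advised minimum of %d",
            n, window$recommended_total[1])
  } else {
    NA_character_
  }
  list(interventions = res, n = n, total_advisory = advisory)
}

#' Build the segmented-regression design matrix
#'
#' Columns: intercept, linear time (1..n), 11 month-of-year indicators
#' (December as reference), one column per covariate, and one effect column
#' per intervention (0/1 step, or linear ramp `1/lag ... 1` starting at the
#' enactment month for lagged shapes).
#'
#' @inheritParams check_design
#' @param covariates Character vector of covariate column names in
#'   `series`; default every numeric column except `value`.
#' @return A numeric matrix with `n` rows, full column rank enforced.
#' @export
build_design_matrix <- function(series, specs,
                                covariates = setdiff(
                                  names(series)[vapply(series, is.numeric,
                                                       logical(1))],
                                  "value"
                                )) {
  months <- as_month(series$month)
  n <- length(months)
  if (any(diff(month_index(months)) != 1)) {
    abort("series months must be consecutive")
  }
  moy <- as.integer(format(months, "%m"))
  season <- vapply(1:11, function(mm) as.numeric(moy == mm), numeric(n))
  colnames(season) <- sprintf("month_%02d", 1:11)

  eff <- vapply(seq_len(nrow(specs)), function(i) {
    k <- month_index(specs$date[i]) - month_index(months[1]) + 1L
    col <- numeric(n)
    if (specs$shape[i] == "abrupt" || specs$lag_months[i] == 1L) {
      if (k <= n) col[max(k, 1):n] <- 1
    } else {
      lag <- specs$lag_months[i]
      idx <- seq_len(n)
      col <- pmin(pmax((idx - k + 1) / lag, 0), 1)
    }
    col
  }, numeric(n))
  colnames(eff) <- specs$name

  X <- cbind(`(Intercept)` = 1, time = seq_len(n), season)
  for (cv in covariates) X <- cbind(X, setNames(list(series[[cv]]), cv)[[1]])
  if (length(covariates)) {
    colnames(X)[(ncol(X) - length(covariates) + 1):ncol(X)] <- covariates
  }
  X <- cbind(X, eff)
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient (collinear columns)")
  }
  X
}

#' Fit a segmented interrupted time-series regression
#'
#' Ordinary least squares of the outcome on the [build_design_matrix()]
#' design; when `ar1 = TRUE`, residual AR(1) correlation is removed by an
#' iterative quasi-differencing scheme (estimate the lag-1 residual
#' autocorrelation, transform outcome and design, refit, repeat until the
#' estimate changes by less than `tol`). Effect estimates, standard errors,
#' and t-based confidence intervals are reported on the original outcome
#' scale.
#'
#' @inheritParams build_design_matrix
#' @param ar1 Apply the AR(1) correction. Default `TRUE`.
#' @param conf_level Confidence level for intervals, default 0.95.
#' @param tol Convergence tolerance on the AR(1) coefficient, default 1e-6.
#' @param max_iter Maximum quasi-differencing iterations, default 50.
#' @return An object of class `its_fit`; see [tidy.its_fit()] and
#'   [glance.its_fit()].
#' @examples
#' cfg <- simulation_config(
#'   months = month_seq("2000-01", "2019-12"), seed = 1,
#'   interventions = tibble::tibble(date = as.Date("2008-01-01"),
#'     shape = "abrupt", true_effect = -0.8, lag_months = NA_integer_)
#' )
#' s <- simulate_outcome(cfg)
#' fit <- fit_its(s, intervention_spec("2008-01"))
#' tidy(fit)
#' @export
fit_its <- function(series, specs, ar1 = TRUE, conf_level = 0.95,
                    tol = 1e-6, max_iter = 50) {
  y <- series$value
  if (anyNA(y) || any(!is.finite(y))) abort("outcome values must be finite")
  X <- build_design_matrix(series, specs)
  n <- length(y)

  ols <- function(yy, XX) {
    fit <- lm(yy ~ XX - 1)
    names(fit$coefficients) <- colnames(XX)
    fit
  }

  fit <- ols(y, X)
  rho <- 0
  iters <- 0L
  converged <- TRUE
  if (ar1) {
    converged <- FALSE
    repeat {
      e <- y - as.vector(X %*% coef(fit))
      rho_new <- sum(e[-1] * e[-n]) / sum(e[-n]^2)
      iters <- iters + 1L
      y_t <- y[-1] - rho_new * y[-n]
      X_t <- X[-1, , drop = FALSE] - rho_new * X[-n, , drop = FALSE]
      fit <- ols(y_t, X_t)
      # coefficients map back to the original scale directly because the
      # whole design (intercept column included) is quasi-differenced
      if (abs(rho_new - rho) < tol) {
        rho <- rho_new
        converged <- TRUE
        break
      }
      rho <- rho_new
      if (iters >= max_iter) {
        warn("AR(1) iteration did not converge; returning last iterate")
        break
      }
    }
  }

  sm <- summary(fit)
  cf <- sm$coefficients
  df_res <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df_res)
  coefs <- tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std_error = cf[, 2],
    statistic = cf[, 3],
    p_value = cf[, 4],
    conf_low = cf[, 1] - tcrit * cf[, 2],
    conf_high = cf[, 1] + tcrit * cf[, 2]
  )

  resid_orig <- y - as.vector(X %*% coef(fit))
  white <- stats::residuals(fit)
  lag1 <- if (length(white) > 2 && sd(white) > 0) {
    sum((white[-1] - mean(white)) * (white[-length(white)] - mean(white))) /
      sum((white - mean(white))^2)
  } else {
    NA_real_
  }

  structure(
    list(coefficients = coefs, effects = dplyr::filter(coefs,
                                                       .data$term %in% specs$name),
         specs = specs, rho = rho, iterations = iters, converged = converged,
         ar1 = ar1, n = n, df_residual = df_res, sigma = sm$sigma,
         r_squared = sm$r.squared, resid_lag1 = lag1,
         fitted = as.vector(X %*% coef(fit)), residuals = resid_orig,
         series = tibble(month = as_month(series$month), value = y),
         conf_level = conf_level),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf(
    "Interrupted time-series fit: n = %d, AR(1) rho = %.3f (%s, %d iteration%s)\n",
    x$n, x$rho, if (x$converged) "converged" else "NOT converged",
    x$iterations, if (x$iterations == 1) "" else "s"
  ))
  cat("Intervention effects:\n")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy an interrupted time-series fit
#'
#' @param x An `its_fit`.
#' @param effects_only Return only the intervention-effect terms. Default
#'   `FALSE`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @exportS3Method generics::tidy
tidy.its_fit <- function(x, effects_only = FALSE, ...) {
  if (effects_only) x$effects else x$coefficients
}

#' One-row summary of an interrupted time-series fit
#'
#' @param x An `its_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `rho`, `iterations`, `converged`,
#'   `sigma`, `r_squared`, `resid_lag1`, `df_residual`.
#' @exportS3Method generics::glance
glance.its_fit <- function(x, ...) {
  tibble(n = x$n, rho = x$rho, iterations = x$iterations,
         converged = x$converged, sigma = x$sigma, r_squared = x$r_squared,
         resid_lag1 = x$resid_lag1, df_residual = x$df_residual)
}

#' @exportS3Method ggplot2::autoplot
autoplot.its_fit <- function(object, ...) {
  d <- object$series
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$specs$date, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Outcome",
                  subtitle = "Observed (grey) and fitted (red); dashed lines mark interventions") +
    ggplot2::theme_minimal()
}
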