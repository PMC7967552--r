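# Expert-rating sensitivity machinery. Ratings come from a modified nominal
# group technique: each expert independently scores every policy measure 0-10
# for its predicted immediate impact on consumption and health. A rating
# table holds one row per rated item (an event or an event/measure pair) with
# item metadata in non-numeric-prefixed columns and one numeric column per
# rater.

#' Extract the numeric rater matrix from a rating table
#'
#' @param ratings A data frame with one row per rated item; every numeric
#'   column except `measure_no` is treated as a rater.
#' @param allow_missing Allow missing cells (default `FALSE`).
#' @return A numeric matrix, items x raters, rater names as colnames.
#' @export
rating_values <- function(ratings, allow_missing = FALSE) {
  meta <- c("event_id", "measure_no", "date", "description")
  rater_cols <- setdiff(names(ratings)[vapply(ratings, is.numeric, logical(1))],
                        meta)
  if (length(rater_cols) < 2) abort("need at least 2 rater columns")
  if (nrow(ratings) < 2) abort("need at least 2 rated items")
  m <- as.matrix(ratings[rater_cols])
  if (!allow_missing && anyNA(m)) {
    abort("rating matrix has missing cells (set allow_missing = TRUE)")
  }
  if (any(m < 0 | m > 10, na.rm = TRUE)) abort("ratings must lie in [0, 10]")
  rownames(m) <- NULL
  m
}

#' Per-item mean expert ratings
#'
#' Arithmetic mean over raters for each rated item. With
#' `allow_missing = TRUE` the mean is taken over available raters and the
#' affected items flagged.
#'
#' @inheritParams rating_values
#' @return The item metadata columns of `ratings` plus `mean_rating`,
#'   `n_raters`, and `incomplete`.
#' @export
mean_ratings <- function(ratings, allow_missing = FALSE) {
  m <- rating_values(ratings, allow_missing = allow_missing)
  meta_cols <- setdiff(names(ratings), colnames(m))
  out <- as_tibble(ratings[meta_cols])
  out$mean_rating <- rowMeans(m, na.rm = TRUE)
  out$n_raters <- rowSums(!is.na(m))
  out$incomplete <- out$n_raters < ncol(m)
  out
}

#' Select enactment dates by expert consensus
#'
#' A date is selected as important for modeling if at least one item rated
#' at that date has a mean rating at or above `threshold` (inclusive).
#' Items are mapped to dates through `events` by `event_id`.
#'
#' @inheritParams rating_values
#' @param events A timeline tibble ([read_timeline()]) providing the
#'   `event_id` to `date` mapping.
#' @param threshold Mean-rating cutoff, default 5.
#' @return A sorted `Date` vector of selected enactment dates.
#' @export
select_dates <- function(ratings, events, threshold = 5,
                         allow_missing = FALSE) {
  means <- mean_ratings(ratings, allow_missing = allow_missing)
  if (!("event_id" %in% names(means))) {
    abort("ratings must carry an event_id column")
  }
  dates <- distinct(as_tibble(events), .data$event_id, .data$date)
  unknown <- setdiff(means$event_id, dates$event_id)
  if (length(unknown) > 0) {
    abort(paste0("rated item references unknown event: ",
                 paste(unknown, collapse = ", ")))
  }
  means |>
    left_join(dates, by = "event_id") |>
    group_by(.data$date) |>
    summarise(top = max(.data$mean_rating), .groups = "drop") |>
    dplyr::filter(.data$top >= threshold) |>
    pull(.data$date) |>
    sort()
}

#' Intraclass correlation coefficient for interrater reliability
#'
#' Single-rater, absolute-agreement ICC under the two-way random-effects
#' model -- commonly written ICC(2,1) -- computed from the two-way ANOVA
#' mean squares (items, raters, residual), with the standard F-based
#' confidence interval. The variant is the usual default when interrater
#' reliability of a fully crossed rating design is reported.
#'
#' @inheritParams rating_values
#' @param confidence Confidence level for the interval, default 0.95.
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `n_items`,
#'   `n_raters`, `variant`.
#' @examples
#' r <- simulate_ratings(c(2, 5, 8, 3, 9, 6), n_raters = 4, rater_sd = 1,
#'                       rater_bias_sd = 0.5, seed = 1)
#' icc(r)
#' @export
icc <- function(ratings, confidence = 0.95) {
  m <- rating_values(ratings)
  n <- nrow(m) # items
  k <- ncol(m) # raters
  if (var(as.vector(m)) == 0) abort("degenerate matrix: zero total variance")

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols

  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based interval for ICC(A,1) (McGraw & Wong)
  alpha <- 1 - confidence
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  # perfect agreement collapses the F interval; report a point interval
  if (!is.finite(lower)) lower <- est
  if (!is.finite(upper)) upper <- est

  tibble(icc = est, ci_low = lower, ci_high = upper,
         n_items = n, n_raters = k, variant = "ICC(2,1) absolute agreement")
}

#' Pairwise Spearman agreement between raters
#'
#' Spearman rank correlation (average ranks for ties) for every unordered
#' rater pair, summarised by the median and interquartile range of the pair
#' distribution. Pairs involving a rater with constant ratings have an
#' undefined correlation; they are dropped and flagged.
#'
#' @inheritParams rating_values
#' @return A list with `pairs` (tibble: `rater1`, `rater2`, `rho`),
#'   `median`, `iqr`, and `dropped_pairs`.
#' @export
spearman_summary <- function(ratings) {
  m <- rating_values(ratings)
  k <- ncol(m)
  raters <- colnames(m) %||% paste0("R", seq_len(k))
  combos <- utils::combn(k, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    i1 <- combos[1, j]; i2 <- combos[2, j]
    rho <- if (var(m[, i1]) == 0 || var(m[, i2]) == 0) {
      NA_real_
    } else {
      cor(m[, i1], m[, i2], method = "spearman")
    }
    tibble(rater1 = raters[i1], rater2 = raters[i2], rho = rho)
  })
  valid <- pairs$rho[!is.na(pairs$rho)]
  list(
    pairs = pairs,
    median = if (length(valid)) median(valid) else NA_real_,
    iqr = if (length(valid)) unname(diff(quantile(valid, c(0.25, 0.75)))) else NA_real_,
    dropped_pairs = sum(is.na(pairs$rho))
  )
}

#' Concordance between expert-selected and criteria-selected dates
#'
#' Partitions enactment dates into those selected by both the expert panel
#' and the objective tier criteria, by the experts only, and by the
#' criteria only. The experts are a superset of the objective selection
#' when `criteria_only` is empty.
#'
#' @param expert_dates Dates selected by [select_dates()].
#' @param tier_assignments Output of [classify_tiers()]; the
#'   criteria-selected dates are the Tier-1 and Tier-2-only events.
#' @return A list with `in_both`, `expert_only`, `criteria_only` (`Date`
#'   vectors) and `expert_superset` (logical).
#' @export
rating_concordance <- function(expert_dates, tier_assignments) {
  expert_dates <- sort(as.Date(expert_dates))
  criteria <- tier_assignments |>
    dplyr::filter(.data$tier %in% c("tier1", "tier2_only")) |>
    pull(.data$date) |>
    sort()
  list(
    in_both = sort(as.Date(intersect(expert_dates, criteria),
                           origin = "1970-01-01")),
    expert_only = sort(as.Date(setdiff(expert_dates, criteria),
                               origin = "1970-01-01")),
    criteria_only = sort(as.Date(setdiff(criteria, expert_dates),
                                 origin = "1970-01-01")),
    expert_superset = length(setdiff(criteria, expert_dates)) == 0
  )
}
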