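# Objective tier classification. An event is scored only if it is aimed at
# the general population, is not a liberalization, and leaves enough monthly
# observations on both sides of its enactment for an interrupted
# time-series analysis. Among the remaining events:
#   Tier 1  - restrictive general taxation/price coinciding with an
#             affordability decrease in the enactment year, or a major
#             (daily-hours) general availability restriction;
#   Tier 2  - restrictive general taxation/price with sub-threshold
#             affordability growth, or a day/night-limited availability
#             restriction. Every Tier-1 event also satisfies a Tier-2
#             criterion (reported in `tier2_qualified`).

#' Define a monthly study window
#'
#' The evaluation window and the minimum number of monthly observations
#' required before and after an enactment for it to be analyzable by
#' interrupted time-series methods (at least 24 on each side by default,
#' with 50-100 total time points advisable).
#'
#' @param start,end First and last month of the window (`Date` or
#'   `"YYYY-MM"`).
#' @param min_pre,min_post Minimum months strictly before / from the
#'   enactment month on (inclusive). Defaults 24 and 24.
#' @return A list of class `study_window`.
#' @examples
#' study_window("2000-01", "2019-12")
#' @export
study_window <- function(start, end, min_pre = 24, min_post = 24) {
  start <- as_month(start)
  end <- as_month(end)
  if (start >= end) abort("window start must precede end")
  if (min_pre < 1 || min_post < 1) abort("min_pre and min_post must be >= 1")
  structure(
    list(start = start, end = end,
         min_pre = as.integer(min_pre), min_post = as.integer(min_post),
         recommended_total = c(50L, 100L)),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf(
    "Study window %s .. %s (%d months; >=%d pre / >=%d post required)\n",
    format(x$start, "%Y-%m"), format(x$end, "%Y-%m"),
    months_spanned(x$start, x$end), x$min_pre, x$min_post
  ))
  invisible(x)
}

#' Check an enactment date's eligibility within a study window
#'
#' An enactment is eligible when the window holds at least `min_pre` months
#' strictly before the enactment month and at least `min_post` months from
#' the enactment month (inclusive) to the window end.
#'
#' @param date Enactment date(s).
#' @param window A [study_window()].
#' @return A tibble with columns `date`, `pre_months`, `post_months`,
#'   `eligible`, `reason` (`NA`, `"insufficient_pre"`,
#'   `"insufficient_post"`, or `"out_of_window"`).
#' @examples
#' w <- study_window("2000-01", "2019-12")
#' check_eligibility(as.Date("2001-06-01"), w) # 17 pre-months: ineligible
#' @export
check_eligibility <- function(date, window) {
  m <- as_month(date)
  pre <- month_index(m) - month_index(window$start)
  post <- month_index(window$end) - month_index(m) + 1L
  out_of_window <- m < window$start | m > window$end
  eligible <- !out_of_window & pre >= window$min_pre & post >= window$min_post
  reason <- dplyr::case_when(
    out_of_window ~ "out_of_window",
    pre < window$min_pre ~ "insufficient_pre",
    post < window$min_post ~ "insufficient_post",
    TRUE ~ NA_character_
  )
  tibble(date = as.Date(m), pre_months = pre, post_months = post,
         eligible = eligible, reason = reason)
}

#' Classify policy events into impact tiers
#'
#' Applies the objective criteria to each event of a timeline:
#'
#' 1. Events whose measures all target a specific population are set aside
#'    as `specific` (they are tested against group-specific outcomes, not
#'    scored for the general-population evaluation).
#' 2. Events containing a liberalizing measure and no qualifying restrictive
#'    measure are `excluded` (`liberalizing`): expected to *increase* harm,
#'    they are left unscored.
#' 3. Events failing the study-window power requirement are `excluded`
#'    (`window_ineligible`).
#' 4. Otherwise, Tier-1 / Tier-2 criteria are evaluated over the event's
#'    restrictive general-population measures; taxation measures are tested
#'    against the affordability change of the enactment calendar year
#'    (annual economic data). Delayed-only bundles (e.g. an advertising ban
#'    alone) never qualify. Events matching nothing are `excluded`
#'    (`no_criterion`).
#'
#' @param timeline A validated timeline tibble ([read_timeline()]).
#' @param econ An annual economic index series
#'   ([validate_economic_series()]); required only for restrictive
#'   general-population taxation measures at eligible dates.
#' @param window A [study_window()].
#' @param threshold Affordability-growth threshold (percent) below which a
#'   tax rise still qualifies for Tier 2. Default 5.
#' @return A tibble, one row per event: `event_id`, `date`, `tier` (factor
#'   `tier1`, `tier2_only`, `specific`, `excluded`), `criteria_fired`
#'   (comma-separated), `affordability_change_used` (percent or `NA`),
#'   `tier2_qualified`, `weight` (1 for Tier 1, 0.5 for Tier 2 only, 0
#'   otherwise).
#' @examples
#' tiers <- classify_tiers(lithuania_timeline(), lithuania_economy(),
#'                         study_window("2000-01", "2019-12"))
#' dplyr::filter(tiers, tier == "tier1")$date
#' @export
classify_tiers <- function(timeline, econ, window, threshold = 5) {
  tl <- validate_timeline(timeline)
  econ <- validate_economic_series(econ, base_year = attr(econ, "base_year") %||% 2010)
  if (nrow(tl) == 0) return(empty_assignments())

  events <- tl |>
    tidyr::nest(measures = -c("event_id", "date")) |>
    arrange(.data$date)

  rows <- purrr::pmap(events, function(event_id, date, measures) {
    classify_one(event_id, date, measures, econ, window, threshold)
  })
  out <- bind_rows(rows)
  out$tier <- factor(out$tier, levels = c("tier1", "tier2_only", "specific",
                                          "excluded"))
  out$weight <- dplyr::case_when(out$tier == "tier1" ~ 1,
                                 out$tier == "tier2_only" ~ 0.5,
                                 TRUE ~ 0)
  out
}

classify_one <- function(event_id, date, measures, econ, window, threshold) {
  elig <- check_eligibility(date, window)
  year <- as.integer(format(as.Date(date), "%Y"))

  result <- function(tier, criteria, change = NA_real_, tier2 = FALSE) {
    tibble(event_id = event_id, date = as.Date(date), tier = tier,
           criteria_fired = paste(criteria, collapse = ","),
           affordability_change_used = change, tier2_qualified = tier2)
  }

  if (all(measures$population == "specific")) {
    crit <- "specific_population"
    if (!elig$eligible) crit <- c(crit, "window_ineligible")
    return(result("specific", crit))
  }

  # criteria over restrictive, general-population, non-delayed measures
  gm <- dplyr::filter(measures, .data$direction == "restrictive",
                      .data$population == "general",
                      .data$immediacy == "immediate")
  crit <- character()
  change <- NA_real_
  if (elig$eligible && nrow(gm) > 0) {
    if (any(gm$domain == "taxation_price")) {
      if (!(year %in% econ$year) || !((year - 1) %in% econ$year)) {
        abort(sprintf(
          "no affordability data for year %d (taxation measure in event %s)",
          year, event_id
        ))
      }
      change <- affordability_change(econ, year)
      cat_ <- as.character(categorize_change(change, threshold = threshold))
      if (cat_ == "decrease") crit <- c(crit, "affordability_decrease")
      if (cat_ == "small_increase") crit <- c(crit, "affordability_small_increase")
    }
    if (any(gm$domain == "availability" & gm$availability_scope == "daily_hours")) {
      crit <- c(crit, "availability_major")
    }
    if (any(gm$domain == "availability" &
              gm$availability_scope == "specific_days_or_night")) {
      crit <- c(crit, "availability_minor")
    }
  }
  tier1_crit <- intersect(crit, c("affordability_decrease", "availability_major"))
  tier2_crit <- intersect(crit, c("affordability_small_increase",
                                  "availability_minor"))
  # Tier-2 qualification in the inclusive sense: any affordability change
  # below the threshold (decreases included) or any qualifying availability
  # restriction, so Tier 1 is always a subset of the Tier-2-qualified set.
  tier2_qualified <- length(tier2_crit) > 0 ||
    (!is.na(change) && change < threshold) ||
    "availability_major" %in% crit

  qualifies <- length(tier1_crit) > 0 || length(tier2_crit) > 0

  if (any(measures$direction == "liberalizing") && !qualifies) {
    return(result("excluded", "liberalizing"))
  }
  if (!elig$eligible) {
    return(result("excluded", "window_ineligible"))
  }
  if (length(tier1_crit) > 0) {
    return(result("tier1", crit, change, tier2 = tier2_qualified))
  }
  if (length(tier2_crit) > 0) {
    return(result("tier2_only", crit, change, tier2 = TRUE))
  }
  result("excluded", "no_criterion", change)
}

empty_assignments <- function() {
  tibble(event_id = character(), date = as.Date(character()),
         tier = factor(character(),
                       levels = c("tier1", "tier2_only", "specific", "excluded")),
         criteria_fired = character(),
         affordability_change_used = numeric(),
         tier2_qualified = logical(), weight = numeric())
}

#' Cumulative policy-score step series
#'
#' Sums tier weights over time on the window's monthly grid: each scored
#' event adds its weight (1 for Tier 1, 0.5 for Tier 2 only) from its
#' enactment month onward (the enactment month itself included; mid-month
#' enactments take effect that calendar month).
#'
#' @param assignments Output of [classify_tiers()].
#' @param window A [study_window()].
#' @param weights Named list of tier weights. Default
#'   `list(tier1 = 1, tier2_only = 0.5)`.
#' @return A tibble of class `score_series` with columns `month` (`Date`,
#'   first of month) and `score`.
#' @examples
#' w <- study_window("2000-01", "2019-12")
#' tiers <- classify_tiers(lithuania_timeline(), lithuania_economy(), w)
#' sc <- cumulative_score(tiers, w)
#' sc[sc$month == as.Date("2019-12-01"), ] # score 4
#' @export
cumulative_score <- function(assignments, window,
                             weights = list(tier1 = 1, tier2_only = 0.5)) {
  grid <- month_seq(window$start, window$end)
  scored <- assignments |>
    dplyr::filter(.data$tier %in% c("tier1", "tier2_only")) |>
    mutate(
      w = dplyr::if_else(.data$tier == "tier1",
                         weights$tier1, weights$tier2_only),
      month = as_month(.data$date)
    )
  score <- vapply(grid, function(m) {
    sum(scored$w[scored$month <= m])
  }, numeric(1))
  out <- tibble(month = grid, score = score)
  class(out) <- c("score_series", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.score_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$month, y = .data$score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = NULL, y = "Cumulative policy score") +
    ggplot2::theme_minimal()
}
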