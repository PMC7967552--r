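# Affordability of alcohol: disposable income index / alcohol price index.
# The year-over-year proportional change in this ratio drives the taxation
# criteria of the tier classifier: a tax rise qualifies as high-impact only
# if affordability actually fell in the enactment year.

#' Read an annual economic index series
#'
#' Reads a CSV with columns `year`, `income_index`, `price_index` (both
#' unitless indices, base year = 100) and validates it.
#'
#' @param path Path to a CSV file.
#' @param base_year Base year of the indices; if present in the data its two
#'   components must equal 100 (within 0.05). Default 2010.
#' @return A tibble with columns `year`, `income_index`, `price_index`, with
#'   attribute `base_year`.
#' @seealso [lithuania_economy()] for the bundled Lithuanian series.
#' @export
read_economic_series <- function(path, base_year = 2010) {
  ec <- readr::read_csv(path, show_col_types = FALSE)
  validate_economic_series(ec, base_year = base_year)
}

#' Validate an annual economic index series
#'
#' Checks the invariants required downstream: columns `year`,
#' `income_index`, `price_index`; strictly increasing consecutive years;
#' strictly positive indices; base-year components equal to 100 when the
#' base year is in range.
#'
#' @param econ A data frame of annual indices.
#' @inheritParams read_economic_series
#' @return The validated series as a tibble (invisibly the same data).
#' @export
validate_economic_series <- function(econ, base_year = 2010) {
  need <- c("year", "income_index", "price_index")
  missing_cols <- setdiff(need, names(econ))
  if (length(missing_cols) > 0) {
    abort(paste0("economic series is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  econ <- as_tibble(econ)[need]
  if (nrow(econ) == 0) abort("no data: economic series is empty")
  if (anyNA(econ)) abort("economic series contains missing values")
  if (any(econ$income_index <= 0) || any(econ$price_index <= 0)) {
    abort("invalid index: income_index and price_index must be positive")
  }
  if (any(diff(econ$year) != 1)) {
    abort("years must be strictly increasing and consecutive (no gaps)")
  }
  if (base_year %in% econ$year) {
    base <- dplyr::filter(econ, .data$year == base_year)
    if (abs(base$income_index - 100) > 0.05 || abs(base$price_index - 100) > 0.05) {
      abort(sprintf("base year %d components must equal 100", base_year))
    }
  }
  attr(econ, "base_year") <- base_year
  econ
}

#' Affordability index levels and year-over-year changes
#'
#' Computes, for each year, the affordability index level
#' `100 * (income_index / price_index) / (income_base / price_base)` and the
#' proportional change versus the previous year (percent; positive means
#' alcohol became *more* affordable), then categorizes each change against
#' the classification threshold.
#'
#' The first year of a series has no change value (`NA`, never imputed 0).
#' Internally everything is kept at full precision; use
#' `round(change_pct, 1)` and `round(index_level)` to reproduce the usual
#' published rendering.
#'
#' @param econ A data frame of annual indices (see
#'   [validate_economic_series()]).
#' @param base_year Base year used to anchor the level at 100. Default 2010.
#' @param threshold Affordability-growth threshold (percent) separating
#'   small from large increases. Default 5.
#' @return A tibble with columns `year`, `index_level`, `change_pct`,
#'   `category` (factor: `decrease`, `small_increase`, `large_increase`).
#' @examples
#' econ <- lithuania_economy()
#' affordability_index(econ)
#' @export
affordability_index <- function(econ, base_year = 2010, threshold = 5) {
  econ <- validate_economic_series(econ, base_year = base_year)
  ratio <- econ$income_index / econ$price_index
  base_ratio <- if (base_year %in% econ$year) {
    ratio[match(base_year, econ$year)]
  } else {
    1
  }
  tibble(
    year = econ$year,
    index_level = 100 * ratio / base_ratio,
    change_pct = 100 * (ratio / dplyr::lag(ratio) - 1)
  ) |>
    mutate(category = categorize_change(.data$change_pct, threshold = threshold))
}

#' Proportional affordability change for one year
#'
#' The percent change of the income/price ratio from `year - 1` to `year`:
#' `100 * ((I_y / P_y) - (I_{y-1} / P_{y-1})) / (I_{y-1} / P_{y-1})`.
#'
#' @inheritParams affordability_index
#' @param year Calendar year; both `year` and `year - 1` must be present.
#' @return A single numeric percent (unrounded).
#' @examples
#' affordability_change(lithuania_economy(), 2010) # -15.3
#' @export
affordability_change <- function(econ, year) {
  econ <- validate_economic_series(econ, base_year = attr(econ, "base_year") %||% 2010)
  if (!(year %in% econ$year)) abort(sprintf("year %d not in series", year))
  if (!((year - 1) %in% econ$year)) {
    abort(sprintf("no prior year: %d not in series", year - 1))
  }
  r <- function(y) {
    i <- match(y, econ$year)
    econ$income_index[i] / econ$price_index[i]
  }
  100 * (r(year) / r(year - 1) - 1)
}

#' Categorize an affordability change
#'
#' Maps a percent change to `decrease` (`< 0`), `small_increase`
#' (`[0, threshold)`), or `large_increase` (`>= threshold`). The comparison
#' always uses the unrounded value, so published one-decimal renderings
#' never create spurious boundary ties.
#'
#' @param change_pct Numeric vector of percent changes (`NA` allowed, kept).
#' @param threshold Threshold percent, default 5.
#' @return A factor with levels `decrease`, `small_increase`,
#'   `large_increase`.
#' @export
categorize_change <- function(change_pct, threshold = 5) {
  if (any(is.infinite(change_pct) | is.nan(change_pct))) {
    abort("change_pct must be finite")
  }
  out <- dplyr::case_when(
    is.na(change_pct) ~ NA_character_,
    change_pct < 0 ~ "decrease",
    change_pct < threshold ~ "small_increase",
    TRUE ~ "large_increase"
  )
  factor(out, levels = c("decrease", "small_increase", "large_increase"))
}

#' Bundled Lithuanian economic index series (2007-2019)
#'
#' Annual average disposable income per household member and alcohol price
#' indices for Lithuania, both base 2010 = 100, as published by the national
#' statistics office. Note that recomputing one-decimal affordability
#' changes from these two published (already rounded) component columns
#' reproduces the nationally published changes for most years but differs by
#' 0.1 percentage points in 2008, 2015, 2016, and 2018, where the original
#' computation evidently used unrounded source series. No tier assignment is
#' sensitive to these 0.1-point differences.
#'
#' @return A validated tibble: `year`, `income_index`, `price_index`.
#' @export
lithuania_economy <- function() {
  read_economic_series(
    system.file("extdata", "lithuania_economy.csv", package = "alcpolicy",
                mustWork = TRUE),
    base_year = 2010
  )
}

#' Plot affordability changes
#'
#' Bar chart of year-over-year affordability changes, colored by category,
#' with the classification threshold drawn as a dashed line.
#'
#' @param econ A data frame of annual indices.
#' @inheritParams affordability_index
#' @return A ggplot object.
#' @export
plot_affordability <- function(econ, base_year = 2010, threshold = 5) {
  aff <- affordability_index(econ, base_year = base_year, threshold = threshold)
  aff <- dplyr::filter(aff, !is.na(.data$change_pct))
  ggplot2::ggplot(aff, ggplot2::aes(x = .data$year, y = .data$change_pct,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0, threshold), linetype = "dashed") +
    ggplot2::labs(x = "Year", y = "Affordability change (%)",
                  fill = "Category") +
    ggplot2::theme_minimal()
}
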