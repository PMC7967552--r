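# Policy timeline: one row per measure, events grouped by event_id + date.
# Table layout ("flat CSV dialect"): event_id, date, measure_no, domain,
# direction, population, specific_group, availability_scope, immediacy,
# description. The nested JSON dialect groups measures under events.

.domains <- c("taxation_price", "availability", "marketing_advertising",
              "drink_driving", "other")
.directions <- c("restrictive", "liberalizing", "neutral")
.populations <- c("general", "specific")
.avail_scopes <- c("daily_hours", "specific_days_or_night", "outlet_type",
                   "production_licensing", "none")
.immediacies <- c("immediate", "delayed")

timeline_cols <- c("event_id", "date", "measure_no", "domain", "direction",
                   "population", "specific_group", "availability_scope",
                   "immediacy", "description")

#' Validate a policy timeline
#'
#' Checks the measure-level attribute vocabulary and the structural
#' invariants of a timeline: every measure has a known `domain`,
#' `direction`, `population`, `availability_scope` and `immediacy`;
#' `availability_scope` differs from `"none"` exactly when the domain is
#' `availability`; `specific_group` is non-empty exactly when `population`
#' is `specific`; each event has at least one measure; enactment dates are
#' unique per event.
#'
#' @param timeline A data frame with one row per policy measure (see
#'   [read_timeline()] for the column layout).
#' @return The validated timeline as a tibble, sorted by `date` then
#'   `measure_no`.
#' @export
validate_timeline <- function(timeline) {
  tl <- as_tibble(timeline)
  missing_cols <- setdiff(timeline_cols, names(tl))
  if (length(missing_cols) > 0) {
    abort(paste0("timeline is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tl <- tl[timeline_cols]
  if (nrow(tl) == 0) return(tl)
  tl$date <- as.Date(tl$date)
  tl$specific_group <- dplyr::coalesce(as.character(tl$specific_group), "")
  tl$description <- dplyr::coalesce(as.character(tl$description), "")

  check_vocab <- function(col, vocab) {
    bad <- which(!(tl[[col]] %in% vocab))
    if (length(bad) > 0) {
      abort(sprintf("row %d: invalid %s value '%s'", bad[1], col,
                    tl[[col]][bad[1]]))
    }
  }
  check_vocab("domain", .domains)
  check_vocab("direction", .directions)
  check_vocab("population", .populations)
  check_vocab("availability_scope", .avail_scopes)
  check_vocab("immediacy", .immediacies)

  bad_scope <- which((tl$domain == "availability") !=
                       (tl$availability_scope != "none"))
  if (length(bad_scope) > 0) {
    abort(sprintf(
      "row %d: availability_scope must be set iff domain is availability",
      bad_scope[1]
    ))
  }
  bad_group <- which((tl$population == "specific") !=
                       (nzchar(tl$specific_group)))
  if (length(bad_group) > 0) {
    abort(sprintf(
      "row %d: specific_group must be non-empty iff population is specific",
      bad_group[1]
    ))
  }

  dates_per_event <- tl |>
    distinct(.data$event_id, .data$date) |>
    dplyr::count(.data$event_id)
  if (any(dates_per_event$n > 1)) {
    abort("each event_id must have a single enactment date")
  }
  events_per_date <- tl |>
    distinct(.data$event_id, .data$date) |>
    dplyr::count(.data$date)
  if (any(events_per_date$n > 1)) {
    abort("duplicate enactment date across events")
  }
  arrange(tl, .data$date, .data$measure_no)
}

#' Read a policy timeline from CSV or JSON
#'
#' Two dialects are supported and detected from the file extension: a flat
#' CSV with one measure per row (`event_id` repeated across an event's
#' measures) and a nested JSON array of events each holding a `measures`
#' array. Events are returned sorted by enactment date and validated (see
#' [validate_timeline()]).
#'
#' @param path Path to a `.csv` or `.json` timeline file.
#' @return A validated timeline tibble, one row per measure.
#' @examples
#' tl <- lithuania_timeline()
#' dplyr::n_distinct(tl$event_id) # 21 events
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) abort(sprintf("timeline file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    events <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(events) == 0 || is.null(nrow(events)) || nrow(events) == 0) {
      return(validate_timeline(empty_timeline()))
    }
    tl <- as_tibble(events) |>
      rename(date = "enactment_date") |>
      tidyr::unnest("measures")
  } else {
    tl <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            date = readr::col_date(),
                            measure_no = readr::col_integer(),
                            .default = readr::col_character()
                          ))
  }
  validate_timeline(tl)
}

#' Write a policy timeline
#'
#' Inverse of [read_timeline()]; the dialect follows the file extension.
#'
#' @param timeline A validated timeline tibble.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  tl <- validate_timeline(timeline)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    events <- tl |>
      tidyr::nest(measures = -c("event_id", "date")) |>
      rename(enactment_date = "date")
    jsonlite::write_json(events, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  } else {
    readr::write_csv(tl, path)
  }
  invisible(path)
}

empty_timeline <- function() {
  tibble(event_id = character(), date = as.Date(character()),
         measure_no = integer(), domain = character(),
         direction = character(), population = character(),
         specific_group = character(), availability_scope = character(),
         immediacy = character(), description = character())
}

#' Filter events by measure attributes
#'
#' Keeps the events (all their measures) for which **at least one** measure
#' matches every supplied attribute filter.
#'
#' @param timeline A validated timeline tibble.
#' @param direction,population,domain Optional attribute values to match.
#' @return The filtered timeline tibble.
#' @examples
#' tl <- lithuania_timeline()
#' # the liberalization-era events
#' unique(filter_events(tl, direction = "liberalizing")$date)
#' @export
filter_events <- function(timeline, direction = NULL, population = NULL,
                          domain = NULL) {
  tl <- as_tibble(timeline)
  if (nrow(tl) == 0) return(tl)
  check_value <- function(value, vocab, name) {
    if (!is.null(value) && !(value %in% vocab)) {
      abort(sprintf("unknown %s value '%s'", name, value))
    }
  }
  check_value(direction, .directions, "direction")
  check_value(population, .populations, "population")
  check_value(domain, .domains, "domain")

  hits <- tl
  if (!is.null(direction)) hits <- dplyr::filter(hits, .data$direction == !!direction)
  if (!is.null(population)) hits <- dplyr::filter(hits, .data$population == !!population)
  if (!is.null(domain)) hits <- dplyr::filter(hits, .data$domain == !!domain)
  semi_join(tl, distinct(hits, .data$event_id), by = "event_id")
}

#' Bundled Lithuanian policy timeline (2001-2019)
#'
#' The 21 major alcohol control policy events enacted in Lithuania between
#' June 2001 and November 2019, with each measure curated into the discrete
#' attribute system the classifier consumes (domain, direction, population,
#' availability scope, immediacy). Liberalization-era measures (2001-2004)
#' are coded `liberalizing`; the night off-premise sales restriction of
#' January 2009 is coded `availability`/`specific_days_or_night`; the
#' reduced daily sales hours of January 2018 `availability`/`daily_hours`;
#' the 2016 petrol-station sales ban targets a specific population segment,
#' following the published classification.
#'
#' @return A validated timeline tibble, one row per measure.
#' @export
lithuania_timeline <- function() {
  read_timeline(system.file("extdata", "lithuania_policies.csv",
                            package = "alcpolicy", mustWork = TRUE))
}
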