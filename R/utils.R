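# Calendar-month helpers. Months are represented as Date objects pinned to
# the first of the month; "YYYY-MM" strings are accepted everywhere.

#' Coerce to a first-of-month Date
#'
#' Accepts `Date` values or strings in `"YYYY-MM"` / `"YYYY-MM-DD"` form and
#' returns a `Date` snapped to the first day of its calendar month.
#'
#' @param x A `Date` vector or character vector.
#' @return A `Date` vector, day-of-month always 1.
#' @examples
#' as_month("2008-01")
#' as_month(as.Date("2017-03-15"))
#' @export
as_month <- function(x) {
  if (inherits(x, "Date")) {
    out <- x
  } else if (is.character(x)) {
    x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
    out <- as.Date(x)
  } else {
    abort("`x` must be a Date or character vector.")
  }
  if (anyNA(out)) abort("could not parse month values")
  as.Date(format(out, "%Y-%m-01"))
}

# zero-based month index since 0000-01 (stable arithmetic on months)
month_index <- function(m) {
  m <- as_month(m)
  as.integer(format(m, "%Y")) * 12L + (as.integer(format(m, "%m")) - 1L)
}

# number of calendar months from a to b inclusive
months_spanned <- function(a, b) month_index(b) - month_index(a) + 1L

#' Sequence of consecutive calendar months
#'
#' @param from,to Month bounds (inclusive), as `Date` or `"YYYY-MM"`.
#' @return A `Date` vector of first-of-month dates.
#' @export
month_seq <- function(from, to) {
  from <- as_month(from)
  to <- as_month(to)
  if (from > to) abort("`from` must not be after `to`")
  seq(from, to, by = "month")
}

# Deterministic child seeds: one root seed, named streams, fixed order, so
# adding a new generator never shifts the draws of an existing one.
.seed_streams <- c(economy = 11L, outcome = 23L, ratings = 37L, study = 53L)

child_seed <- function(seed, stream) {
  offset <- .seed_streams[[stream]]
  as.integer((as.numeric(seed) * 101 + as.numeric(offset) * 10007) %%
               2147483629)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, stream))
  force(code)
}
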