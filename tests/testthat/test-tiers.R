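test_that("window eligibility counts pre and post months on the calendar", {
  w <- lt_window()
  e1 <- check_eligibility(as.Date("2001-06-01"), w)
  expect_false(e1$eligible)
  expect_equal(e1$pre_months, 17)
  expect_equal(e1$reason, "insufficient_pre")

  e2 <- check_eligibility(as.Date("2019-03-01"), w)
  expect_false(e2$eligible)
  expect_equal(e2$post_months, 10)
  expect_equal(e2$reason, "insufficient_post")

  e3 <- check_eligibility(as.Date("2018-01-01"), w)
  expect_true(e3$eligible)
  expect_equal(e3$pre_months, 216)
  expect_equal(e3$post_months, 24)

  e4 <- check_eligibility(as.Date("1999-06-01"), w)
  expect_equal(e4$reason, "out_of_window")
})

test_that("the Lithuanian fixture classifies into the published tier sets", {
  tiers <- classify_tiers(lithuania_timeline(), lithuania_economy(),
                          lt_window())
  expect_setequal(format(tiers$date[tiers$tier == "tier1"]),
                  c("2008-01-01", "2017-03-01", "2018-01-01"))
  expect_setequal(format(tiers$date[tiers$tier == "tier2_only"]),
                  c("2009-01-01", "2014-04-01"))
  expect_setequal(format(tiers$date[tiers$tier == "specific"]),
                  c("2015-01-01", "2016-01-01", "2017-01-01", "2019-04-01"))

  crit <- function(d) tiers$criteria_fired[format(tiers$date) == d]
  expect_match(crit("2008-01-01"), "affordability_decrease")
  expect_match(crit("2018-01-01"), "availability_major")
  expect_match(crit("2009-01-01"), "affordability_small_increase")
  expect_match(crit("2009-01-01"), "availability_minor")
  expect_match(crit("2015-03-01"), "no_criterion")
  expect_match(crit("2001-06-01"), "window_ineligible")
  expect_match(crit("2002-07-01"), "liberalizing")
  # every Tier-1 event also satisfies a Tier-2 criterion
  expect_true(all(tiers$tier2_qualified[tiers$tier == "tier1"]))
  # liberalizing and specific-population events carry zero weight
  expect_true(all(tiers$weight[tiers$tier %in% c("specific", "excluded")] == 0))
})

test_that("classification is invariant to event order and to dropping excluded events", {
  tl <- lithuania_timeline()
  econ <- lithuania_economy()
  w <- lt_window()
  base <- classify_tiers(tl, econ, w)

  set.seed(1)
  shuffled <- tl[sample(nrow(tl)), ]
  expect_equal(classify_tiers(shuffled, econ, w), base)

  dropped <- dplyr::filter(tl, .data$event_id != "LT13") # an excluded event
  sub <- classify_tiers(dropped, econ, w)
  expect_equal(dplyr::filter(base, event_id != "LT13"), sub)
  expect_equal(cumulative_score(sub, w)$score,
               cumulative_score(base, w)$score)
})

test_that("relaxing the pre/post minimums only grows the eligible set", {
  tl <- lithuania_timeline()
  econ <- lithuania_economy()
  strict <- classify_tiers(tl, econ, lt_window())
  loose <- classify_tiers(tl, econ,
                          study_window("2000-01", "2019-12",
                                       min_pre = 24, min_post = 2))
  ineligible <- function(x) {
    x$event_id[grepl("window_ineligible", x$criteria_fired)]
  }
  expect_true(all(ineligible(loose) %in% ineligible(strict)))
  # June 2001 becomes scoreable once the pre-window requirement drops,
  # but still needs affordability data, hence errors on the missing year
  expect_error(
    classify_tiers(tl, econ, study_window("2000-01", "2019-12",
                                          min_pre = 1, min_post = 1)),
    "2001"
  )
})

test_that("the cumulative score is a right-continuous step function with tier-sized jumps", {
  w <- lt_window()
  tiers <- classify_tiers(lithuania_timeline(), lithuania_economy(), w)
  sc <- cumulative_score(tiers, w)
  expect_equal(nrow(sc), 240)

  at <- function(m) sc$score[sc$month == as.Date(paste0(m, "-01"))]
  expect_equal(at("2007-12"), 0)
  expect_equal(at("2008-01"), 1)
  expect_equal(at("2008-12"), 1)
  expect_equal(at("2009-01"), 1.5)
  expect_equal(at("2014-03"), 1.5)
  expect_equal(at("2014-04"), 2)
  expect_equal(at("2014-06"), 2)
  expect_equal(at("2017-03"), 3)
  expect_equal(at("2018-01"), 4)
  expect_equal(at("2019-12"), 4)

  jumps <- diff(sc$score)
  expect_true(all(jumps >= 0))
  expect_setequal(unique(jumps[jumps > 0]), c(1, 0.5))
  expect_equal(sum(jumps > 0),
               sum(tiers$tier %in% c("tier1", "tier2_only")) -
                 (sc$score[1] > 0))
})

test_that("mid-month enactments score from their calendar month and weights are configurable", {
  w <- study_window("2009-01", "2013-12", min_pre = 3, min_post = 3)
  econ <- tibble::tibble(year = 2008:2013,
                         income_index = c(100, 100, 100, 100, 100, 100),
                         price_index = c(100, 102, 104, 106, 108, 110))
  attr(econ, "base_year") <- 2008
  tl <- measure_row("E1", "2010-06-15") # affordability decreasing
  tiers <- classify_tiers(tl, econ, w, threshold = 5)
  expect_equal(as.character(tiers$tier), "tier1")
  sc <- cumulative_score(tiers, w, weights = list(tier1 = 2, tier2_only = 0.5))
  expect_equal(sc$score[sc$month == as.Date("2010-05-01")], 0)
  expect_equal(sc$score[sc$month == as.Date("2010-06-01")], 2)
})
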