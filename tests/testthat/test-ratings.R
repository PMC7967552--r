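ratings_tbl <- function(m, event_ids = paste0("E", seq_len(nrow(m)))) {
  out <- tibble::tibble(event_id = event_ids)
  for (j in seq_len(ncol(m))) out[[paste0("rater_", j)]] <- m[, j]
  out
}

test_that("per-item means are plain arithmetic over raters", {
  r <- ratings_tbl(rbind(c(5, 5, 5, 5, 5), c(2, 4, 6, 8, 10)))
  mr <- mean_ratings(r)
  expect_equal(mr$mean_rating, c(5, 6))
  r2 <- ratings_tbl(rbind(c(0, 10), c(10, 0)))
  expect_equal(mean_ratings(r2)$mean_rating, c(5, 5))
  # missing cells flagged under pairwise-available mode, rejected otherwise
  r3 <- ratings_tbl(rbind(c(2, NA, 6), c(4, 4, 4)))
  expect_error(mean_ratings(r3), "missing")
  mr3 <- mean_ratings(r3, allow_missing = TRUE)
  expect_equal(mr3$mean_rating, c(4, 4))
  expect_equal(mr3$incomplete, c(TRUE, FALSE))
})

test_that("date selection uses the max item mean per date with an inclusive threshold", {
  events <- dplyr::bind_rows(
    measure_row("E1", "2010-01-01"),
    measure_row("E2", "2011-01-01"),
    measure_row("E3", "2012-01-01")
  )
  r <- ratings_tbl(rbind(c(5, 5), c(4, 5), c(0, 0)))
  expect_equal(format(select_dates(r, events)),
               c("2010-01-01")) # E2 mean 4.5 < 5; boundary 5.0 selected
  expect_equal(length(select_dates(ratings_tbl(rbind(c(0, 0), c(0, 0)),
                                               c("E1", "E2")), events)), 0)
  # monotone: raising the threshold never adds dates
  for (th in c(0, 2.5, 5, 7.5, 10)) {
    lo <- select_dates(r, events, threshold = th)
    hi <- select_dates(r, events, threshold = th + 1)
    expect_true(all(hi %in% lo))
  }
  expect_error(select_dates(ratings_tbl(rbind(c(1, 1), c(1, 1)),
                                        c("E1", "EX")), events),
               "unknown event")
})

test_that("the ICC matches an independent ANOVA oracle on random matrices", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    k <- sample(3:6, 1)
    m <- matrix(round(runif(n * k, 0, 10)), n, k)
    if (var(as.vector(m)) == 0) next
    got <- icc(ratings_tbl(m))
    expect_equal(got$icc, icc_oracle(m), tolerance = 1e-10)
    expect_lte(got$ci_low, got$icc)
    expect_gte(got$ci_high, got$icc)
  }
})

test_that("the ICC is shift-invariant, unity for identical raters, and penalizes offsets", {
  m <- matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5), 3, 3)
  expect_equal(icc(ratings_tbl(m))$icc, icc(ratings_tbl(m + 3))$icc,
               tolerance = 1e-12)
  # duplicated rater columns, varying items: perfect agreement
  dup <- matrix(rep(c(1, 5, 9), 4), 3, 4)
  expect_equal(icc(ratings_tbl(dup))$icc, 1)
  # constant items, raters differing by an offset: absolute agreement < 1
  off <- cbind(c(4, 4, 4, 4), c(6, 6, 6, 6), c(5, 5, 5, 5))
  off <- off + matrix(c(0.2, -0.1, 0, 0.1, 0, -0.2, 0.1, -0.1, 0, 0, 0.2, -0.2), 4, 3)
  expect_lt(icc(ratings_tbl(off))$icc, 1)
  expect_error(icc(ratings_tbl(matrix(5, 3, 3))), "degenerate")
})

test_that("pairwise Spearman agreement matches a rank-based brute-force recomputation", {
  ident <- ratings_tbl(cbind(c(1, 4, 7, 9), c(1, 4, 7, 9)))
  expect_equal(spearman_summary(ident)$pairs$rho, 1)
  rev <- ratings_tbl(cbind(c(1, 4, 7, 9), c(9, 7, 4, 1)))
  expect_equal(spearman_summary(rev)$pairs$rho, -1)

  r <- simulate_ratings(c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10, 0, 5, 7, 3, 6,
                          2, 8, 9, 1, 4, 5),
                        n_raters = 5, rater_sd = 2, rater_bias_sd = 1,
                        seed = 17)
  got <- spearman_summary(r)
  m <- rating_values(r)
  oracle <- combn(ncol(m), 2, function(idx) {
    spearman_oracle(m[, idx[1]], m[, idx[2]])
  })
  expect_equal(got$pairs$rho, as.numeric(oracle), tolerance = 1e-12)
  expect_equal(got$median, median(oracle), tolerance = 1e-12)
  expect_equal(got$iqr, unname(diff(quantile(oracle, c(0.25, 0.75)))),
               tolerance = 1e-12)
  # rho invariant under a strictly monotone transform of one rater
  r2 <- r
  r2$rater_1 <- r2$rater_1^1.5 / 10 # keeps values in [0, 10]
  expect_equal(spearman_summary(r2)$pairs$rho, got$pairs$rho,
               tolerance = 1e-12)
  # constant rater: pair dropped and flagged
  rc <- ratings_tbl(cbind(c(3, 3, 3), c(1, 5, 9), c(2, 4, 8)))
  sc <- spearman_summary(rc)
  expect_equal(sc$dropped_pairs, 2)
  expect_equal(nrow(sc$pairs), 3)
})

test_that("concordance partitions expert and criteria selections", {
  tiers <- classify_tiers(lithuania_timeline(), lithuania_economy(),
                          lt_window())
  criteria_dates <- sort(tiers$date[tiers$tier %in% c("tier1", "tier2_only")])

  expert <- sort(c(criteria_dates,
                   as.Date(c("2015-03-01", "2016-01-01"))))
  conc <- rating_concordance(expert, tiers)
  expect_equal(format(conc$expert_only), c("2015-03-01", "2016-01-01"))
  expect_length(conc$criteria_only, 0)
  expect_true(conc$expert_superset)
  expect_equal(sort(conc$in_both), criteria_dates)

  same <- rating_concordance(criteria_dates, tiers)
  expect_length(same$expert_only, 0)
  expect_length(same$criteria_only, 0)

  disjoint <- rating_concordance(as.Date("1999-01-01"), tiers)
  expect_length(disjoint$in_both, 0)
  expect_false(disjoint$expert_superset)
})
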