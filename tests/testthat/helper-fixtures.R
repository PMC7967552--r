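# In-code fixtures shared across test files.

lt_window <- function() study_window("2000-01", "2019-12")

# a small valid economic series with no base year in range
toy_econ <- function(years = 2000:2005,
                     income = c(100, 104, 110, 118, 120, 131),
                     price = c(100, 101, 105, 106, 112, 118)) {
  tibble::tibble(year = years, income_index = income, price_index = price)
}

# single-measure event row in the flat timeline layout
measure_row <- function(event_id, date, domain = "taxation_price",
                        direction = "restrictive", population = "general",
                        specific_group = "", availability_scope = "none",
                        immediacy = "immediate", measure_no = 1L,
                        description = "test measure") {
  tibble::tibble(event_id = event_id, date = as.Date(date),
                 measure_no = measure_no, domain = domain,
                 direction = direction, population = population,
                 specific_group = specific_group,
                 availability_scope = availability_scope,
                 immediacy = immediacy, description = description)
}

# independent ANOVA-based ICC(2,1) oracle: explicit aov() mean squares,
# coded apart from the package's own sums-of-squares implementation
icc_oracle <- function(m) {
  long <- data.frame(
    v = as.vector(m),
    item = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(v ~ item + rater, data = long))[[1]]
  msr <- tab["item", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# rank-based brute-force Spearman: average ranks, explicit Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
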