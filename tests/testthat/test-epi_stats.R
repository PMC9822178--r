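test_that("2x2 tables validate their cells", {
  expect_s3_class(two_by_two(1, 2, 3, 4), "two_by_two")
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
  expect_error(two_by_two(1.5, 2, 3, 4), "integer")
})

test_that("odds ratios and Wald intervals follow the closed form", {
  null <- odds_ratio(two_by_two(1, 1, 1, 1))
  expect_equal(null$or, 1)
  expect_equal(null$z, 0)
  expect_equal(null$p, 1)

  # the period-by-negative table of the study's printed counts
  neg <- odds_ratio(two_by_two(91242, 74518, 65164, 74397))
  expect_equal(neg$or, 1.3979, tolerance = 1e-4)
  expect_equal(neg$ci_low, 1.378, tolerance = 1e-3)
  expect_equal(neg$ci_high, 1.418, tolerance = 1e-3)
  expect_true(neg$p < 0.001)

  # row-scaling invariance of the point estimate
  scaled <- odds_ratio(two_by_two(912420, 745180, 65164, 74397))
  expect_equal(scaled$or, neg$or, tolerance = 1e-12)

  # OR(a,b,c,d) = 1 / OR(c,d,a,b)
  flip <- odds_ratio(two_by_two(65164, 74397, 91242, 74518))
  expect_equal(flip$or, 1 / neg$or, tolerance = 1e-12)
})

test_that("CI brackets the estimate and tightens as counts grow", {
  withr::local_seed(9)
  for (i in 1:50) {
    cells <- sample(5:400, 4, replace = TRUE)
    o <- odds_ratio(two_by_two(cells[1], cells[2], cells[3], cells[4]))
    expect_lte(o$ci_low, o$or)
    expect_gte(o$ci_high, o$or)
    o10 <- odds_ratio(two_by_two(cells[1] * 10, cells[2] * 10,
                                 cells[3] * 10, cells[4] * 10))
    expect_lt(o10$ci_high / o10$ci_low, o$ci_high / o$ci_low)
    expect_equal(o10$or, o$or, tolerance = 1e-12)
  }
})

test_that("zero cells error unless the Haldane correction is requested", {
  expect_error(odds_ratio(two_by_two(0, 5, 5, 5)), "zero cell")
  h <- odds_ratio(two_by_two(0, 5, 5, 5), haldane = TRUE)
  expect_equal(h$or, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("the 2x2 chi-square matches the hand-computed Pearson value", {
  null <- two_proportion_chisq(two_by_two(1, 1, 1, 1))
  expect_equal(null$chisq, 0)
  expect_equal(null$p, 1)
  t <- two_proportion_chisq(two_by_two(30, 70, 10, 90))
  expect_equal(t$chisq, 12.5, tolerance = 1e-12)
  expect_equal(t$df, 1L)
  expect_error(two_proportion_chisq(two_by_two(0, 0, 10, 90)), "empty margin")
})

test_that("chi-square equals the squared pooled two-proportion z", {
  withr::local_seed(33)
  for (i in 1:50) {
    cells <- sample(3:300, 4, replace = TRUE)
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    res <- two_proportion_chisq(t)
    # pooled z computed independently
    n1 <- cells[1] + cells[2]; n2 <- cells[3] + cells[4]
    p1 <- cells[1] / n1; p2 <- cells[3] / n2
    pp <- (cells[1] + cells[3]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(res$chisq, z^2, tolerance = 1e-9)
    expect_equal(res$z^2, res$chisq, tolerance = 1e-12)
    expect_equal(sign(res$z), if (z == 0) 1 else sign(z))
  }
})

test_that("percent change is relative to the baseline count", {
  expect_equal(percent_change(100, 150), 50)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(139561, 165760), 18.772, tolerance = 1e-3)
  expect_error(percent_change(0, 10), "> 0")
})

test_that("sentiment share tables tally counts and within-period percentages", {
  x <- data.frame(
    period = c(rep("peripandemic", 8), rep("prepandemic", 2), "out_of_window"),
    gold_label = c(rep("negative", 6), "neutral", "positive",
                   "negative", "positive", "neutral")
  )
  tbl <- sentiment_share_table(x)
  expect_equal(tbl$n_peri[tbl$sentiment == "negative"], 6)
  expect_equal(tbl$pct_peri[tbl$sentiment == "negative"], 75.0)
  expect_equal(attr(tbl, "n_out_of_window"), 1)
  expect_equal(unname(attr(tbl, "totals")["peripandemic"]), 8)

  mono <- data.frame(period = rep("prepandemic", 5),
                     gold_label = rep("negative", 5))
  tm <- sentiment_share_table(mono)
  expect_equal(tm$pct_pre, c(100, 0, 0))
})

test_that("the printed study counts replay through the table builder", {
  # reconstruct per-period label counts from the published table
  counts <- list(
    prepandemic = c(negative = 65164, neutral = 39764, positive = 34633),
    peripandemic = c(negative = 91242, neutral = 46897, positive = 27621)
  )
  x <- data.frame(
    period = rep(names(counts), times = vapply(counts, sum, 0)),
    gold_label = unlist(lapply(counts, function(k) rep(names(k), k)), use.names = FALSE)
  )
  tbl <- sentiment_share_table(x)
  expect_equal(tbl$pct_peri[tbl$sentiment == "negative"], 55.0)
  expect_equal(tbl$pct_pre[tbl$sentiment == "negative"], 46.7)
  expect_equal(tbl$pct_pre[tbl$sentiment == "positive"], 24.8)
  expect_equal(tbl$pct_peri[tbl$sentiment == "positive"], 16.7)
  expect_equal(tbl$pct_total[tbl$sentiment == "positive"], 20.4)
  con <- period_sentiment_contrasts(tbl)
  expect_equal(con$or[con$sentiment == "negative"], 1.3979, tolerance = 1e-4)
  expect_equal(con$or[con$sentiment == "positive"], 0.6058, tolerance = 1e-4)
  expect_equal(con$or[con$sentiment == "neutral"], 0.99, tolerance = 1e-2)
})

test_that("temporal analysis returns unit odds ratios under a null design", {
  cfg <- simulation_config(
    n_pre = 4000, n_peri = 4000,
    prevalence_pre = c(0.5, 0.25, 0.25),
    prevalence_peri = c(0.5, 0.25, 0.25),
    after_midnight_negative_odds_multiplier = 1,
    seed = 77L
  )
  corp <- simulate_corpus(cfg)
  ta <- temporal_negative_analysis(corp)
  for (o in list(ta$overall, ta$by_period$prepandemic, ta$by_period$peripandemic)) {
    expect_lt(o$ci_low, 1)
    expect_gt(o$ci_high, 1)
  }
  expect_equal(sum(ta$hourly_negative), sum(corp$gold_label == "negative"))
})

test_that("temporal analysis recovers an injected after-midnight odds multiplier", {
  cfg <- simulation_config(
    n_pre = 10000, n_peri = 10000,
    prevalence_pre = c(0.467, 0.285, 0.248),
    prevalence_peri = c(0.550, 0.283, 0.167),
    after_midnight_negative_odds_multiplier = 1.5,
    seed = 2024L
  )
  corp <- simulate_corpus(cfg)
  ta <- temporal_negative_analysis(corp)
  expect_gt(ta$overall$or, 1.4)
  expect_lt(ta$overall$or, 1.6)
  # the multiplier acts within each period as well
  expect_gt(ta$by_period$peripandemic$or, 1.3)
  # conservation: hourly distribution sums to the negative total
  expect_equal(sum(ta$hourly_negative), sum(corp$gold_label == "negative"))
})

test_that("chi-square power search returns the minimal sufficient sample size", {
  expect_identical(chisq_power_sample_size(w = 0.3, alpha = 0.05,
                                           power = 0.80, df = 5), 143L)
  expect_identical(chisq_power_sample_size(w = 0.5, alpha = 0.05,
                                           power = 0.80, df = 1), 32L)
  # minimality: power crosses the target exactly at the returned n
  for (w in c(0.2, 0.3, 0.5)) {
    n <- chisq_power_sample_size(w = w, df = 2, power = 0.9)
    expect_gte(chisq_power(n, w, df = 2), 0.9)
    expect_lt(chisq_power(n - 1, w, df = 2), 0.9)
  }
  # monotonicity: doubling the effect size reduces the requirement
  expect_lt(chisq_power_sample_size(w = 0.6, df = 5),
            chisq_power_sample_size(w = 0.3, df = 5))
  expect_error(chisq_power_sample_size(w = 0, df = 1), "unattainable")
  # power itself is monotone in n
  ns <- c(10, 50, 100, 500)
  pw <- vapply(ns, chisq_power, 0, w = 0.3, df = 5)
  expect_true(all(diff(pw) > 0))
})
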