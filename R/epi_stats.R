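# Statistical layer of the two-period study: sentiment-share tables, 2x2
# odds ratios with Wald intervals and z-statistics, two-proportion
# chi-square tests, percent change, the before/after-midnight temporal
# contrasts, and chi-square power / sample size.

#' 2x2 exposure-by-outcome table
#'
#' Cell layout: `a` = exposed with outcome, `b` = exposed without, `c` =
#' unexposed with outcome, `d` = unexposed without.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  x <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stopf("cells a, b, c, d must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.numeric(x), c("a", "b", "c", "d"))),
            class = "two_by_two")
}

#' Odds ratio with Wald confidence interval
#'
#' Closed-form odds ratio `(a*d)/(b*c)` on a 2x2 table with the Wald
#' interval `exp(log(OR) +/- z_crit * SE)`, `SE = sqrt(1/a+1/b+1/c+1/d)`,
#' the z-statistic `log(OR)/SE` and its two-sided normal p-value. This is
#' exactly the univariate logistic-regression odds ratio for a binary
#' exposure, computed without fitting machinery. A zero cell is an error
#' unless `haldane = TRUE`, which adds 0.5 to every cell explicitly (no
#' silent continuity correction).
#'
#' @param t A [two_by_two()] table.
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Add 0.5 to all cells when any cell is zero.
#' @return Object of class `or_result` with `or`, `ci_low`, `ci_high`, `z`,
#'   `p`, `se_log_or` and the input table.
#' @export
#' @examples
#' odds_ratio(two_by_two(91242, 74518, 65164, 74397))
odds_ratio <- function(t, conf_level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- as.numeric(c(t$a, t$b, t$c, t$d))  # doubles: a*d overflows int
  if (any(cells == 0)) {
    if (!haldane) {
      stopf("zero cell in 2x2 table (a=%d b=%d c=%d d=%d); set haldane = TRUE for an explicit 0.5 correction",
            t$a, t$b, t$c, t$d)
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(or) / se
  res <- list(or = or,
              ci_low = exp(log(or) - zc * se),
              ci_high = exp(log(or) + zc * se),
              z = z,
              p = 2 * stats::pnorm(-abs(z)),
              se_log_or = se,
              conf_level = conf_level,
              table = t)
  class(res) <- "or_result"
  res
}

#' @export
print.or_result <- function(x, digits = 2, mode = "round", ...) {
  cat(sprintf("OR %s (%d%% CI %s-%s), z = %.2f, p %s\n",
              format_ratio(x$or, digits, mode),
              round(100 * x$conf_level),
              format_ratio(x$ci_low, digits, mode),
              format_ratio(x$ci_high, digits, mode),
              x$z,
              if (x$p < 0.001) "< .001" else sprintf("= %.3f", x$p)))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), the signed
#' z-statistic `sqrt(chi2)` carrying the direction of the association (the
#' sign of `log` odds ratio), and the two-sided p-value. Identical to the
#' pooled two-proportion z-test: `chi2 = z^2`.
#'
#' @param t A [two_by_two()] table.
#' @return List with `chisq`, `df`, `z`, `p`.
#' @export
two_proportion_chisq <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stopf("empty margin in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  chisq <- unname(ct$statistic)
  direction <- sign(log((t$a * t$d) / max(t$b * t$c, .Machine$double.xmin)))
  if (!is.finite(direction) || direction == 0) direction <- 1
  list(chisq = chisq, df = 1L, z = direction * sqrt(chisq), p = unname(ct$p.value))
}

#' Percent change between two counts
#'
#' `100 * (n_after - n_before) / n_before`.
#'
#' @param n_before Baseline count (> 0).
#' @param n_after Later count.
#' @return Signed percentage.
#' @export
#' @examples
#' percent_change(139561, 165760)  # +18.77
percent_change <- function(n_before, n_after) {
  if (is.na(n_before) || n_before <= 0) stopf("`n_before` must be > 0")
  100 * (n_after - n_before) / n_before
}

#' Sentiment shares by study period
#'
#' Tabulates counts and within-period percentages for each sentiment in the
#' prepandemic and peripandemic windows, with totals. Records outside both
#' windows are rejected from the table and their count reported in
#' `attr(, "n_out_of_window")`.
#'
#' @param x A `corpus` (or data.frame) with a `period` column and a
#'   sentiment label column.
#' @param label_col Name of the label column (default `"gold_label"`; use
#'   the fused `"decision"` column for pipeline output).
#' @return Data frame of class `share_table` with one row per sentiment:
#'   counts and percentages for total / prepandemic / peripandemic.
#' @export
sentiment_share_table <- function(x, label_col = "gold_label") {
  if (!"period" %in% names(x)) stopf("records need a `period` column (see annotate_time())")
  if (!label_col %in% names(x)) stopf("no label column '%s'", label_col)
  lab <- as.character(x[[label_col]])
  per <- as.character(x$period)
  if (anyNA(lab)) stopf("every record needs a sentiment label")
  oow <- !(per %in% c("prepandemic", "peripandemic"))
  lab <- lab[!oow]; per <- per[!oow]
  lv <- sentiment_levels()
  n_pre_tot <- sum(per == "prepandemic")
  n_peri_tot <- sum(per == "peripandemic")
  n_tot <- length(lab)
  rows <- lapply(lv, function(s) {
    n_pre <- sum(per == "prepandemic" & lab == s)
    n_peri <- sum(per == "peripandemic" & lab == s)
    data.frame(sentiment = s,
               n_total = n_pre + n_peri,
               pct_total = if (n_tot > 0) round_half_up(100 * (n_pre + n_peri) / n_tot, 1) else NA_real_,
               n_pre = n_pre,
               pct_pre = if (n_pre_tot > 0) round_half_up(100 * n_pre / n_pre_tot, 1) else NA_real_,
               n_peri = n_peri,
               pct_peri = if (n_peri_tot > 0) round_half_up(100 * n_peri / n_peri_tot, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(total = n_tot, prepandemic = n_pre_tot,
                           peripandemic = n_peri_tot)
  attr(out, "n_out_of_window") <- sum(oow)
  class(out) <- c("share_table", "data.frame")
  out
}

#' Period contrasts per sentiment (peripandemic vs prepandemic)
#'
#' For each sentiment, builds the 2x2 table with exposure = peripandemic
#' period and outcome = that sentiment, and reports the odds ratio, Wald CI,
#' chi-square z and p-value — the row structure of a period-contrast report.
#'
#' @param tbl A [sentiment_share_table()] result.
#' @param conf_level Confidence level for the Wald CI.
#' @return Data frame with one row per sentiment: counts, `or`, `ci_low`,
#'   `ci_high`, `z` (from the chi-square), `p`.
#' @export
period_sentiment_contrasts <- function(tbl, conf_level = 0.95) {
  stopifnot(inherits(tbl, "share_table"))
  totals <- attr(tbl, "totals")
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    r <- tbl[i, ]
    t <- two_by_two(r$n_peri, totals["peripandemic"] - r$n_peri,
                    r$n_pre, totals["prepandemic"] - r$n_pre)
    orr <- odds_ratio(t, conf_level = conf_level)
    ch <- two_proportion_chisq(t)
    data.frame(sentiment = r$sentiment,
               n_peri = r$n_peri, n_pre = r$n_pre,
               or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
               z = ch$z, p = ch$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Before/after-midnight temporal analysis of negative sentiment
#'
#' Builds the study's temporal 2x2 contrasts on a labelled, time-annotated
#' corpus: (i) after vs before midnight x negative vs non-negative over all
#' records; (ii) peripandemic vs prepandemic among negatives within each
#' clock bucket; (iii) after vs before midnight among negatives within each
#' period; plus the hourly (0-23) distribution of negative posts.
#'
#' Contrast (ii) and (iii) condition on negative sentiment as the outcome:
#' (ii) exposure = peripandemic, outcome = negative, within each bucket;
#' (iii) exposure = after_midnight, outcome = negative, within each period.
#'
#' @param x A `corpus` (or data.frame) with `period`, `bucket`, `timestamp`
#'   and a sentiment label column.
#' @param label_col Name of the label column (default `"gold_label"`).
#' @return List of class `temporal_analysis`: `overall` (contrast i),
#'   `by_bucket` (named list, contrast ii), `by_period` (named list,
#'   contrast iii), each an `or_result`; `hourly_negative` (named integer
#'   vector over hours 0-23); `share_after_midnight_negative` (percentage of
#'   negative posts that fall after midnight).
#' @export
temporal_negative_analysis <- function(x, label_col = "gold_label") {
  for (col in c("period", "bucket")) {
    if (!col %in% names(x)) stopf("records need a `%s` column (see annotate_time())", col)
  }
  if (!label_col %in% names(x)) stopf("no label column '%s'", label_col)
  lab <- as.character(x[[label_col]])
  neg <- lab == "negative"
  after <- x$bucket == "after_midnight"
  peri <- x$period == "peripandemic"
  in_window <- x$period %in% c("prepandemic", "peripandemic")
  neg <- neg[in_window]; after <- after[in_window]; peri <- peri[in_window]
  ts <- x$timestamp[in_window]

  tab <- function(exposed, outcome, name) {
    t <- two_by_two(sum(exposed & outcome), sum(exposed & !outcome),
                    sum(!exposed & outcome), sum(!exposed & !outcome))
    tryCatch(odds_ratio(t),
             error = function(e) stopf("contrast '%s': %s", name, conditionMessage(e)))
  }

  overall <- tab(after, neg, "after vs before midnight (all records)")
  by_bucket <- list(
    after_midnight = tab(peri[after], neg[after], "peri vs pre, after midnight"),
    before_midnight = tab(peri[!after], neg[!after], "peri vs pre, before midnight")
  )
  by_period <- list(
    prepandemic = tab(after[!peri], neg[!peri], "after vs before midnight, prepandemic"),
    peripandemic = tab(after[peri], neg[peri], "after vs before midnight, peripandemic")
  )
  hours <- as.integer(format(ts[neg], "%H", tz = "UTC"))
  hourly <- stats::setNames(tabulate(hours + 1L, nbins = 24L), 0:23)
  res <- list(overall = overall, by_bucket = by_bucket, by_period = by_period,
              hourly_negative = hourly,
              share_after_midnight_negative =
                if (any(neg)) round_half_up(100 * sum(neg & after) / sum(neg), 1) else NA_real_)
  class(res) <- "temporal_analysis"
  res
}

#' @export
print.temporal_analysis <- function(x, ...) {
  cat("<temporal_analysis>\n  after vs before midnight (negative outcome): ")
  print(x$overall)
  cat("  peri vs pre | after midnight:  "); print(x$by_bucket$after_midnight)
  cat("  peri vs pre | before midnight: "); print(x$by_bucket$before_midnight)
  cat("  after vs before | prepandemic:  "); print(x$by_period$prepandemic)
  cat("  after vs before | peripandemic: "); print(x$by_period$peripandemic)
  cat(sprintf("  %% of negative posts after midnight: %.1f\n",
              x$share_after_midnight_negative))
  invisible(x)
}

#' Chi-square power and minimum sample size
#'
#' Exact power of the chi-square test computed from the noncentral
#' chi-square distribution: with effect size `w`, sample size `n` and
#' noncentrality `lambda = n * w^2`, power is
#' `P(Chi2_df(lambda) > critical value at alpha)`.
#' `chisq_power_sample_size()` returns the smallest integer `n` whose power
#' reaches the target (power at `n - 1` falls below it).
#'
#' @param n Sample size.
#' @param w Cohen's chi-square effect-size index (> 0).
#' @param df Degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return `chisq_power()`: power in \[0, 1\].
#' @export
#' @examples
#' chisq_power_sample_size(w = 0.3, alpha = 0.05, power = 0.80, df = 5)  # 143
chisq_power <- function(n, w, df, alpha = 0.05) {
  if (w <= 0) stopf("`w` must be > 0")
  if (df < 1) stopf("`df` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  crit <- stats::qchisq(1 - alpha, df = df)
  stats::pchisq(crit, df = df, ncp = n * w^2, lower.tail = FALSE)
}

#' @param power Target power in (0, 1).
#' @param n_max Upper bound of the search range.
#' @rdname chisq_power
#' @return `chisq_power_sample_size()`: minimal integer sample size.
#' @export
chisq_power_sample_size <- function(w, alpha = 0.05, power = 0.80, df = 1,
                                    n_max = 1e7) {
  if (w <= 0) stopf("power is unattainable with `w` = 0; `w` must be > 0")
  if (power <= 0 || power >= 1) stopf("`power` must be in (0, 1)")
  lo <- 1
  hi <- n_max
  if (chisq_power(hi, w, df, alpha) < power) {
    stopf("target power not reachable within n_max = %g", n_max)
  }
  # bisection on the integer lattice; power is monotone increasing in n
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (chisq_power(mid, w, df, alpha) >= power) hi <- mid else lo <- mid
  }
  n <- if (chisq_power(lo, w, df, alpha) >= power) lo else hi
  as.integer(n)
}
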