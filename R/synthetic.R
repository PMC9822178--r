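# Seeded generators for tweet-like corpora and noisy classifier ensembles
# with the statistical structure the analysis layer estimates: two study
# periods with configurable sentiment prevalences, an hour-of-day
# distribution in which negative posts have their after-midnight odds
# multiplied by a known factor (the generating parameter is exactly the
# estimand of the temporal analysis), and conditionally independent mock
# classifiers defined by confusion matrices.

#' Simulation configuration
#'
#' @param n_pre,n_peri Record counts for the prepandemic (calendar 2019)
#'   and peripandemic (calendar 2020) windows.
#' @param prevalence_pre,prevalence_peri Probability triples over
#'   (negative, neutral, positive) within each period.
#' @param after_midnight_negative_odds_multiplier Positive real; the odds
#'   of a negative post falling in the after-midnight bucket (local hours
#'   0-12) are this factor times the corresponding odds for non-negative
#'   posts.
#' @param hour_weights 24 non-negative weights (hours 0-23) for the
#'   baseline posting-time distribution of non-negative posts.
#' @param classifiers Named list of [mock_params()] defining the mock
#'   ensemble.
#' @param seed Integer master seed; all draws derive from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_pre, n_peri,
                              prevalence_pre, prevalence_peri,
                              after_midnight_negative_odds_multiplier = 1,
                              hour_weights = rep(1, 24),
                              classifiers = list(),
                              seed = 1L) {
  if (n_pre < 0 || n_peri < 0) stopf("record counts must be >= 0")
  assert_prob_vector(prevalence_pre, what = "prevalence_pre")
  assert_prob_vector(prevalence_peri, what = "prevalence_peri")
  if (after_midnight_negative_odds_multiplier <= 0) {
    stopf("odds multiplier must be > 0")
  }
  if (length(hour_weights) != 24L || any(hour_weights < 0) || all(hour_weights == 0)) {
    stopf("`hour_weights` must be 24 non-negative weights, not all zero")
  }
  if (length(classifiers)) {
    if (is.null(names(classifiers)) || any(!nzchar(names(classifiers)))) {
      stopf("`classifiers` must be a named list")
    }
    for (p in classifiers) stopifnot(inherits(p, "mock_params"))
  }
  structure(list(
    n_pre = as.integer(n_pre), n_peri = as.integer(n_peri),
    prevalence_pre = stats::setNames(as.numeric(prevalence_pre), sentiment_levels()),
    prevalence_peri = stats::setNames(as.numeric(prevalence_peri), sentiment_levels()),
    after_midnight_negative_odds_multiplier = after_midnight_negative_odds_multiplier,
    hour_weights = as.numeric(hour_weights),
    classifiers = classifiers,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default study-shaped simulation profile
#'
#' A configuration emulating the published study's structure at one tenth of
#' its corpus size (so a full pipeline run stays fast): 13,956 prepandemic
#' and 16,576 peripandemic records; per-period sentiment prevalences
#' (negative, neutral, positive) of (0.467, 0.285, 0.248) prepandemic and
#' (0.550, 0.283, 0.167) peripandemic; an after-midnight negative odds
#' multiplier of 1.43; and five mock classifiers with symmetric confusion
#' accuracies (0.803, 0.527, 0.530, 0.493, 0.453) echoing the accuracy
#' spread of a realistic pretrained-model ensemble.
#'
#' @param seed Master seed.
#' @return A [simulation_config()].
#' @export
default_study_profile <- function(seed = 1L) {
  accs <- c(model1 = 0.803, model2 = 0.527, model3 = 0.530,
            model4 = 0.493, model5 = 0.453)
  classifiers <- lapply(seq_along(accs), function(i) {
    mock_params(confusion = accs[[i]], concentration = 20,
                seed = derive_seed(seed, names(accs)[i]))
  })
  names(classifiers) <- names(accs)
  simulation_config(
    n_pre = 13956L, n_peri = 16576L,
    prevalence_pre = c(0.467, 0.285, 0.248),
    prevalence_peri = c(0.550, 0.283, 0.167),
    after_midnight_negative_odds_multiplier = 1.43,
    hour_weights = rep(1, 24),
    classifiers = classifiers,
    seed = seed
  )
}

# Sentiment-keyed text templates; every template contains "insomnia" so the
# inclusion filter keeps all generated records.
SENTIMENT_TEMPLATES <- list(
  negative = c(
    "another awful night of insomnia, cannot sleep at all",
    "this insomnia is ruining my life, so exhausted and miserable",
    "crying at 3am because insomnia will not let me rest",
    "worst insomnia ever, my head hurts and nothing helps",
    "so anxious and wired, insomnia wins again tonight"
  ),
  neutral = c(
    "reading an article about insomnia and sleep hygiene",
    "study finds insomnia affects many adults worldwide",
    "podcast episode today covers insomnia and circadian rhythms",
    "my doctor mentioned insomnia at the checkup, more tests next week",
    "survey on insomnia open until friday for volunteers"
  ),
  positive = c(
    "finally beat my insomnia, slept eight hours and feel great",
    "new routine really helps my insomnia, grateful and rested",
    "good news, the insomnia clinic had a cancellation, got in early",
    "insomnia much better this month, mornings are lovely again",
    "thankful my insomnia treatment works, sweet dreams everyone"
  )
)

SALT_URLS <- c("https://t.co/abc123", "http://example.com/sleep", "https://t.co/xyz987")
SALT_TAGS <- c("#insomnia", "#sleepless", "#cantsleep", "#nosleep")
SALT_MENTIONS <- c("@sleepdoc", "@nightowl42", "@friend")
SALT_EMOJI <- c("\U0001F62B", "\U0001F634", "\U0001F62D", "\U0001F31B")

assemble_texts <- function(gold) {
  n <- length(gold)
  base <- vapply(gold, function(g) {
    tpl <- SENTIMENT_TEMPLATES[[g]]
    tpl[sample.int(length(tpl), 1L)]
  }, "", USE.NAMES = FALSE)
  add_url <- stats::runif(n) < 0.3
  add_tag <- stats::runif(n) < 0.5
  add_mention <- stats::runif(n) < 0.25
  add_emoji <- stats::runif(n) < 0.4
  salt <- function(pool, on) ifelse(on, pool[sample.int(length(pool), n, replace = TRUE)], "")
  out <- paste(base,
               salt(SALT_TAGS, add_tag),
               salt(SALT_MENTIONS, add_mention),
               salt(SALT_EMOJI, add_emoji),
               salt(SALT_URLS, add_url))
  trimws(gsub("\\s+", " ", out))
}

# Draw posting hours: baseline weights for non-negative posts; for negative
# posts the after-midnight hours (0-12) have their weights multiplied so
# that odds(after-midnight | negative) = multiplier x odds(after | other).
draw_hours <- function(gold, hour_weights, multiplier) {
  w_base <- hour_weights / sum(hour_weights)
  w_neg <- hour_weights
  w_neg[1:13] <- w_neg[1:13] * multiplier  # hours 0..12
  w_neg <- w_neg / sum(w_neg)
  n <- length(gold)
  hours <- integer(n)
  is_neg <- gold == "negative"
  if (any(is_neg)) hours[is_neg] <- sample(0:23, sum(is_neg), replace = TRUE, prob = w_neg)
  if (any(!is_neg)) hours[!is_neg] <- sample(0:23, sum(!is_neg), replace = TRUE, prob = w_base)
  hours
}

#' Simulate a gold-labelled corpus
#'
#' Generates `n_pre + n_peri` tweet-like records: per-period gold sentiments
#' drawn from the configured prevalences; timestamps uniform over the
#' period's days with hours drawn from the (negativity-tilted) hour
#' distribution; texts assembled from a sentiment-keyed template lexicon and
#' salted with URLs, hashtags, mentions and emoji so the cleaning step has
#' real work to do. Every text contains the keyword "insomnia". Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A `corpus` with `gold_label`, `period` and `bucket` columns.
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_pre + cfg$n_peri
  if (n == 0L) return(empty_corpus(provenance = "simulated (empty)"))
  with_local_seed(derive_seed(cfg$seed, "corpus"), {
    period <- rep(c("prepandemic", "peripandemic"), c(cfg$n_pre, cfg$n_peri))
    lv <- sentiment_levels()
    gold <- character(n)
    pre_idx <- period == "prepandemic"
    if (cfg$n_pre > 0) {
      gold[pre_idx] <- sample(lv, cfg$n_pre, replace = TRUE, prob = cfg$prevalence_pre)
    }
    if (cfg$n_peri > 0) {
      gold[!pre_idx] <- sample(lv, cfg$n_peri, replace = TRUE, prob = cfg$prevalence_peri)
    }
    days_in_period <- ifelse(pre_idx, 365L, 366L)
    day <- floor(stats::runif(n) * days_in_period)
    origin <- as.POSIXct(ifelse(pre_idx, "2019-01-01", "2020-01-01"), tz = "UTC")
    hour <- draw_hours(gold, cfg$hour_weights,
                       cfg$after_midnight_negative_odds_multiplier)
    minute <- floor(stats::runif(n) * 60)
    second <- floor(stats::runif(n) * 60)
    ts <- origin + day * 86400 + hour * 3600 + minute * 60 + second
    texts <- assemble_texts(gold)
    out <- corpus(id = sprintf("t%07d", seq_len(n)),
                  text = texts, timestamp = ts, lang = "en",
                  gold_label = gold,
                  provenance = sprintf("simulated (seed %d)", cfg$seed))
    annotate_time(out)
  })
}

#' Simulate ensemble classifier outputs for a corpus
#'
#' For each record and each mock classifier, draws the predicted tendency
#' from the classifier's confusion-matrix row for the record's gold label,
#' then a probability vector from a Dirichlet centred on that tendency.
#' Draws are conditionally independent across classifiers given the gold
#' labels (each classifier has its own derived stream).
#'
#' @param corpus A `corpus` whose records all carry `gold_label`.
#' @param classifiers Named list of [mock_params()] (at least one).
#' @param seed Master seed for the ensemble draws.
#' @return Long data.frame in probability-matrix interchange format
#'   (`id`, `model`, `p_negative`, `p_neutral`, `p_positive`).
#' @export
simulate_ensemble_outputs <- function(corpus, classifiers, seed = 1L) {
  if (length(classifiers) == 0L) stopf("need at least one classifier")
  if (is.null(names(classifiers)) || any(!nzchar(names(classifiers)))) {
    stopf("`classifiers` must be a named list")
  }
  gold <- as.character(corpus$gold_label)
  if (anyNA(gold)) stopf("every record needs a gold label")
  gi <- match(gold, sentiment_levels())
  n <- length(gold)
  per_model <- lapply(names(classifiers), function(mod) {
    params <- classifiers[[mod]]
    stopifnot(inherits(params, "mock_params"))
    with_local_seed(derive_seed(seed, paste0("ensemble-", mod)), {
      # predicted tendency per record, then Dirichlet draw centred on it
      u <- stats::runif(n)
      cum <- t(apply(params$confusion, 1, cumsum))
      k <- max.col(u <= cum[gi, , drop = FALSE], ties.method = "first")
      alpha <- matrix(1, n, 3)
      alpha[cbind(seq_len(n), k)] <- params$concentration
      g <- matrix(stats::rgamma(3L * n, shape = as.vector(alpha)), n, 3)
      p <- g / rowSums(g)
      data.frame(id = corpus$id, model = mod,
                 p_negative = p[, 1], p_neutral = p[, 2], p_positive = p[, 3],
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, per_model)
}
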