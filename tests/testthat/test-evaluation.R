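test_that("confusion matrices tally gold against predictions", {
  lv <- sentiment_levels()
  perfect <- confusion_matrix(rep(lv, 2), rep(lv, 2))
  expect_equal(sum(diag(unclass(perfect))), 6)
  expect_equal(sum(perfect) - sum(diag(unclass(perfect))), 0)

  degenerate <- confusion_matrix(rep("negative", 4), rep("positive", 4))
  expect_equal(degenerate["negative", "positive"], 4L)
  expect_equal(sum(degenerate), 4)

  gold <- c("negative", "negative", "neutral", "positive", "positive", "neutral")
  pred <- c("negative", "neutral", "neutral", "positive", "negative", "neutral")
  cm <- confusion_matrix(gold, pred)
  # hand tally: neg->neg 1, neg->neu 1, neu->neu 2, pos->pos 1, pos->neg 1
  expect_equal(cm["negative", "negative"], 1L)
  expect_equal(cm["negative", "neutral"], 1L)
  expect_equal(cm["neutral", "neutral"], 2L)
  expect_equal(cm["positive", "positive"], 1L)
  expect_equal(cm["positive", "negative"], 1L)
  expect_equal(sum(cm), 6)
  expect_error(confusion_matrix(gold, pred[-1]), "equal length")
  expect_error(confusion_matrix("negative", "angry"), "unknown label")
})

test_that("one-vs-rest metrics follow the four formulas and flag undefined ratios", {
  # build a matrix with known binary counts for 'negative':
  # TP=3, FN=2, FP=1, TN=4
  cm <- confusion_matrix(
    gold = c(rep("negative", 5), rep("neutral", 3), rep("positive", 2)),
    predicted = c("negative", "negative", "negative", "neutral", "positive",
                  "negative", "neutral", "neutral", "positive", "positive")
  )
  m <- class_metrics(cm, "negative")
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)
  expect_length(m$undefined, 0)

  perfect <- confusion_matrix(sentiment_levels(), sentiment_levels())
  for (cls in sentiment_levels()) {
    pm <- class_metrics(perfect, cls)
    expect_equal(unlist(pm[c("sensitivity", "precision", "accuracy", "f1")]),
                 c(sensitivity = 1, precision = 1, accuracy = 1, f1 = 1))
  }

  # class absent from gold and predictions: sensitivity undefined, accuracy 1
  vac <- confusion_matrix(c("negative", "neutral"), c("negative", "neutral"))
  vm <- class_metrics(vac, "positive")
  expect_true(is.na(vm$sensitivity))
  expect_true("sensitivity" %in% vm$undefined)
  expect_equal(vm$accuracy, 1)
})

test_that("overall accuracy is trace over total", {
  perfect <- confusion_matrix(rep(sentiment_levels(), 4), rep(sentiment_levels(), 4))
  expect_equal(overall_accuracy(perfect), 1)
  wrong <- confusion_matrix(rep("negative", 3), rep("positive", 3))
  expect_equal(overall_accuracy(wrong), 0)
  # a 300-record matrix with trace 241 scores 80.3%
  gold <- rep(sentiment_levels(), 100)
  pred <- gold
  pred[1:59] <- ifelse(gold[1:59] == "negative", "neutral", "negative")
  cm <- confusion_matrix(gold, pred)
  expect_equal(sum(diag(unclass(cm))), 241)
  expect_equal(round_trip <- overall_accuracy(cm), 241 / 300)
  expect_equal(round(100 * overall_accuracy(cm), 1), 80.3)
  # micro accuracy equals the independently computed exact-match fraction
  expect_equal(overall_accuracy(cm), mean(gold == pred))
})

test_that("Cohen's kappa corrects agreement for chance", {
  a <- rep(sentiment_levels(), 10)
  expect_equal(cohen_kappa(a, a), 1)
  # 2x2 agreement table [[40,10],[20,30]]: p_o = .7, p_e = .5, kappa = .4
  x <- c(rep("A", 50), rep("B", 50))
  y <- c(rep("A", 40), rep("B", 10), rep("A", 20), rep("B", 30))
  expect_equal(cohen_kappa(x, y), 0.4)
  expect_equal(cohen_kappa(y, x), 0.4)  # symmetric
  expect_warning(k <- cohen_kappa(rep("A", 5), rep("A", 5)), "undefined")
  expect_true(is.na(k))
  # independent random labels: kappa near 0 (3-sigma Monte-Carlo band)
  withr::local_seed(17)
  n <- 6000
  r1 <- sample(sentiment_levels(), n, replace = TRUE)
  r2 <- sample(sentiment_levels(), n, replace = TRUE)
  expect_lt(abs(cohen_kappa(r1, r2)), 3 * sqrt(1 / n) * 1.5)
})

test_that("kappa matches an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  withr::local_seed(23)
  for (i in 1:20) {
    a <- sample(sentiment_levels(), 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.6, a, sample(sentiment_levels(), 200, replace = TRUE))
    tab <- table(factor(a, levels = sentiment_levels()),
                 factor(b, levels = sentiment_levels()))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("ensemble sweeps score singletons and requested combinations", {
  withr::local_seed(5)
  n <- 600
  gold <- sample(sentiment_levels(), n, replace = TRUE)
  corp <- corpus(id = sprintf("r%04d", 1:n),
                 text = rep("insomnia", n),
                 timestamp = rep("2019-06-01T02:00:00Z", n),
                 gold_label = gold)
  same <- mock_params(0.75, concentration = 50, seed = 88L)
  probs <- simulate_ensemble_outputs(
    corp, list(m1 = same, m2 = same), seed = 88L)
  # two identical mock models: each record gets identical vectors twice,
  # so the fused decision equals the individual decision
  probs2 <- probs
  probs2$model <- rep(c("m1", "m2"), each = n)
  probs2[probs2$model == "m2", 3:5] <- probs2[probs2$model == "m1", 3:5]
  rep_tbl <- sweep_combinations(probs2, data.frame(id = corp$id, gold_label = gold),
                                subsets = list(c("m1", "m2")))
  acc <- rep_tbl$accuracy
  names(acc) <- rep_tbl$subset
  expect_equal(unname(acc["m1+m2"]), unname(acc["m1"]))
  expect_equal(rep_tbl$n_conflict, rep(0L, nrow(rep_tbl)))
})

test_that("independent moderately accurate models fuse to higher accuracy", {
  withr::local_seed(6)
  n <- 5000
  gold <- sample(sentiment_levels(), n, replace = TRUE)
  corp <- corpus(id = sprintf("r%05d", 1:n),
                 text = rep("insomnia", n),
                 timestamp = rep("2019-06-01T02:00:00Z", n),
                 gold_label = gold)
  mocks <- list(
    m1 = mock_params(0.7, concentration = 20, seed = 101L),
    m2 = mock_params(0.7, concentration = 20, seed = 202L),
    m3 = mock_params(0.7, concentration = 20, seed = 303L)
  )
  probs <- simulate_ensemble_outputs(corp, mocks, seed = 404L)
  rep_tbl <- sweep_combinations(probs, data.frame(id = corp$id, gold_label = gold),
                                subsets = list(c("m1", "m2", "m3")))
  accs <- setNames(rep_tbl$accuracy, rep_tbl$subset)
  best_single <- max(accs[c("m1", "m2", "m3")])
  se <- sqrt(best_single * (1 - best_single) / n)
  expect_gt(accs[["m1+m2+m3"]], best_single - 3 * se)
  expect_gt(accs[["m1+m2+m3"]], best_single)  # strict at this n and seed
})

test_that("an empty subset list yields an empty report and unknown models error", {
  probs <- data.frame(id = "a", model = "m1",
                      p_negative = 0.5, p_neutral = 0.3, p_positive = 0.2)
  expect_equal(nrow(sweep_combinations(probs, c(a = "negative"), list())), 0L)
  expect_error(sweep_combinations(probs, c(a = "negative"), list("mX")),
               "unregistered")
})
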