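# Scoring of individual and fused classifiers against gold labels:
# confusion matrices, one-vs-rest class metrics, Cohen's kappa, and
# ensemble-subset sweeps.

#' Confusion matrix of gold vs predicted labels
#'
#' @param gold,predicted Character vectors of equal length with values among
#'   [sentiment_levels()] (`NA` predictions are dropped pairwise with a
#'   warning).
#' @return 3x3 integer matrix of class `sent_confusion`; rows = gold,
#'   columns = predicted.
#' @export
confusion_matrix <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stopf("`gold` and `predicted` must have equal length")
  }
  if (length(gold) == 0L) stopf("need at least one scored record")
  keep <- !is.na(gold) & !is.na(predicted)
  if (any(!keep)) {
    warning(sprintf("dropping %d record(s) with missing labels", sum(!keep)))
    gold <- gold[keep]; predicted <- predicted[keep]
  }
  lv <- sentiment_levels()
  bad <- setdiff(unique(c(gold, predicted)), lv)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  tab <- table(factor(gold, levels = lv), factor(predicted, levels = lv))
  m <- matrix(as.integer(tab), 3, 3, dimnames = list(gold = lv, predicted = lv))
  class(m) <- c("sent_confusion", class(m))
  m
}

# One-vs-rest reduction for class `cls`.
ovr_counts <- function(cm, cls) {
  lv <- sentiment_levels()
  i <- match(cls, lv)
  if (is.na(i)) stopf("unknown class '%s'", cls)
  tp <- cm[i, i]
  fn <- sum(cm[i, -i])
  fp <- sum(cm[-i, i])
  tn <- sum(cm[-i, -i])
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Per-class evaluation metrics (one-vs-rest)
#'
#' Reduces the 3x3 confusion matrix to binary counts for one class and
#' computes sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/total` and the F1 score (harmonic mean of sensitivity and
#' precision). Ratios with a zero denominator are reported as `NA` with an
#' `undefined` flag, never coerced to 0.
#'
#' @param cm A `sent_confusion` matrix.
#' @param cls One of [sentiment_levels()].
#' @return List of class `class_metrics`: `sensitivity`, `precision`,
#'   `accuracy`, `f1` (proportions in \[0,1\] or `NA`), `undefined`
#'   (character vector naming undefined metrics) and the binary `counts`.
#' @export
class_metrics <- function(cm, cls) {
  stopifnot(inherits(cm, "sent_confusion"))
  k <- ovr_counts(cm, cls)
  total <- sum(k)
  undefined <- character()
  safe_ratio <- function(num, den, nm) {
    if (den == 0) {
      undefined <<- c(undefined, nm)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_ratio(k["TP"], k["TP"] + k["FN"], "sensitivity")
  prec <- safe_ratio(k["TP"], k["TP"] + k["FP"], "precision")
  acc <- (k["TP"] + k["TN"]) / total
  f1 <- if (is.na(sens) || is.na(prec)) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else if (sens + prec == 0) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else {
    2 * sens * prec / (sens + prec)
  }
  structure(list(class = cls,
                 sensitivity = unname(sens), precision = unname(prec),
                 accuracy = unname(acc), f1 = unname(f1),
                 undefined = unique(undefined), counts = k),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<class_metrics> %s: sensitivity %s, precision %s, accuracy %s, F1 %s\n",
              x$class, fmt(x$sensitivity), fmt(x$precision),
              fmt(x$accuracy), fmt(x$f1)))
  invisible(x)
}

#' Overall (micro) accuracy
#'
#' @param cm A `sent_confusion` matrix.
#' @return Proportion of exact matches, trace / total.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "sent_confusion"))
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  sum(diag(unclass(cm))) / total
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the two raters' marginal
#' distributions. Works for any shared label set, not only sentiments.
#'
#' @param rater_a,rater_b Equal-length label vectors.
#' @return Kappa in \[-1, 1\]; `NA` with a warning when `p_e = 1` (both
#'   raters constant and identical, agreement undefined).
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) stopf("rater vectors must have equal length")
  if (length(rater_a) == 0L) stopf("need at least one rating")
  lv <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  a <- factor(rater_a, levels = lv)
  b <- factor(rater_b, levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    warning("kappa undefined: expected agreement is 1 (constant identical raters)")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Sweep ensemble subsets and score fused accuracy
#'
#' For each named subset of models, fuses the per-record probability
#' vectors with Dempster's rule ([fuse_probs()]), decides labels, and scores
#' overall accuracy against the gold labels. Singleton subsets for every
#' individual model are always included, so the report compares each model
#' with each requested combination. Records whose combination collapses in
#' total conflict are excluded from the accuracy denominator and counted in
#' `n_conflict`.
#'
#' @param probs Long probability table (`id`, `model`, `p_negative`,
#'   `p_neutral`, `p_positive`).
#' @param gold Data frame with columns `id` and `gold_label`, or a named
#'   character vector keyed by id.
#' @param subsets List of character vectors of model names; may be empty.
#' @param discount Passed to [fuse_probs()].
#' @return Data frame of class `sweep_report` with columns `subset`,
#'   `n_models`, `n_scored`, `n_conflict`, `accuracy` (proportion) and
#'   `accuracy_pct` (percentage, one decimal).
#' @export
sweep_combinations <- function(probs, gold, subsets = list(), discount = 1) {
  if (is.data.frame(gold)) {
    if (!all(c("id", "gold_label") %in% names(gold))) {
      stopf("`gold` data frame needs columns id, gold_label")
    }
    gold_vec <- stats::setNames(as.character(gold$gold_label), as.character(gold$id))
  } else {
    gold_vec <- gold
    if (is.null(names(gold_vec))) stopf("`gold` vector must be named by id")
  }
  avail <- unique(probs$model)
  for (s in subsets) {
    unknown <- setdiff(s, avail)
    if (length(unknown)) {
      stopf("subset references unregistered model(s): %s", paste(unknown, collapse = ", "))
    }
  }
  if (length(subsets) == 0L) {
    out <- data.frame(subset = character(), n_models = integer(),
                      n_scored = integer(), n_conflict = integer(),
                      accuracy = numeric(), accuracy_pct = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("sweep_report", "data.frame")
    return(out)
  }
  singletons <- lapply(avail, identity)
  all_subsets <- c(singletons, subsets)
  rows <- lapply(all_subsets, function(s) {
    fused <- fuse_probs(probs, discount = discount, models = s)
    ok <- !fused$conflicted & fused$id %in% names(gold_vec)
    g <- gold_vec[fused$id[ok]]
    acc <- if (any(ok)) mean(fused$decision[ok] == g) else NA_real_
    data.frame(subset = paste(s, collapse = "+"),
               n_models = length(s),
               n_scored = sum(ok),
               n_conflict = sum(fused$conflicted),
               accuracy = acc,
               accuracy_pct = round_half_up(100 * acc, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_report", "data.frame")
  out
}
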