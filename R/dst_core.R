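# Dempster-Shafer machinery on the fixed three-class sentiment frame
# Theta = {negative, neutral, positive}.
#
# A BBA is stored as a numeric vector of length 8 over the explicit powerset,
# indexed by bitmask + 1 (bit 1 = negative, bit 2 = neutral, bit 3 =
# positive): element 1 is m(empty set), element 8 is m(Theta). The frame is
# fixed at three classes; masses over the explicit 8-subset powerset keep
# the combination rule transparent.

FRAME_SIZE <- 3L
N_SUBSETS <- 8L

subset_names <- function() {
  lv <- sentiment_levels()
  vapply(0:7, function(m) {
    members <- lv[bitwAnd(m, c(1L, 2L, 4L)) != 0L]
    if (length(members) == 0L) "{}" else paste0("{", paste(members, collapse = ","), "}")
  }, "")
}

#' Construct a basic belief assignment
#'
#' A basic belief assignment (BBA) over the three-sentiment frame of
#' discernment assigns a mass to every subset of
#' \{negative, neutral, positive\}, with zero mass on the empty set and
#' total mass one. Subsets with positive mass are the focal elements.
#'
#' @param masses Numeric vector of length 8 over the powerset in bitmask
#'   order (empty set, \{negative\}, \{neutral\}, \{negative,neutral\},
#'   \{positive\}, \{negative,positive\}, \{neutral,positive\}, Theta), or a
#'   named numeric vector using those subset names.
#' @param tol Tolerance for the unit-sum check.
#' @return An object of class `bba`.
#' @export
#' @examples
#' # 0.5 on {negative}, 0.3 on {negative,neutral}, 0.2 on Theta
#' b <- bba(c(0, 0.5, 0, 0.3, 0, 0, 0, 0.2))
#' belief(b, c("negative", "neutral"))
bba <- function(masses, tol = 1e-9) {
  if (!is.numeric(masses) || length(masses) != N_SUBSETS || anyNA(masses)) {
    stopf("a BBA needs %d non-missing masses over the powerset", N_SUBSETS)
  }
  m <- as.numeric(masses)
  if (abs(m[1]) > tol) stopf("m(empty set) must be 0 (got %g)", m[1])
  m[1] <- 0
  if (any(m < -tol)) stopf("masses must be non-negative")
  m[m < 0] <- 0
  if (abs(sum(m) - 1) > tol) stopf("masses must sum to 1 (got %.12f)", sum(m))
  names(m) <- subset_names()
  structure(m, class = "bba")
}

#' Vacuous BBA (total ignorance)
#'
#' All mass on the full frame Theta; the identity element of
#' [combine_bba()].
#'
#' @return A `bba`.
#' @export
vacuous_bba <- function() {
  bba(c(rep(0, N_SUBSETS - 1L), 1))
}

#' Embed a classifier probability vector as a BBA
#'
#' Singleton focal elements receive the (optionally discounted) class
#' probabilities; the reliability remainder `1 - discount` goes to Theta.
#' With `discount = 1` the BBA is a bare Bayesian embedding of the
#' probability vector.
#'
#' @param p Numeric length-3 probability vector over
#'   (negative, neutral, positive), summing to 1.
#' @param discount Reliability factor in (0, 1]; mass `1 - discount` is
#'   moved to the full frame.
#' @return A `bba` with focal elements among the singletons and Theta.
#' @export
#' @examples
#' bba_from_probs(c(0.5, 0.3, 0.2), discount = 0.8)
bba_from_probs <- function(p, discount = 1) {
  assert_prob_vector(p)
  if (!is.numeric(discount) || length(discount) != 1L ||
      is.na(discount) || discount <= 0 || discount > 1) {
    stopf("`discount` must lie in (0, 1]")
  }
  m <- numeric(N_SUBSETS)
  m[c(2L, 3L, 5L)] <- discount * p  # singleton bitmasks 1, 2, 4
  m[8L] <- 1 - discount
  # guard against floating residue
  m[8L] <- m[8L] + (1 - sum(m))
  bba(m)
}

#' Belief function
#'
#' The belief committed to a subset: the sum of masses of all its nonempty
#' subsets, `bel(A) = sum over nonempty B subset of A of m(B)`.
#'
#' @param b A `bba`.
#' @param subset Character vector of hypotheses (a nonempty subset of
#'   [sentiment_levels()]), or an integer bitmask 1-7.
#' @return Belief value in \[0, 1\].
#' @export
belief <- function(b, subset) {
  stopifnot(inherits(b, "bba"))
  mask <- subset_to_mask(subset)
  if (mask == 0L) stopf("belief of the empty set is not defined")
  idx <- which(vapply(0:7, function(s) s != 0L && bitwAnd(s, mask) == s, TRUE))
  sum(b[idx])
}

subset_to_mask <- function(subset) {
  if (is.numeric(subset)) {
    mask <- as.integer(subset)
    if (mask < 0L || mask > 7L) stopf("subset bitmask must be in 0..7")
    return(mask)
  }
  lv <- sentiment_levels()
  if (!all(subset %in% lv)) {
    stopf("unknown hypothesis: %s", paste(setdiff(subset, lv), collapse = ", "))
  }
  sum(c(1L, 2L, 4L)[lv %in% subset])
}

#' Dempster's rule of combination (orthogonal sum)
#'
#' Combines two BBAs by intersecting focal elements and multiplying masses:
#' the combined mass on a nonempty subset A is proportional to the total
#' product mass of pairs whose intersection is A, renormalised by `1 - K`,
#' where the conflict `K` is the total product mass falling on empty
#' intersections. Total conflict (`K` within `1e-12` of 1, e.g. two
#' contradictory point masses) is an error, not a silent renormalisation.
#'
#' @param m1,m2 `bba` objects on the same frame.
#' @param sources Optional character names of the two inputs, used in the
#'   conflict error message and recorded in the result.
#' @return A list of class `dst_combination` with elements `combined`
#'   (a `bba`), `conflict` (K in \[0, 1)) and `sources`.
#' @export
#' @examples
#' m1 <- bba_from_probs(c(0.6, 0.3, 0.1))
#' m2 <- bba_from_probs(c(0.5, 0.3, 0.2))
#' combine_bba(m1, m2)  # conflict K = 0.59
combine_bba <- function(m1, m2, sources = c("m1", "m2")) {
  stopifnot(inherits(m1, "bba"), inherits(m2, "bba"))
  prod_mat <- outer(as.numeric(m1), as.numeric(m2))
  inter <- outer(0:7, 0:7, bitwAnd)
  raw <- vapply(0:7, function(s) sum(prod_mat[inter == s]), 0)
  K <- raw[1]
  if (K >= 1 - 1e-12) {
    stopf("total conflict (K = %.15f) combining %s and %s",
          K, sources[1], sources[2])
  }
  comb <- raw / (1 - K)
  comb[1] <- 0
  res <- list(combined = bba(comb / sum(comb)), conflict = K,
              sources = sources)
  class(res) <- "dst_combination"
  res
}

#' Combine a sequence of BBAs
#'
#' Left fold of [combine_bba()]. Dempster's rule is commutative and
#' associative, so the combined masses do not depend on input order. The
#' reported `conflict` is the conflict of the final pairwise step (the
#' accumulated evidence against the last input); `step_conflicts` records
#' every pairwise K.
#'
#' @param bbas List of `bba` objects (at least one).
#' @param sources Optional character names, one per input.
#' @return A `dst_combination`; for a single input, the input itself with
#'   zero conflict.
#' @export
combine_all <- function(bbas, sources = NULL) {
  if (!is.list(bbas) || length(bbas) == 0L) stopf("need at least one BBA")
  if (is.null(sources)) sources <- paste0("bba", seq_along(bbas))
  acc <- bbas[[1]]
  stopifnot(inherits(acc, "bba"))
  ks <- numeric(0)
  acc_name <- sources[1]
  if (length(bbas) > 1L) {
    for (i in 2:length(bbas)) {
      step <- tryCatch(
        combine_bba(acc, bbas[[i]], sources = c(acc_name, sources[i])),
        error = function(e) {
          stopf("combination degenerated at step %d (%s + %s): %s",
                i - 1L, acc_name, sources[i], conditionMessage(e))
        }
      )
      acc <- step$combined
      ks <- c(ks, step$conflict)
      acc_name <- paste0(acc_name, "+", sources[i])
    }
  }
  res <- list(combined = acc,
              conflict = if (length(ks)) ks[length(ks)] else 0,
              step_conflicts = ks,
              sources = sources)
  class(res) <- "dst_combination"
  res
}

#' Decide a sentiment label from a BBA
#'
#' Returns the singleton hypothesis with maximal belief (equal to maximal
#' singleton mass when all focal elements are singletons). Ties are broken
#' by canonical order (negative, neutral, positive) and flagged.
#'
#' @param b A `bba`, or a `dst_combination` (its `combined` BBA is used).
#' @param tol Tie tolerance on belief values.
#' @return Length-1 character label with attribute `tie` (logical).
#' @export
decide <- function(b, tol = 1e-12) {
  if (inherits(b, "dst_combination")) b <- b$combined
  stopifnot(inherits(b, "bba"))
  lv <- sentiment_levels()
  bel <- vapply(lv, function(h) belief(b, h), 0)
  top <- max(bel)
  winners <- which(bel >= top - tol)
  out <- lv[winners[1]]
  attr(out, "tie") <- length(winners) > 1L
  out
}

#' @export
print.bba <- function(x, ...) {
  cat("<bba> focal elements:\n")
  foc <- x[x > 0]
  if (length(foc) == 0L) cat("  (none)\n")
  for (i in seq_along(foc)) {
    cat(sprintf("  m(%s) = %.6f\n", names(foc)[i], foc[i]))
  }
  invisible(x)
}

#' @export
print.dst_combination <- function(x, ...) {
  cat(sprintf("<dst_combination> of %s (conflict K = %.4f)\n",
              paste(x$sources, collapse = " + "), x$conflict))
  print(x$combined)
  invisible(x)
}

#' Fuse per-model probability tables into decisions
#'
#' Takes a long probability table (one row per record x model) and combines
#' each record's model outputs with Dempster's rule. Records whose
#' combination degenerates to total conflict get `NA` masses and decision
#' and `conflicted = TRUE` rather than aborting the batch.
#'
#' @param probs Data frame with columns `id`, `model`, `p_negative`,
#'   `p_neutral`, `p_positive` (the interchange format written by
#'   [write_prob_matrix()]).
#' @param discount Reliability discount passed to [bba_from_probs()];
#'   either a single value or a named vector keyed by model name.
#' @param models Optional subset of model names to fuse (default: all
#'   models present).
#' @return Data frame with one row per id: fused singleton masses
#'   `m_negative`, `m_neutral`, `m_positive`, `m_theta`, the final-step
#'   `conflict`, the `decision`, `tie_flag` and `conflicted`.
#' @export
fuse_probs <- function(probs, discount = 1, models = NULL) {
  req <- c("id", "model", "p_negative", "p_neutral", "p_positive")
  missing_cols <- setdiff(req, names(probs))
  if (length(missing_cols)) {
    stopf("probability table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(models)) models <- unique(probs$model)
  probs <- probs[probs$model %in% models, , drop = FALSE]
  if (nrow(probs) == 0L) stopf("no rows for requested models")
  disc_for <- function(mod) {
    if (length(discount) == 1L && is.null(names(discount))) return(discount)
    d <- discount[[mod]]
    if (is.null(d)) stopf("no discount given for model '%s'", mod)
    d
  }
  ids <- unique(probs$id)
  idx_by_id <- split(seq_len(nrow(probs)), factor(probs$id, levels = ids))
  pm <- as.matrix(probs[, c("p_negative", "p_neutral", "p_positive")])
  n <- length(ids)
  out <- data.frame(
    id = ids,
    m_negative = NA_real_, m_neutral = NA_real_, m_positive = NA_real_,
    m_theta = NA_real_, conflict = NA_real_, decision = NA_character_,
    tie_flag = NA, conflicted = FALSE, stringsAsFactors = FALSE
  )
  for (r in seq_len(n)) {
    idx <- idx_by_id[[r]]
    bbas <- lapply(idx, function(i) {
      bba_from_probs(pm[i, ], discount = disc_for(probs$model[i]))
    })
    res <- tryCatch(combine_all(bbas, sources = probs$model[idx]),
                    error = function(e) NULL)
    if (is.null(res)) {
      out$conflicted[r] <- TRUE
      next
    }
    m <- res$combined
    d <- decide(m)
    out$m_negative[r] <- m[[2]]
    out$m_neutral[r] <- m[[3]]
    out$m_positive[r] <- m[[5]]
    out$m_theta[r] <- m[[8]]
    out$conflict[r] <- res$conflict
    out$decision[r] <- as.character(d)
    out$tie_flag[r] <- isTRUE(attr(d, "tie"))
  }
  out
}
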