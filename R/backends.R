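# Classifier backends: a uniform contract for probabilistic three-class
# sentiment classifiers. External pretrained models are reached only through
# an adapter slot (a user-supplied function); the package itself ships a
# seeded mock classifier parameterised by a 3x3 confusion matrix, so the
# whole pipeline builds and tests without any model download.

#' Mock-classifier parameters
#'
#' A mock classifier is defined by a 3x3 row-stochastic confusion matrix
#' (rows = true label, columns = predicted tendency, in canonical order), a
#' Dirichlet concentration controlling how sharp its probability outputs
#' are, and a seed.
#'
#' @param confusion 3x3 matrix with non-negative entries and unit row sums.
#'   A single number `a` is shorthand for the symmetric matrix with `a` on
#'   the diagonal and `(1-a)/2` off it.
#' @param concentration Positive real; the Dirichlet parameter on the
#'   predicted-tendency class (others get 1). Large values give near-one-hot
#'   outputs; the default 20 is sharp but non-degenerate.
#' @param seed Integer seed for the classifier's private stream.
#' @return An object of class `mock_params`.
#' @export
mock_params <- function(confusion, concentration = 20, seed = 1L) {
  if (is.numeric(confusion) && length(confusion) == 1L) {
    a <- confusion
    if (is.na(a) || a < 0 || a > 1) stopf("scalar confusion must be in [0, 1]")
    confusion <- matrix((1 - a) / 2, 3, 3)
    diag(confusion) <- a
  }
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3L, 3L)) || anyNA(confusion) || any(confusion < 0)) {
    stopf("`confusion` must be a non-negative 3x3 matrix")
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stopf("confusion rows must each sum to 1")
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stopf("`concentration` must be > 0")
  }
  dimnames(confusion) <- list(sentiment_levels(), sentiment_levels())
  structure(list(confusion = confusion, concentration = concentration,
                 seed = as.integer(seed)),
            class = "mock_params")
}

#' Classifier specification
#'
#' @param name Unique model name within an ensemble.
#' @param kind `"mock"` (seeded synthetic classifier) or
#'   `"external_adapter"` (a user-supplied function
#'   `function(text) -> length-3 probability vector`).
#' @param params A [mock_params()] object for mocks, or the adapter
#'   function for external adapters.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, kind = c("mock", "external_adapter"), params) {
  kind <- match.arg(kind)
  if (!is_string(name) || !nzchar(name)) stopf("`name` must be a nonempty string")
  if (kind == "mock" && !inherits(params, "mock_params")) {
    stopf("mock classifier needs `params` from mock_params()")
  }
  if (kind == "external_adapter" && !is.function(params)) {
    stopf("external adapter unavailable: supply a function(text) -> prob vector, or use a mock classifier")
  }
  structure(list(name = name, kind = kind, params = params),
            class = "classifier_spec")
}

#' Map a five-star review distribution to three sentiment classes
#'
#' Star ratings 1-2 count as negative, 3 as neutral, 4-5 as positive:
#' `p_negative = s1 + s2`, `p_neutral = s3`, `p_positive = s4 + s5`. Total
#' probability is preserved exactly.
#'
#' @param stars Numeric length-5 probability vector over 1..5 stars.
#' @return Named length-3 probability vector over
#'   (negative, neutral, positive).
#' @export
#' @examples
#' map_five_star_to_three(c(0.1, 0.1, 0.3, 0.3, 0.2))  # (0.2, 0.3, 0.5)
map_five_star_to_three <- function(stars) {
  if (!is.numeric(stars) || length(stars) != 5L || anyNA(stars)) {
    stopf("`stars` must be 5 non-missing probabilities")
  }
  if (any(stars < -1e-9) || any(stars > 1 + 1e-9) || abs(sum(stars) - 1) > 1e-9) {
    stopf("`stars` must be a probability vector summing to 1")
  }
  p <- c(negative = stars[1] + stars[2],
         neutral = stars[3],
         positive = stars[4] + stars[5])
  p
}

# Dirichlet draw centred on class `k`: alpha = 1 everywhere except
# `concentration` on k. Mean -> point mass on k as concentration grows.
rdirichlet_centered <- function(k, concentration) {
  alpha <- c(1, 1, 1)
  alpha[k] <- concentration
  g <- stats::rgamma(3L, shape = alpha, rate = 1)
  g / sum(g)
}

#' Draw a mock classifier output for a gold label
#'
#' Draws the classifier's predicted tendency from the confusion-matrix row
#' of the gold label, then draws a probability vector from a Dirichlet
#' distribution centred on that tendency. Reproducible: the same
#' `params$seed` (xor any `salt`) gives the same draw.
#'
#' @param gold Gold sentiment label (one of [sentiment_levels()]).
#' @param params A [mock_params()] object.
#' @param salt Optional integer folded into the seed so successive records
#'   get independent draws from one classifier seed.
#' @return Named length-3 probability vector.
#' @export
mock_classify <- function(gold, params, salt = 0L) {
  stopifnot(inherits(params, "mock_params"))
  gi <- match(gold, sentiment_levels())
  if (is.na(gi)) stopf("unknown gold label '%s'", gold)
  with_local_seed(derive_seed(params$seed, paste0("draw", salt)), {
    k <- sample.int(3L, 1L, prob = params$confusion[gi, ])
    p <- rdirichlet_centered(k, params$concentration)
    names(p) <- sentiment_levels()
    p
  })
}

#' Classify a text with a classifier spec
#'
#' For an external adapter, calls the adapter function on the text and
#' validates its output. For a mock, the output depends deterministically on
#' the spec and the text: the text is hashed into the mock's seed, and the
#' `gold` argument (required for mocks) selects the confusion row.
#'
#' @param text Nonempty character scalar (cleaned text).
#' @param spec A [classifier_spec()].
#' @param gold Gold label, required when `spec$kind == "mock"`.
#' @return Named length-3 probability vector summing to 1.
#' @export
classify <- function(text, spec, gold = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!is_string(text) || !nzchar(trimws(text))) {
    stopf("`text` must be nonempty after cleaning")
  }
  if (spec$kind == "external_adapter") {
    p <- spec$params(text)
    assert_prob_vector(p, what = sprintf("output of adapter '%s'", spec$name))
    names(p) <- sentiment_levels()
    return(p)
  }
  if (is.null(gold)) stopf("mock classifier '%s' needs a gold label", spec$name)
  text_salt <- sum(utf8ToInt(text) * (seq_along(utf8ToInt(text)) %% 97L + 1L)) %% 1000003L
  mock_classify(gold, spec$params, salt = text_salt)
}

#' Read / write the per-model probability-matrix interchange file
#'
#' CSV with columns `id`, `model`, `p_negative`, `p_neutral`, `p_positive`;
#' the format exchanged between classification and fusion.
#'
#' @param path File path.
#' @return `read_prob_matrix`: a data.frame in interchange format.
#' @export
read_prob_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "model", "p_negative", "p_neutral", "p_positive")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stopf("probability matrix lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df
}

#' @param probs Data frame in interchange format.
#' @rdname read_prob_matrix
#' @return `write_prob_matrix`: `path`, invisibly.
#' @export
write_prob_matrix <- function(probs, path) {
  utils::write.csv(probs, path, row.names = FALSE)
  invisible(path)
}
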