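#' @keywords internal
"_PACKAGE"

#' Canonical sentiment levels
#'
#' The three-class sentiment frame used throughout the package, in canonical
#' order. All label columns are matched against these values.
#'
#' @return Character vector `c("negative", "neutral", "positive")`.
#' @export
#' @examples
#' sentiment_levels()
sentiment_levels <- function() c("negative", "neutral", "positive")

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. Mersenne-Twister/Inversion is pinned so streams
# are identical across platforms and R sessions.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Derive a child seed from a parent seed and a string tag; keeps independent
# substreams (per model, per stage) reproducible from one user-facing seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Round half away from zero (display convention for percentages).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Truncate toward zero at `digits` decimals (display convention for ORs).
trunc_digits <- function(x, digits = 2) {
  m <- 10^digits
  trunc(x * m) / m
}

#' Format a ratio estimate for display
#'
#' Formats an odds ratio (or any positive ratio) to a fixed number of
#' decimals, either rounding or truncating toward zero. Truncation matches
#' the display convention of reports that drop trailing digits rather than
#' rounding them.
#'
#' @param x Numeric value(s).
#' @param digits Number of decimals (default 2).
#' @param mode `"round"` (default) or `"truncate"`.
#' @return Character vector of formatted values.
#' @export
#' @examples
#' format_ratio(1.3979, mode = "truncate")  # "1.39"
#' format_ratio(1.3979, mode = "round")     # "1.40"
format_ratio <- function(x, digits = 2, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  v <- if (mode == "truncate") trunc_digits(x, digits) else round_half_up(x, digits)
  formatC(v, digits = digits, format = "f")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_prob_vector <- function(p, tol = 1e-9, what = "probability vector") {
  if (!is.numeric(p) || length(p) != 3L || anyNA(p)) {
    stopf("%s must be 3 non-missing numbers", what)
  }
  if (any(p < -tol) || any(p > 1 + tol)) {
    stopf("%s components must lie in [0, 1]", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("%s must sum to 1 (got %.12f)", what, sum(p))
  }
  invisible(p)
}
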