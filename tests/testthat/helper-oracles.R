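# Independent oracles and fixture builders shared across test files.
# The DST oracle below works on explicit character subsets with set
# operations; it shares no code with the package's bitmask implementation.

ALL_SUBSETS <- local({
  lv <- c("negative", "neutral", "positive")
  subs <- list(character(0))
  for (k in 1:3) subs <- c(subs, combn(lv, k, simplify = FALSE))
  subs
})

# BBA as a list(subsets = list of character vectors, masses = numeric).
oracle_bba <- function(masses8) {
  # masses8 in the package's bitmask order; re-expressed as explicit sets
  lv <- c("negative", "neutral", "positive")
  subs <- lapply(0:7, function(m) lv[bitwAnd(m, c(1L, 2L, 4L)) != 0L])
  list(subsets = subs, masses = as.numeric(masses8))
}

same_set <- function(a, b) length(a) == length(b) && setequal(a, b)

# Brute-force Dempster combination: enumerate all 8 x 8 subset pairs,
# intersect, accumulate, renormalise by 1 - K.
oracle_combine <- function(b1, b2) {
  masses <- numeric(8)
  K <- 0
  for (j in seq_along(b1$subsets)) {
    for (k in seq_along(b2$subsets)) {
      w <- b1$masses[j] * b2$masses[k]
      if (w == 0) next
      inter <- intersect(b1$subsets[[j]], b2$subsets[[k]])
      if (length(inter) == 0L) {
        K <- K + w
      } else {
        idx <- which(vapply(b1$subsets, same_set, TRUE, b = inter))
        masses[idx] <- masses[idx] + w
      }
    }
  }
  list(masses = masses / (1 - K), conflict = K)
}

# Brute-force belief: sum masses over nonempty sub-subsets.
oracle_belief <- function(b, subset) {
  tot <- 0
  for (j in seq_along(b$subsets)) {
    s <- b$subsets[[j]]
    if (length(s) > 0L && all(s %in% subset)) tot <- tot + b$masses[j]
  }
  tot
}

# Closed form for singleton-only BBAs: normalised elementwise product.
oracle_singleton_fuse <- function(prob_list) {
  prod <- Reduce(`*`, prob_list)
  prod / sum(prod)
}

# Random valid BBA over the full powerset (masses Dirichlet-ish via gamma).
random_bba_masses <- function(full_powerset = TRUE) {
  g <- rgamma(8, shape = 1)
  g[1] <- 0
  if (!full_powerset) g[sample(2:8, 3)] <- 0
  g / sum(g)
}

# Small in-memory corpus fixture.
tiny_corpus <- function() {
  corpus(
    id = c("a1", "a2", "a3", "a4", "a5", "a6"),
    text = c("Insomnia again tonight", "cannot sleep at all",
             "my #insomnia diary https://t.co/x", "I'm an insomniac",
             "insomnia much better now", "l'insomnie me tue"),
    timestamp = c("2019-06-15T10:00:00Z", "2019-07-01T23:10:00Z",
                  "2020-03-20T02:30:00Z", "2020-06-01T13:05:00Z",
                  "2020-11-11T00:30:00Z", "2019-02-02T08:00:00Z"),
    lang = c("en", "en", "en", "en", "en", "fr"),
    gold_label = c("negative", "negative", "neutral", "negative",
                   "positive", "negative")
  )
}
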