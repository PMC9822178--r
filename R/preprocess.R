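# Tweet text cleaning. Order matters: URLs are stripped before punctuation
# so URL fragments cannot survive later steps.

# Textual emoticons removed as whole tokens (fixed list, escaped literally).
EMOTICON_PATTERNS <- c(
  ":)", ":-)", ":(", ":-(", ":D", ":-D", ":P", ":-P", ";)", ";-)",
  ":'(", ":o", ":O", ":/", ":-/", ":|", "<3", "</3", "xD", "XD",
  "=)", "=(", "^_^", "-_-", "o_O", "T_T", ":3"
)

# Unicode emoji / pictograph blocks (PCRE, perl = TRUE):
# misc symbols & dingbats, emoticons, transport, supplemental pictographs,
# flags (regional indicators), variation selectors, skin-tone modifiers.
EMOJI_CLASS <- paste0(
  "(*UTF)[",  # force PCRE UTF mode even for all-ASCII subjects
  "\\x{2190}-\\x{21FF}",  # arrows
  "\\x{2600}-\\x{27BF}",  # misc symbols, dingbats
  "\\x{2B00}-\\x{2BFF}",
  "\\x{FE00}-\\x{FE0F}",  # variation selectors
  "\\x{1F000}-\\x{1FAFF}", # emoticons, pictographs, transport, supplement
  "\\x{1FB00}-\\x{1FBFF}",
  "]"
)

#' Clean raw tweet text
#'
#' Applies, in order: (1) strip URLs (`http(s)://...` and bare `t.co/...`
#' short links); (2) strip `@mentions`; (3) strip a leading `RT` retweet
#' marker; (4) drop the `#` sigil but keep the hashtag word (or drop whole
#' hashtag tokens with `keep_hashtag_words = FALSE`); (5) remove emoji
#' codepoints and a fixed list of textual emoticons; (6) remove remaining
#' characters other than letters, digits and sentence punctuation
#' (`. , ! ? ' -`); (7) collapse runs of whitespace and trim. Cleaning is
#' idempotent and never lengthens a string.
#'
#' @param x Character vector of raw texts.
#' @param keep_hashtag_words Keep the word of a hashtag, dropping only the
#'   `#` sigil (default `TRUE`); `FALSE` removes the whole token.
#' @return Character vector of cleaned texts (no URLs survive).
#' @export
#' @examples
#' clean_text("Can't sleep \U0001F629 #insomnia again... https://t.co/xyz @friend")
clean_text <- function(x, keep_hashtag_words = TRUE) {
  if (length(x) == 0L) return(character())
  x <- as.character(x)
  x <- enc2utf8(x)
  # (1) URLs
  x <- gsub("(https?://\\S+)|(\\bt\\.co/\\S+)|(\\bwww\\.\\S+)", " ", x,
            perl = TRUE, ignore.case = TRUE)
  # (2) mentions
  x <- gsub("@[A-Za-z0-9_]+", " ", x, perl = TRUE)
  # (3) leading retweet marker(s)
  x <- sub("^\\s*(RT\\b:?\\s*)+", " ", x, perl = TRUE)
  # (4) hashtags
  if (keep_hashtag_words) {
    x <- gsub("#", " ", x, fixed = TRUE)
  } else {
    x <- gsub("#\\S+", " ", x, perl = TRUE)
  }
  # (5) emoji and textual emoticons
  x <- gsub(EMOJI_CLASS, " ", x, perl = TRUE)
  for (pat in EMOTICON_PATTERNS) {
    x <- gsub(pat, " ", x, fixed = TRUE)
  }
  # (6) restrict character set
  x <- gsub("[^A-Za-z0-9.,!?'\\s-]", " ", x, perl = TRUE)
  # (7) collapse whitespace; re-apply the retweet-marker strip in case an
  # earlier removal (emoticon, hashtag, mention) exposed a leading "RT" —
  # keeps cleaning idempotent
  x <- trimws(gsub("\\s+", " ", x, perl = TRUE))
  x <- sub("^(RT\\b:?\\s*)+", "", x, perl = TRUE)
  trimws(x)
}

#' Count words in a text
#'
#' Number of whitespace-delimited tokens; empty or all-whitespace input
#' counts zero.
#'
#' @param x Character vector.
#' @return Integer vector of token counts.
#' @export
#' @examples
#' word_count("a b c")  # 3
word_count <- function(x) {
  if (length(x) == 0L) return(integer())
  x <- trimws(as.character(x))
  n <- lengths(strsplit(x, "\\s+", perl = TRUE))
  n[!nzchar(x) | is.na(x)] <- 0L
  as.integer(n)
}

#' Add cleaned text to a corpus
#'
#' @param x A `corpus`.
#' @param keep_hashtag_words Passed to [clean_text()].
#' @return The corpus with a `clean_text` column.
#' @export
preprocess_corpus <- function(x, keep_hashtag_words = TRUE) {
  x$clean_text <- clean_text(x$text, keep_hashtag_words = keep_hashtag_words)
  x
}
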