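# Corpus I/O, inclusion filtering, and time-derived annotations.
#
# A corpus is a data.frame (class "corpus") with columns:
#   id (character), text (character), timestamp (POSIXct, UTC),
#   lang (character or NA), gold_label (character or NA),
# and optionally clean_text, period, bucket added by downstream steps.
# Attribute "provenance" carries a free-text source note; attribute
# "errors" (from read_corpus) is a data.frame of rejected rows.

CORPUS_REQUIRED <- c("id", "text", "timestamp")

#' Build a corpus from in-memory vectors
#'
#' @param id Character vector of unique record ids.
#' @param text Character vector of raw texts.
#' @param timestamp `POSIXct` vector (UTC) or ISO-8601 strings.
#' @param lang Optional 2-letter language codes (`NA` allowed).
#' @param gold_label Optional gold sentiment labels among
#'   [sentiment_levels()] (`NA` allowed).
#' @param provenance Free-text source note stored as an attribute.
#' @return A `corpus` data.frame.
#' @export
corpus <- function(id, text, timestamp, lang = NA_character_,
                   gold_label = NA_character_, provenance = "in-memory") {
  n <- length(id)
  id <- as.character(id)
  if (n > 0 && (anyNA(id) || any(!nzchar(id)))) stopf("record ids must be nonempty")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stopf("duplicate record id(s): %s", paste(dup, collapse = ", "))
  }
  ts <- parse_timestamp(timestamp)
  if (anyNA(ts) && n > 0) {
    bad <- id[is.na(ts)]
    stopf("unparseable timestamp for id(s): %s", paste(bad, collapse = ", "))
  }
  gl <- as.character(gold_label)
  bad_lab <- !is.na(gl) & !(gl %in% sentiment_levels())
  if (any(bad_lab)) {
    stopf("invalid gold_label value(s): %s",
          paste(unique(gl[bad_lab]), collapse = ", "))
  }
  out <- data.frame(
    id = id,
    text = as.character(text),
    timestamp = ts,
    lang = rep_len(as.character(lang), n),
    gold_label = rep_len(gl, n),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("corpus", "data.frame")
  out
}

# Parse ISO-8601 timestamps to POSIXct UTC. Accepts "YYYY-MM-DDTHH:MM:SS[Z]",
# the space-separated variant, and bare dates. Returns NA for failures.
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  x2 <- sub("Z$", "", x)
  x2 <- sub("T", " ", x2, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x2)), origin = "1970-01-01", tz = "UTC")
  # element-wise format fallback: a malformed row must not poison the batch
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x2)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x2[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read a tweet-record corpus from JSONL or CSV
#'
#' JSONL input has one object per line with keys `id`, `text`, `timestamp`
#' (ISO-8601) and optionally `lang` and `gold_label`. CSV input has the same
#' columns with a header row. Malformed rows (unparseable timestamp, empty
#' id, invalid label) are not silently dropped: they are collected into an
#' error report attached as `attr(corpus, "errors")`, a data.frame with
#' columns `id` and `problem`. Structural problems (a missing required
#' column, duplicate ids) abort with an informative error.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return A `corpus`; rejected rows in `attr(, "errors")`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(empty_corpus(provenance = path))
    }
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    df <- data.frame(
      id = vapply(rows, function(r) as.character(r$id %||% NA_character_), ""),
      text = vapply(rows, function(r) as.character(r$text %||% NA_character_), ""),
      timestamp = vapply(rows, function(r) as.character(r$timestamp %||% NA_character_), ""),
      lang = vapply(rows, function(r) as.character(r$lang %||% NA_character_), ""),
      gold_label = vapply(rows, function(r) as.character(r$gold_label %||% NA_character_), ""),
      stringsAsFactors = FALSE
    )
    missing_keys <- CORPUS_REQUIRED[vapply(CORPUS_REQUIRED, function(k) all(is.na(df[[k]])), TRUE)]
    if (length(missing_keys) && nrow(df) > 0) {
      stopf("missing required field(s) in %s: %s", path,
            paste(missing_keys, collapse = ", "))
    }
  } else {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8",
                          check.names = TRUE)
    missing_cols <- setdiff(CORPUS_REQUIRED, names(df))
    if (length(missing_cols)) {
      stopf("missing required column(s) in %s: %s", path,
            paste(missing_cols, collapse = ", "))
    }
    if (nrow(df) == 0L) return(empty_corpus(provenance = path))
    if (!"lang" %in% names(df)) df$lang <- rep(NA_character_, nrow(df))
    if (!"gold_label" %in% names(df)) df$gold_label <- rep(NA_character_, nrow(df))
  }

  df$lang[!is.na(df$lang) & !nzchar(df$lang)] <- NA_character_
  df$gold_label[!is.na(df$gold_label) & !nzchar(df$gold_label)] <- NA_character_

  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stopf("duplicate record id(s): %s", paste(dup, collapse = ", "))
  }

  ts <- parse_timestamp(df$timestamp)
  problems <- character(nrow(df))
  problems[is.na(df$id) | !nzchar(df$id)] <- "empty id"
  problems[is.na(ts) & problems == ""] <- "unparseable timestamp"
  bad_lab <- !is.na(df$gold_label) & !(df$gold_label %in% sentiment_levels())
  problems[bad_lab & problems == ""] <- "invalid gold_label"

  ok <- problems == ""
  out <- corpus(df$id[ok], df$text[ok], ts[ok], df$lang[ok],
                df$gold_label[ok], provenance = path)
  if (any(!ok)) {
    attr(out, "errors") <- data.frame(
      id = ifelse(nzchar(df$id[!ok]) & !is.na(df$id[!ok]), df$id[!ok], "<missing>"),
      problem = problems[!ok],
      stringsAsFactors = FALSE
    )
  }
  out
}

empty_corpus <- function(provenance = "empty") {
  corpus(character(), character(),
         as.POSIXct(character(), tz = "UTC"), provenance = provenance)
}

#' Write a corpus to JSONL or CSV
#'
#' Field-for-field inverse of [read_corpus()]: a read-write-read round trip
#' preserves ids, texts, timestamps, language codes and gold labels in
#' order. Timestamps are serialised as ISO-8601 UTC (`...T...Z`). Derived
#' columns (`clean_text`, `period`, `bucket`), if present, are written too.
#'
#' @param x A `corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- as.data.frame(x)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v[[1]]), TRUE)]
      jsonlite::toJSON(row, auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Apply the study inclusion filter
#'
#' Keeps records whose text contains `keyword` as a word-boundary token
#' (case-insensitive, matched on cleaned text so that e.g. `#insomnia`
#' matches after the hashtag sigil is stripped) and whose `lang` field, when
#' present, equals `lang`. Records with a missing `lang` are not excluded on
#' language. Matching is token-based: "insomnia" does not match
#' "insomniac".
#'
#' @param x A `corpus`.
#' @param keyword Inclusion keyword (default `"insomnia"`).
#' @param lang Required language code (default `"en"`).
#' @return The filtered `corpus`; `attr(, "exclusions")` is a named count
#'   vector with reasons `keyword` and `lang`.
#' @export
filter_inclusion <- function(x, keyword = "insomnia", lang = "en") {
  if (!is_string(keyword) || !nzchar(keyword)) stopf("`keyword` must be a nonempty string")
  cleaned <- tolower(vapply(x$text, clean_text, "", USE.NAMES = FALSE))
  pat <- paste0("\\b", tolower(keyword), "\\b")
  has_kw <- grepl(pat, cleaned, perl = TRUE)
  lang_ok <- is.na(x$lang) | x$lang == lang
  keep <- has_kw & lang_ok
  excl <- c(keyword = sum(!has_kw), lang = sum(has_kw & !lang_ok))
  out <- x[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(x, "provenance")
  attr(out, "exclusions") <- excl
  class(out) <- c("corpus", "data.frame")
  out
}

#' Assign study period from a UTC timestamp
#'
#' Periods are half-open calendar-year windows:
#' prepandemic `[2019-01-01, 2020-01-01)` and peripandemic
#' `[2020-01-01, 2021-01-01)`, so the shared boundary instant
#' 2020-01-01T00:00Z belongs to the peripandemic window only. Instants
#' outside both windows map to `"out_of_window"`.
#'
#' @param timestamp `POSIXct` (UTC) or ISO-8601 strings.
#' @return Character vector among
#'   `c("prepandemic", "peripandemic", "out_of_window")`.
#' @export
#' @examples
#' assign_period("2019-06-15T10:00:00Z")
#' assign_period("2020-01-01T00:00:00Z")  # boundary -> peripandemic
assign_period <- function(timestamp) {
  ts <- parse_timestamp(timestamp)
  if (anyNA(ts)) stopf("unparseable timestamp")
  t0 <- as.POSIXct("2019-01-01", tz = "UTC")
  t1 <- as.POSIXct("2020-01-01", tz = "UTC")
  t2 <- as.POSIXct("2021-01-01", tz = "UTC")
  out <- rep("out_of_window", length(ts))
  out[ts >= t0 & ts < t1] <- "prepandemic"
  out[ts >= t1 & ts < t2] <- "peripandemic"
  out
}

#' Assign before/after-midnight clock bucket
#'
#' Local hours 13-23 (1 PM to midnight) map to `"before_midnight"`; local
#' hours 0-12 map to `"after_midnight"`. The span 1 AM to noon leaves the
#' midnight-to-1AM hour unassigned by its literal reading; those posts are
#' literally after midnight, so hour 0 is assigned to `"after_midnight"`.
#' Timestamps are UTC; `tz_offset_minutes` shifts to a local clock when a
#' fixed offset is known.
#'
#' @param timestamp `POSIXct` (UTC) or ISO-8601 strings.
#' @param tz_offset_minutes Fixed offset added before taking the local hour;
#'   must lie within +/- 14 hours.
#' @return Character vector among `c("before_midnight", "after_midnight")`.
#' @export
assign_clock_bucket <- function(timestamp, tz_offset_minutes = 0) {
  if (abs(tz_offset_minutes) > 14 * 60) stopf("|tz_offset_minutes| must be <= 840")
  ts <- parse_timestamp(timestamp)
  if (anyNA(ts)) stopf("unparseable timestamp")
  local <- ts + tz_offset_minutes * 60
  h <- as.integer(format(local, "%H", tz = "UTC"))
  ifelse(h >= 13, "before_midnight", "after_midnight")
}

#' Annotate a corpus with derived time fields
#'
#' Adds `period` ([assign_period()]) and `bucket`
#' ([assign_clock_bucket()]) columns.
#'
#' @param x A `corpus`.
#' @param tz_offset_minutes Passed to [assign_clock_bucket()].
#' @return The corpus with `period` and `bucket` columns.
#' @export
annotate_time <- function(x, tz_offset_minutes = 0) {
  x$period <- assign_period(x$timestamp)
  x$bucket <- assign_clock_bucket(x$timestamp, tz_offset_minutes)
  x
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d records (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  errs <- attr(x, "errors")
  if (!is.null(errs)) cat(sprintf("  %d malformed row(s) rejected\n", nrow(errs)))
  excl <- attr(x, "exclusions")
  if (!is.null(excl)) {
    cat(sprintf("  exclusions: %s\n",
                paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))
  }
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
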