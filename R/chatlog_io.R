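CORPUS_FIELDS <- c("utterance_id", "user_id", "country", "region",
                   "timestamp", "user_text", "bot_text")

# Default country -> cultural-region table for the eight study countries.
# Accepts both full names and ISO-3166 alpha-2 codes (lowercased keys).
REGION_TABLE <- c(
  "malaysia" = "Eastern", "my" = "Eastern",
  "philippines" = "Eastern", "the philippines" = "Eastern", "ph" = "Eastern",
  "india" = "Eastern", "in" = "Eastern",
  "indonesia" = "Eastern", "id" = "Eastern",
  "thailand" = "Eastern", "th" = "Eastern",
  "canada" = "Western", "ca" = "Western",
  "united kingdom" = "Western", "the united kingdom" = "Western",
  "gb" = "Western", "uk" = "Western",
  "united states" = "Western", "the united states" = "Western",
  "us" = "Western", "usa" = "Western"
)

#' Map a country to its cultural region
#'
#' The study countries are split into Eastern (Malaysia, the Philippines,
#' India, Indonesia, Thailand) and Western (Canada, the United Kingdom, the
#' United States) groups. Unlisted countries raise an error rather than being
#' silently assigned.
#'
#' @param country Character vector of country names or ISO alpha-2 codes
#'   (case-insensitive).
#' @param table Optional named character vector extending/replacing the
#'   built-in mapping; names are lowercase country keys, values are
#'   \code{"Eastern"} or \code{"Western"}.
#' @return Character vector of \code{"Eastern"}/\code{"Western"}.
#' @examples
#' map_region("Malaysia")
#' map_region(c("Canada", "PH"))
#' @export
map_region <- function(country, table = NULL) {
  tab <- REGION_TABLE
  if (!is.null(table)) {
    stopifnot(is.character(table), !is.null(names(table)),
              all(table %in% c("Eastern", "Western")))
    tab[tolower(names(table))] <- unname(table)
  }
  key <- tolower(trimws(country))
  out <- unname(tab[key])
  if (anyNA(out)) {
    bad <- unique(country[is.na(out)])
    stop("unknown country (no region mapping): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  out
}

#' Load a packaged keyword set
#'
#' Two keyword sets drive corpus construction: nine depressed/sad phrases
#' (including the stem "depress", so inflections such as "depressed" and
#' "depression" match) and fourteen happy/excited phrases used for the
#' temporal contrast.
#'
#' @param name \code{"depressed_sad"} or \code{"happy_excited"}.
#' @return An object of class \code{keyword_set}: a list with \code{name} and
#'   \code{phrases} (lowercase, ordered).
#' @export
keyword_set <- function(name = c("depressed_sad", "happy_excited")) {
  name <- match.arg(name)
  file <- switch(name,
                 depressed_sad = "keywords_depressed_sad.txt",
                 happy_excited = "keywords_happy_excited.txt")
  phrases <- readLines(chatmood_extdata(file), encoding = "UTF-8")
  phrases <- phrases[nzchar(phrases)]
  stopifnot(!anyDuplicated(phrases), identical(phrases, tolower(phrases)))
  structure(list(name = name, phrases = phrases), class = "keyword_set")
}

#' @export
print.keyword_set <- function(x, ...) {
  cat("<keyword_set> ", x$name, ": ", length(x$phrases), " phrases\n", sep = "")
  cat(" ", paste(sQuote(x$phrases), collapse = ", "), "\n")
  invisible(x)
}

new_chat_corpus <- function(df) {
  stopifnot(all(CORPUS_FIELDS %in% names(df)))
  df <- df[, CORPUS_FIELDS, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("chat_corpus", "data.frame")
  df
}

parse_record <- function(rec, line) {
  required <- c("user_id", "country", "timestamp", "user_text", "bot_text")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0)
    stop("line ", line, ": missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nzchar(trimws(rec[["user_text"]])))
    stop("line ", line, ": empty user_text", call. = FALSE)
  data.frame(
    utterance_id = if (!is.null(rec[["utterance_id"]])) as.character(rec[["utterance_id"]])
                   else sprintf("u%06d", line),
    user_id = as.character(rec[["user_id"]]),
    country = as.character(rec[["country"]]),
    region = map_region(rec[["country"]]),
    timestamp = as.character(rec[["timestamp"]]),
    user_text = as.character(rec[["user_text"]]),
    bot_text = as.character(rec[["bot_text"]]),
    stringsAsFactors = FALSE
  )
}

#' Read a chat-log corpus from JSONL or TSV
#'
#' Each record carries the five source fields (timestamp, user id, country,
#' user utterance, bot response); an \code{utterance_id} is taken if present
#' and generated from the line number otherwise. The region is populated
#' deterministically via \code{\link{map_region}}. Malformed lines (missing
#' fields, empty utterance, unknown country, unparseable JSON, wrong TSV field
#' count) are skipped, counted, and reported in the \code{"parse_errors"}
#' attribute of the result.
#'
#' @param path File path.
#' @param format \code{"jsonl"} (one JSON object per line) or \code{"tsv"}
#'   (tab-separated with a header row).
#' @return A \code{chat_corpus} data frame (columns \code{utterance_id},
#'   \code{user_id}, \code{country}, \code{region}, \code{timestamp},
#'   \code{user_text}, \code{bot_text}) with attribute \code{parse_errors},
#'   a data frame of \code{line} and \code{message}.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  errors <- list()
  rows <- list()

  if (format == "jsonl") {
    keep <- which(nzchar(trimws(lines)))
    for (i in keep) {
      row <- tryCatch({
        rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
        parse_record(rec, i)
      }, error = function(e) e)
      if (inherits(row, "error")) {
        errors[[length(errors) + 1L]] <-
          data.frame(line = i, message = conditionMessage(row))
      } else rows[[length(rows) + 1L]] <- row
    }
  } else {
    if (length(lines) > 0) {
      header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
      for (i in seq_along(lines)[-1]) {
        if (!nzchar(trimws(lines[[i]]))) next
        row <- tryCatch({
          vals <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
          # a trailing empty field (e.g. empty bot_text) is dropped by strsplit
          if (length(vals) == length(header) - 1L) vals <- c(vals, "")
          if (length(vals) != length(header))
            stop("line ", i, ": expected ", length(header), " fields, got ",
                 length(vals), call. = FALSE)
          rec <- as.list(vals)
          names(rec) <- header
          parse_record(rec, i)
        }, error = function(e) e)
        if (inherits(row, "error")) {
          errors[[length(errors) + 1L]] <-
            data.frame(line = i, message = conditionMessage(row))
        } else rows[[length(rows) + 1L]] <- row
      }
    }
  }

  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(utterance_id = character(), user_id = character(),
               country = character(), region = character(),
               timestamp = character(), user_text = character(),
               bot_text = character(), stringsAsFactors = FALSE)
  out <- new_chat_corpus(df)
  err_df <- if (length(errors) > 0) do.call(rbind, errors) else
    data.frame(line = integer(), message = character())
  attr(out, "parse_errors") <- err_df
  if (nrow(err_df) > 0)
    message(nrow(err_df), " malformed record(s) skipped; see attr(x, 'parse_errors')")
  out
}

#' Write a chat-log corpus to JSONL or TSV
#'
#' The TSV dialect is tab-separated with a header row, UTF-8, no quoting;
#' tabs and newlines inside text fields are replaced by spaces on write.
#'
#' @param records A \code{chat_corpus} data frame.
#' @param path Output file path.
#' @param format \code{"jsonl"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(records, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(records)[, CORPUS_FIELDS, drop = FALSE]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                    auto_unbox = TRUE))
    }, character(1))
  } else {
    clean <- function(x) gsub("[\t\r\n]+", " ", x)
    body <- apply(df, 1, function(r) paste(clean(r), collapse = "\t"))
    lines <- c(paste(CORPUS_FIELDS, collapse = "\t"), body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Keep records whose utterance contains a keyword phrase
#'
#' Matching is case-insensitive raw substring containment (no tokenization):
#' the stem "depress" matches "depressed" and "depression", and multiword
#' phrases such as "hate myself" match as contiguous substrings. Record order
#' is preserved and the operation is idempotent.
#'
#' @param records A \code{chat_corpus} data frame.
#' @param keys A \code{\link{keyword_set}} (or character vector of lowercase
#'   phrases).
#' @return The matching subset of \code{records}.
#' @export
filter_by_keywords <- function(records, keys) {
  phrases <- if (inherits(keys, "keyword_set")) keys$phrases else tolower(keys)
  stopifnot(length(phrases) > 0)
  text <- tolower(records$user_text)
  hit <- rep(FALSE, length(text))
  for (p in phrases) hit <- hit | grepl(p, text, fixed = TRUE)
  out <- records[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parse_errors") <- NULL
  out
}

#' Sample one utterance per user
#'
#' Prevents any single user's conversation from dominating downstream
#' statistics: for every distinct \code{user_id}, one record is chosen
#' uniformly at random. Deterministic for a fixed seed.
#'
#' @param records A \code{chat_corpus} data frame.
#' @param seed Integer seed.
#' @return Subset of \code{records} with exactly one row per user, in
#'   original record order.
#' @export
sample_one_per_user <- function(records, seed) {
  idx <- with_seed(seed, {
    by_user <- split(seq_len(nrow(records)), records$user_id)
    vapply(by_user, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
  })
  out <- records[sort(unname(idx)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parse_errors") <- NULL
  out
}

#' Mask runs of digits in free text
#'
#' Privacy masking for phone numbers and similar identifiers: every maximal
#' run of at least \code{min_run} consecutive digits is replaced by asterisks
#' of equal length, so string length is preserved and the operation is
#' idempotent. Shorter digit runs (ages, counts) are left alone.
#'
#' @param text Character vector.
#' @param min_run Minimum digit-run length to mask (default 4).
#' @return Masked character vector.
#' @examples
#' mask_pii("call me 5551234")
#' mask_pii("I am 16")
#' @export
mask_pii <- function(text, min_run = 4) {
  stopifnot(min_run >= 1)
  pattern <- sprintf("[0-9]{%d,}", as.integer(min_run))
  vapply(text, function(s) {
    m <- gregexpr(pattern, s)[[1]]
    if (m[1] == -1) return(s)
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      substr(s, m[j], m[j] + len[j] - 1L) <- strrep("*", len[j])
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the local hour from corpus timestamps
#'
#' Timestamps are stored as local wall-clock strings
#' (\code{"YYYY-MM-DD HH:MM:SS"}); no timezone conversion is applied, since
#' region-local time is what the diurnal analysis needs.
#'
#' @param timestamp Character vector of timestamps.
#' @return Integer vector of hours in \code{[0, 23]}.
#' @export
chat_hour <- function(timestamp) {
  h <- as.integer(substr(timestamp, 12, 13))
  stopifnot(all(h >= 0 & h <= 23, na.rm = TRUE))
  h
}
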