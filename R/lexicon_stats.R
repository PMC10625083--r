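#' Tokenize text for dictionary scoring and n-gram counting
#'
#' Lowercases, splits on whitespace, strips leading/trailing non-alphanumeric
#' characters from each token (in-word apostrophes survive, so "i'm" stays
#' one token), and drops empty tokens.
#'
#' @param text Character scalar (or vector; a list of token vectors is then
#'   returned).
#' @return Character vector of tokens, or a list of such vectors.
#' @examples
#' tokenize("I'm SAD!!")
#' @export
tokenize <- function(text) {
  one <- function(s) {
    toks <- strsplit(tolower(s), "\\s+")[[1]]
    toks <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", toks)
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Read a word-category lexicon
#'
#' One pattern per line; blank lines and \code{#} comments are ignored.
#' A pattern ending in \code{*} is a stem and matches any token with that
#' prefix; all other patterns match whole tokens.
#'
#' @param path Path to a lexicon file.
#' @return Character vector of patterns.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  pats <- tolower(lines[nzchar(lines)])
  if (length(pats) == 0)
    stop("lexicon ", sQuote(path), " has no patterns", call. = FALSE)
  pats
}

#' Read a directory of lexicons (one file per category)
#'
#' The packaged demonstration set (\code{demo_lexicons()}) covers the 24
#' word-category subfamilies used in the cross-cultural contrast (positive/
#' negative/anxiety/anger/sad emotion, swearing, physical/health/mental/
#' sexual/death, family/friend/home/work, past/present/future focus,
#' visual/auditory/feeling perception, and 1st/2nd/3rd-person pronouns) with
#' a few illustrative patterns each. Full psycholinguistic dictionaries are
#' proprietary; users can point this reader at their own directory in the
#' same format.
#'
#' @param dir Directory containing \code{<category>.txt} files.
#' @return Named list of pattern vectors.
#' @export
read_lexicon_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no lexicon files in ", sQuote(dir), call. = FALSE)
  out <- lapply(files, read_lexicon)
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}

#' @rdname read_lexicon_set
#' @export
demo_lexicons <- function() {
  read_lexicon_set(chatmood_extdata("liwc_demo"))
}

match_patterns <- function(tokens, patterns) {
  stems <- patterns[endsWith(patterns, "*")]
  literals <- patterns[!endsWith(patterns, "*")]
  hit <- tokens %in% literals
  for (s in sub("\\*$", "", stems)) hit <- hit | startsWith(tokens, s)
  hit
}

#' Percentage of tokens matching a word-category lexicon
#'
#' Dictionary-based scoring: the score of an utterance for a category is
#' 100 times the fraction of its tokens matching any of the category's
#' patterns. Utterances that tokenize to nothing have no defined score and
#' return \code{NA}; group statistics must exclude them.
#'
#' @param text Character vector of utterances.
#' @param patterns Character vector of lexicon patterns (see
#'   \code{\link{read_lexicon}}).
#' @return Numeric vector of percentages in \code{[0, 100]} (\code{NA} for
#'   zero-token text).
#' @examples
#' score_lexicon("sad sad ok", "sad")   # 66.67
#' score_lexicon("depressed", "depress*")
#' @export
score_lexicon <- function(text, patterns) {
  if (length(patterns) == 0 || !all(nzchar(patterns)))
    stop("lexicon has no usable patterns", call. = FALSE)
  patterns <- tolower(patterns)
  vapply(text, function(s) {
    toks <- tokenize(s)
    if (length(toks) == 0) return(NA_real_)
    100 * sum(match_patterns(toks, patterns)) / length(toks)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score every utterance against every category of a lexicon set
#'
#' @param texts Character vector of utterances.
#' @param lexicons Named list of pattern vectors (see
#'   \code{\link{read_lexicon_set}}).
#' @param ids Optional utterance ids.
#' @return Data frame: one row per utterance, one column per category, values
#'   are percentages (NA for zero-token text).
#' @export
lexicon_profiles <- function(texts, lexicons, ids = NULL) {
  scores <- lapply(lexicons, function(p) score_lexicon(texts, p))
  df <- as.data.frame(scores, check.names = FALSE)
  if (!is.null(ids)) df <- cbind(utterance_id = ids, df)
  df
}

#' Welch two-sample t-test from summary statistics
#'
#' The unequal-variance t statistic
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch--Satterthwaite degrees of freedom and a two-tailed p-value from
#' the t distribution. Computing from (mean, SD, n) directly lets printed
#' group summaries be re-tested without the raw data.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Object of class \code{welch_result}: list with \code{t}, \code{df},
#'   \code{p}, and the group summaries.
#' @examples
#' welch_t(29.68, 20.76, 21156, 29.17, 20.40, 21156)  # t = 2.55
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("both group standard deviations are zero; t is undefined",
         call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p,
                 group1 = list(mean = mean1, sd = sd1, n = n1),
                 group2 = list(mean = mean2, sd = sd2, n = n2)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t test: t = %.4f, df = %.1f, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  group1: mean %.4g (SD %.4g), n = %d\n",
              x$group1$mean, x$group1$sd, x$group1$n))
  cat(sprintf("  group2: mean %.4g (SD %.4g), n = %d\n",
              x$group2$mean, x$group2$sd, x$group2$n))
  invisible(x)
}

#' Welch t-test from raw score vectors
#'
#' Computes group means and sample standard deviations (denominator
#' \code{n - 1}), dropping undefined (\code{NA}) scores, then delegates to
#' \code{\link{welch_t}}.
#'
#' @param group1,group2 Numeric score vectors.
#' @return A \code{welch_result}.
#' @export
welch_t_from_samples <- function(group1, group2) {
  g1 <- group1[!is.na(group1)]
  g2 <- group2[!is.na(group2)]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 defined scores", call. = FALSE)
  welch_t(mean(g1), stats::sd(g1), length(g1),
          mean(g2), stats::sd(g2), length(g2))
}

#' Top-k n-grams of a corpus
#'
#' Tokenizes each utterance, always removes single-character tokens (pure
#' punctuation is already dropped by the tokenizer), optionally removes
#' stopwords, counts n-grams within utterance boundaries, and returns the
#' top \code{k} by proportion of all n-grams. Ties are broken by count
#' descending, then lexicographically.
#'
#' @param texts Character vector of utterances.
#' @param n N-gram order, 1 or 2.
#' @param k Number of entries to return.
#' @param remove_stopwords Drop packaged English stopwords first?
#' @param stopwords Stopword list (defaults to the packaged one).
#' @return Data frame with columns \code{ngram}, \code{count},
#'   \code{proportion} (proportions over ALL n-grams, so the full table sums
#'   to 1), ordered by count descending.
#' @export
top_ngrams <- function(texts, n = 1, k = 10, remove_stopwords = TRUE,
                       stopwords = chatmood_stopwords()) {
  stopifnot(n %in% c(1, 2), k >= 1)
  toks <- if (length(texts) == 1L) list(tokenize(texts)) else tokenize(texts)
  grams <- unlist(lapply(toks, function(tk) {
    tk <- tk[nchar(tk) > 1]
    if (remove_stopwords) tk <- tk[!(tk %in% stopwords)]
    if (length(tk) < n) return(character(0))
    if (n == 1) tk
    else paste(tk[-length(tk)], tk[-1])
  }), use.names = FALSE)
  if (length(grams) == 0)
    return(data.frame(ngram = character(), count = integer(),
                      proportion = numeric()))
  tab <- table(grams)
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord]
  out <- data.frame(ngram = names(tab),
                    count = as.integer(tab),
                    proportion = as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Relative hourly chat frequency per region
#'
#' For each region, the number of chats in each local hour divided by that
#' region's total -- the diurnal profile used to locate evening peaks of
#' depressive chatting.
#'
#' @param records A \code{chat_corpus} data frame.
#' @return Named list (one element per region present) of lists with
#'   \code{region}, \code{freq} (length-24 relative frequencies summing to 1),
#'   \code{n}, and \code{peak_hour} (argmax, 0-23).
#' @export
hourly_profile <- function(records) {
  hours <- chat_hour(records$timestamp)
  out <- lapply(split(hours, records$region), function(h) {
    counts <- tabulate(h + 1L, nbins = 24L)
    freq <- if (sum(counts) > 0) counts / sum(counts) else rep(0, 24)
    list(freq = freq, n = sum(counts),
         peak_hour = which.max(counts) - 1L)
  })
  for (r in names(out)) out[[r]]$region <- r
  out
}
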