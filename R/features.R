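#' Build a bag-of-words vocabulary
#'
#' Terms are tokens (via \code{\link{tokenize}}) whose total corpus frequency
#' is at least \code{min_count}, sorted lexicographically for stable
#' indexing. When used inside an evaluation, build the vocabulary on the
#' training split only; out-of-vocabulary tokens in held-out text are simply
#' ignored by \code{\link{bow_vector}}.
#'
#' @param texts Character vector of utterances.
#' @param min_count Minimum total frequency (default 5).
#' @return Character vector of terms with attribute \code{min_count}.
#' @export
build_vocab <- function(texts, min_count = 5) {
  stopifnot(min_count >= 1)
  toks <- unlist(tokenize(c(texts, "")), use.names = FALSE)
  tab <- table(toks)
  terms <- sort(names(tab)[tab >= min_count])
  if (length(terms) == 0)
    stop("no term reaches min_count = ", min_count, call. = FALSE)
  structure(terms, min_count = min_count)
}

#' Multi-hot bag-of-words vector
#'
#' Presence indicator (not counts) per vocabulary term; out-of-vocabulary
#' tokens are ignored.
#'
#' @param text Character scalar.
#' @param vocab Vocabulary from \code{\link{build_vocab}}.
#' @return Named integer vector of 0/1 of length \code{length(vocab)}.
#' @export
bow_vector <- function(text, vocab) {
  stopifnot(length(vocab) > 0)
  v <- as.integer(vocab %in% tokenize(text))
  names(v) <- as.character(vocab)
  v
}

bow_matrix <- function(texts, vocab) {
  toks <- if (length(texts) == 1L) list(tokenize(texts)) else tokenize(texts)
  m <- matrix(0L, length(texts), length(vocab),
              dimnames = list(NULL, as.character(vocab)))
  for (i in seq_along(toks)) {
    idx <- match(unique(toks[[i]]), vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) m[i, idx] <- 1L
  }
  m
}

#' The frozen 46-tag part-of-speech inventory
#'
#' The fine-grained English (Penn-Treebank-style) tag set, frozen as a
#' packaged list so tag-frequency features are backend-independent and
#' reproducible.
#'
#' @return Character vector of 46 tags, in fixed order.
#' @export
pos_tags_inventory <- function() {
  readLines(chatmood_extdata("pos_tags.txt"), encoding = "UTF-8")
}

# Compact English tagging lexicon for the default rule tagger.
POS_LEXICON <- c(
  i = "PRP", you = "PRP", me = "PRP", he = "PRP", she = "PRP", it = "PRP",
  they = "PRP", we = "PRP", us = "PRP", them = "PRP", him = "PRP",
  her = "PRP", myself = "PRP", yourself = "PRP", u = "PRP",
  "i'm" = "PRP", im = "PRP", "i've" = "PRP", "i'll" = "PRP",
  my = "PRP$", your = "PRP$", his = "PRP$", its = "PRP$", our = "PRP$",
  their = "PRP$", mine = "PRP$",
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", all = "DT", some = "DT", any = "DT", no = "DT",
  every = "DT", everything = "NN", nothing = "NN", nobody = "NN",
  and = "CC", but = "CC", or = "CC", nor = "CC",
  "in" = "IN", on = "IN", at = "IN", of = "IN", "for" = "IN", with = "IN",
  about = "IN", because = "IN", from = "IN", inside = "IN", outside = "IN",
  like = "IN",
  to = "TO",
  can = "MD", could = "MD", will = "MD", would = "MD", should = "MD",
  must = "MD", may = "MD", might = "MD", shall = "MD", "can't" = "MD",
  cant = "MD", "won't" = "MD",
  am = "VBP", are = "VBP", do = "VBP", have = "VBP", feel = "VBP",
  want = "VBP", know = "VBP", hate = "VBP", love = "VBP", need = "VBP",
  think = "VBP", "don't" = "VBP", dont = "VBP",
  is = "VBZ", has = "VBZ", does = "VBZ", makes = "VBZ", feels = "VBZ",
  was = "VBD", were = "VBD", did = "VBD", had = "VBD", felt = "VBD",
  went = "VBD", said = "VBD", told = "VBD", called = "VBD", left = "VBD",
  lost = "VBD", yelled = "VBD",
  be = "VB", die = "VB", kill = "VB", sleep = "VB", eat = "VB", cry = "VB",
  help = "VB", stop = "VB", give = "VB", end = "VB", disappear = "VB",
  heal = "VB", cope = "VB", talk = "VB", tell = "VB",
  being = "VBG", been = "VBN",
  not = "RB", so = "RB", very = "RB", really = "RB", just = "RB",
  now = "RB", never = "RB", always = "RB", too = "RB", again = "RB",
  here = "RB", there = "RB", anymore = "RB", ever = "RB", away = "RB",
  yeah = "UH", oh = "UH", hey = "UH", please = "UH", wow = "UH",
  why = "WRB", how = "WRB", when = "WRB", where = "WRB",
  who = "WP", what = "WP",
  sad = "JJ", happy = "JJ", lonely = "JJ", gloomy = "JJ", tired = "JJ",
  bad = "JJ", good = "JJ", okay = "JJ", fine = "JJ", empty = "JJ",
  worthless = "JJ", useless = "JJ", suicidal = "JJ", depressed = "JJ",
  stressed = "JJ", numb = "JJ", alone = "JJ", hard = "JJ",
  "it's" = "PRP", "that's" = "DT", "i'd" = "PRP", "she's" = "PRP",
  "he's" = "PRP", "they're" = "PRP", "you're" = "PRP", youre = "PRP")

#' Part-of-speech tagger backends
#'
#' A tagger is a function mapping a token vector to a tag vector drawn from
#' the frozen 46-tag inventory. \code{pos_tagger_default()} is a compact
#' lexicon + suffix-rule tagger (pronouns, determiners, common verbs;
#' \code{-ly} adverbs, \code{-ing}/\code{-ed} verb forms, plural nouns,
#' numerals; noun fallback). \code{pos_tagger_lookup()} builds a pure
#' lookup-table tagger, useful as an exact oracle in tests.
#'
#' @param table Named character vector, token -> tag.
#' @param default Tag for tokens absent from \code{table}.
#' @return A function \code{tokens -> tags}.
#' @export
pos_tagger_default <- function() {
  function(tokens) {
    tags <- unname(POS_LEXICON[tokens])
    miss <- is.na(tags)
    if (any(miss)) {
      tk <- tokens[miss]
      tags[miss] <- ifelse(grepl("^[0-9]+$", tk), "CD",
                    ifelse(endsWith(tk, "ly"), "RB",
                    ifelse(endsWith(tk, "ing"), "VBG",
                    ifelse(endsWith(tk, "ed"), "VBD",
                    ifelse(endsWith(tk, "s") & !endsWith(tk, "ss"), "NNS",
                           "NN")))))
    }
    tags
  }
}

#' @rdname pos_tagger_default
#' @export
pos_tagger_lookup <- function(table, default = "NN") {
  stopifnot(is.character(table), !is.null(names(table)))
  function(tokens) {
    tags <- unname(table[tokens])
    tags[is.na(tags)] <- default
    tags
  }
}

#' Part-of-speech tag-frequency vector
#'
#' Counts of each tag of the frozen 46-tag inventory for one utterance; the
#' counts sum to the token count seen by the tagger. A tagger emitting a tag
#' outside the inventory is an error (named in the message), never silently
#' binned.
#'
#' @param text Character scalar.
#' @param tagger A tagger function (default \code{\link{pos_tagger_default}}).
#' @return Named integer vector of length 46.
#' @export
pos_vector <- function(text, tagger = pos_tagger_default()) {
  inventory <- pos_tags_inventory()
  tokens <- tokenize(text)
  counts <- stats::setNames(integer(length(inventory)), inventory)
  if (length(tokens) == 0) return(counts)
  tags <- tagger(tokens)
  bad <- setdiff(unique(tags), inventory)
  if (length(bad) > 0)
    stop("tagger emitted tag(s) outside the 46-tag inventory: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  tab <- table(factor(tags, levels = inventory))
  counts[] <- as.integer(tab)
  counts
}

#' Deterministic offline sentence embedding
#'
#' The default backend (\code{"hashing"}) embeds a sentence by signed feature
#' hashing of its character trigrams (text padded with spaces, lowercased)
#' into \code{dim} dimensions, followed by L2 normalization. It is fully
#' deterministic, needs no model download, and gives related strings nearby
#' vectors through shared trigrams. The default dimension of 768 matches the
#' width of common pretrained sentence encoders so downstream code is
#' drop-in compatible with one. Unknown backends are an explicit error --
#' there is no silent fallback.
#'
#' @param text Character scalar.
#' @param dim Embedding dimension E (default 768).
#' @param backend Embedding backend; only \code{"hashing"} ships.
#' @return Numeric vector of length \code{dim} with unit L2 norm (all zeros
#'   for empty text).
#' @export
embed_text <- function(text, dim = 768, backend = "hashing") {
  if (!identical(backend, "hashing"))
    stop("embedding backend ", sQuote(backend), " is not available",
         call. = FALSE)
  stopifnot(dim >= 2)
  s <- paste0(" ", tolower(text), " ")
  b <- utf8ToInt(s)
  v <- numeric(dim)
  if (length(b) >= 3) {
    c1 <- b[seq_len(length(b) - 2)]
    c2 <- b[seq(2, length(b) - 1)]
    c3 <- b[seq(3, length(b))]
    h1 <- ((c1 * 31 + c2) * 31 + c3) %% 2147483647
    h2 <- ((c1 * 37 + c2) * 37 + c3) %% 2147483629
    idx <- (h1 %% dim) + 1
    sgn <- ifelse(h2 %% 2 == 0, 1, -1)
    for (k in seq_along(idx)) v[idx[k]] <- v[idx[k]] + sgn[k]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

embed_matrix <- function(texts, dim = 768, backend = "hashing") {
  t(vapply(texts, embed_text, numeric(dim), dim = dim, backend = backend,
           USE.NAMES = FALSE))
}

#' Concatenate the three feature blocks
#'
#' Feature order is bag-of-words, then the 46 part-of-speech counts, then the
#' embedding, so the combined dimension is \code{|vocab| + 46 + E} (6027 +
#' 46 + 768 = 6841 under the reference configuration).
#'
#' @param bow Multi-hot bag-of-words vector.
#' @param pos 46-dimensional tag-count vector.
#' @param emb Dense embedding vector.
#' @return Numeric vector of length \code{length(bow) + 46 + length(emb)}.
#' @export
concat_features <- function(bow, pos, emb) {
  if (length(pos) != 46)
    stop("pos block must have 46 dimensions, got ", length(pos), call. = FALSE)
  c(bow, pos, emb)
}

#' Build the full feature matrix for a set of utterances
#'
#' @param texts Character vector.
#' @param vocab Vocabulary from \code{\link{build_vocab}}.
#' @param tagger Tagger backend.
#' @param dim Embedding dimension.
#' @param ids Optional rownames (utterance ids).
#' @return Numeric matrix, one row per utterance,
#'   \code{length(vocab) + 46 + dim} columns.
#' @export
feature_matrix <- function(texts, vocab, tagger = pos_tagger_default(),
                           dim = 768, ids = NULL) {
  bow <- bow_matrix(texts, vocab)
  pos <- t(vapply(texts, function(s) as.numeric(pos_vector(s, tagger)),
                  numeric(46), USE.NAMES = FALSE))
  emb <- embed_matrix(texts, dim = dim)
  m <- cbind(bow, pos, emb)
  colnames(m) <- c(paste0("bow_", as.character(vocab)),
                   paste0("pos_", pos_tags_inventory()),
                   paste0("emb_", seq_len(dim)))
  if (!is.null(ids)) rownames(m) <- ids
  m
}
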