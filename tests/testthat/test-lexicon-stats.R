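test_that("tokenizer lowercases, strips edge punctuation and keeps apostrophes", {
  expect_equal(tokenize("I'm SAD!!"), c("i'm", "sad"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("a  b"), c("a", "b"))
  expect_equal(tokenize("...!!!"), character(0))
  expect_equal(tokenize("don't stop-me now."), c("don't", "stop-me", "now"))
})

test_that("lexicon scoring follows percentage-of-tokens semantics", {
  expect_equal(score_lexicon("sad sad ok", "sad"), 100 * 2 / 3)
  expect_equal(score_lexicon("depressed", "depress*"), 100)
  expect_equal(score_lexicon("nothing matches", "sad"), 0)
  expect_true(is.na(score_lexicon("!!!", "sad")))
  expect_error(score_lexicon("any", character(0)), "patterns")

  # invariant to token order and to added pure-punctuation tokens
  s1 <- score_lexicon("sad day again sad", c("sad", "day"))
  s2 <- score_lexicon("sad sad day again", c("sad", "day"))
  s3 <- score_lexicon("sad day :: !! again sad", c("sad", "day"))
  expect_equal(s1, s2)
  expect_equal(s1, s3)
})

test_that("packaged demo lexicon set covers the 24 word-category subfamilies", {
  lex <- demo_lexicons()
  expect_length(lex, 24)
  expect_true(all(c("emo_pos", "emo_neg", "emo_sad", "swear", "physical",
                    "health", "mental", "sexual", "death", "family",
                    "friend", "home", "work", "past_focus", "present_focus",
                    "future_focus", "visual", "auditory", "feel",
                    "pron_1st", "pron_2nd", "pron_3rd") %in% names(lex)))
  prof <- lexicon_profiles(c("i feel sad", "we went home"), lex)
  expect_equal(prof$emo_sad, c(100 / 3, 0))
  expect_true(all(vapply(prof, function(col)
    all(col >= 0 & col <= 100, na.rm = TRUE), logical(1))))
})

test_that("Welch t from summary statistics matches the closed form and t.test", {
  # hand-checkable case: A = (0,0,10,10), B = (5,5,5,5) has equal means
  a <- c(0, 0, 10, 10); b <- c(5, 5, 5, 5)
  w <- welch_t_from_samples(a, b)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    mine <- welch_t_from_samples(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # closed form on the samples' own summaries agrees exactly
    direct <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(mine$t, direct$t, tolerance = 1e-12)
    expect_equal(mine$df, direct$df, tolerance = 1e-12)
  }

  # symmetry and the equal-n equal-SD df limit
  expect_equal(welch_t_from_samples(c(1, 2, 3), c(1, 2, 3))$t, 0)
  w2 <- welch_t(1, 2, 10, 3, 2, 10)
  expect_equal(w2$df, 18)
  expect_equal(sign(w2$t), sign(1 - 3))
  expect_error(welch_t(1, 0, 5, 1, 0, 5), "zero")
  # permutation within groups changes nothing
  expect_equal(welch_t_from_samples(c(3, 1, 2), c(9, 7, 8))$t,
               welch_t_from_samples(c(1, 2, 3), c(7, 8, 9))$t)
})

test_that("n-gram tables count within utterances with deterministic tie-breaks", {
  t1 <- top_ngrams("sad sad im", n = 1, k = 10, remove_stopwords = FALSE)
  expect_equal(t1$ngram, c("sad", "im"))
  expect_equal(t1$proportion, c(2 / 3, 1 / 3))

  # bigram of a one-token utterance: nothing; no bigrams across utterances
  expect_equal(nrow(top_ngrams("sad", n = 2, k = 5, remove_stopwords = FALSE)), 0)
  t2 <- top_ngrams(c("im sad", "sad im"), n = 2, k = 10,
                   remove_stopwords = FALSE)
  expect_equal(sort(t2$ngram), c("im sad", "sad im"))

  # k beyond the table returns everything; full proportions sum to 1
  t3 <- top_ngrams(c("aa bb aa", "bb cc"), n = 1, k = 100,
                   remove_stopwords = FALSE)
  expect_equal(sum(t3$proportion), 1)
  # ties broken lexicographically after count
  expect_equal(t3$ngram, c("aa", "bb", "cc"))

  # stopword and single-character removal
  t4 <- top_ngrams("i am so sad x", n = 1, k = 10, remove_stopwords = TRUE)
  expect_equal(t4$ngram, "sad")
})

test_that("hourly profiles normalize per region and locate the peak", {
  corp <- make_corpus(rep("sad", 10), hour = 20)
  hp <- hourly_profile(corp)
  expect_equal(hp$Western$freq[21], 1)
  expect_equal(hp$Western$peak_hour, 20L)

  # uniform fixture: 24 hours x equal counts
  corp2 <- make_corpus(rep("sad", 48), hour = rep(0:23, each = 2))
  hp2 <- hourly_profile(corp2)
  expect_equal(hp2$Western$freq, rep(1 / 24, 24))
  expect_equal(sum(hp2$Western$freq), 1)
})
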