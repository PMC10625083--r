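test_that("region mapping covers the eight study countries and rejects others", {
  expect_equal(map_region("Malaysia"), "Eastern")
  expect_equal(map_region("Canada"), "Western")
  expect_equal(map_region(c("india", "GB", "us", "Thailand")),
               c("Eastern", "Western", "Western", "Eastern"))
  expect_error(map_region("France"), "France")
  # extension table
  expect_equal(map_region("France", table = c(france = "Western")), "Western")
})

test_that("packaged keyword sets have the documented sizes and casing", {
  dep <- keyword_set("depressed_sad")
  hap <- keyword_set("happy_excited")
  expect_length(dep$phrases, 9)
  expect_length(hap$phrases, 14)
  expect_true("depress" %in% dep$phrases)
  expect_true("hate myself" %in% dep$phrases)
  expect_identical(dep$phrases, tolower(dep$phrases))
})

test_that("keyword filtering is substring-based, order-preserving and idempotent", {
  dep <- keyword_set("depressed_sad")
  corp <- make_corpus(c("I am so depressed today", "happy birthday",
                        "she was feeling low yesterday", "nothing here",
                        "I HATE MYSELF"))
  kept <- filter_by_keywords(corp, dep)
  expect_equal(kept$utterance_id, c("u0001", "u0003", "u0005"))
  expect_identical(filter_by_keywords(kept, dep), kept)

  # planted-subset scan on a larger fixture, checked by brute force
  texts <- rep("all is well", 20)
  planted <- c(3, 7, 8, 15)
  texts[planted] <- c("so sad", "this is depressing", "gloomy weather mood",
                      "i am ashamed of myself")
  corp20 <- make_corpus(texts)
  brute <- vapply(tolower(texts), function(s)
    any(vapply(dep$phrases, function(p) grepl(p, s, fixed = TRUE), logical(1))),
    logical(1))
  expect_equal(filter_by_keywords(corp20, dep)$utterance_id,
               corp20$utterance_id[brute])
  expect_equal(unname(which(brute)), planted)
  # every kept record really contains one of the nine phrases
  kept20 <- filter_by_keywords(corp20, dep)
  expect_true(all(vapply(tolower(kept20$user_text), function(s)
    any(vapply(dep$phrases, grepl, logical(1), x = s, fixed = TRUE)),
    logical(1))))
})

test_that("one-per-user sampling keeps one record per user, reproducibly", {
  corp <- make_corpus(rep("hello sad world", 50),
                      user_id = rep(sprintf("u%d", 1:5), each = 10))
  s1 <- sample_one_per_user(corp, seed = 7)
  s2 <- sample_one_per_user(corp, seed = 7)
  s3 <- sample_one_per_user(corp, seed = 8)
  expect_equal(nrow(s1), 5)
  expect_equal(sort(unique(s1$user_id)), sort(unique(corp$user_id)))
  expect_identical(s1, s2)
  expect_false(identical(s1$utterance_id, s3$utterance_id))
  # identity when every user already has one record
  single <- make_corpus(letters[1:4], user_id = sprintf("u%d", 1:4))
  expect_equal(sample_one_per_user(single, 1)$utterance_id,
               single$utterance_id)
})

test_that("PII masking replaces long digit runs and preserves length", {
  expect_equal(mask_pii("call me 5551234"), "call me *******")
  expect_equal(mask_pii("I am 16"), "I am 16")
  expect_equal(mask_pii("no digits here"), "no digits here")
  expect_equal(mask_pii("a 123456 b 99 c 7777"), "a ****** b 99 c ****")
  strs <- c("x12345y", "128", "ring 0123456789 now")
  expect_equal(nchar(mask_pii(strs)), nchar(strs))
  expect_equal(mask_pii(mask_pii(strs)), mask_pii(strs))
  expect_equal(mask_pii("ab 123 cd", min_run = 3), "ab *** cd")
})

test_that("corpus round-trips through jsonl and tsv", {
  corp <- make_corpus(c("i am sad", "why so gloomy", "ok then"),
                      user_id = c("a", "b", "c"),
                      country = c("Canada", "Malaysia", "India"),
                      bot_text = c("oh no", "", "cheer up"))
  for (fmt in c("jsonl", "tsv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_corpus(corp, path, fmt)
    back <- read_corpus(path, fmt)
    expect_equal(nrow(attr(back, "parse_errors")), 0)
    attr(back, "parse_errors") <- NULL
    expect_equal(as.data.frame(back), as.data.frame(corp))
  }
})

test_that("malformed lines are skipped and reported with line numbers", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"user_id":"a","country":"Canada","timestamp":"2020-01-01 10:00:00","user_text":"i am sad","bot_text":""}',
    '{"user_id":"b","country":"Canada","timestamp":"2020-01-01 11:00:00"}',
    '{"user_id":"c","country":"Malaysia","timestamp":"2020-01-01 12:00:00","user_text":"so gloomy","bot_text":"oh"}'),
    path)
  expect_message(corp <- read_corpus(path, "jsonl"), "1 malformed")
  expect_equal(nrow(corp), 2)
  errs <- attr(corp, "parse_errors")
  expect_equal(errs$line, 2L)
  expect_match(errs$message, "user_text")

  # unknown country is a record-level error naming the country
  writeLines(c(
    '{"user_id":"a","country":"Mars","timestamp":"2020-01-01 10:00:00","user_text":"hi","bot_text":""}'),
    path)
  expect_message(corp2 <- read_corpus(path, "jsonl"))
  expect_equal(nrow(corp2), 0)
  expect_match(attr(corp2, "parse_errors")$message, "Mars")

  # empty file: empty corpus, zero errors
  writeLines(character(0), path)
  empty <- read_corpus(path, "jsonl")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(attr(empty, "parse_errors")), 0)
})

test_that("chat_hour extracts valid local hours", {
  expect_equal(chat_hour("2020-05-01 23:10:00"), 23L)
  expect_equal(chat_hour(c("2020-05-01 00:10:00", "2020-05-01 09:59:59")),
               c(0L, 9L))
})
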