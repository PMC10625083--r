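# Shared fixtures and independent oracles used across the test files.

cats8 <- chatmood_categories()

# Build a small in-memory corpus data frame from parallel vectors.
make_corpus <- function(user_text,
                        user_id = sprintf("user%02d", seq_along(user_text)),
                        country = "Canada",
                        hour = 12,
                        bot_text = "") {
  n <- length(user_text)
  country <- rep_len(country, n)
  df <- data.frame(
    utterance_id = sprintf("u%04d", seq_len(n)),
    user_id = rep_len(user_id, n),
    country = country,
    region = map_region(country),
    timestamp = sprintf("2019-06-01 %02d:30:00", rep_len(hour, n)),
    user_text = user_text,
    bot_text = rep_len(bot_text, n),
    stringsAsFactors = FALSE)
  class(df) <- c("chat_corpus", "data.frame")
  df
}

# Brute-force Fleiss kappa: mean pairwise agreement per item vs pooled
# chance agreement, written directly from the definition.
fleiss_oracle <- function(m) {
  n <- nrow(m); r <- ncol(m)
  p_i <- vapply(seq_len(n), function(i) {
    agree <- 0; pairs <- 0
    for (a in 1:(r - 1)) for (b in (a + 1):r) {
      agree <- agree + (m[i, a] == m[i, b])
      pairs <- pairs + 1
    }
    agree / pairs
  }, numeric(1))
  labs <- table(as.vector(m))
  p_j <- labs / sum(labs)
  p_exp <- sum(p_j^2)
  (mean(p_i) - p_exp) / (1 - p_exp)
}

# Brute-force one-vs-rest AUC: proportion of (positive, negative) pairs
# ranked correctly, ties counted half.
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Pearson chi-square statistic for a 2x2 table, written out cell by cell.
chisq_2x2_oracle <- function(a1, n1, a2, n2) {
  obs <- c(a1, n1 - a1, a2, n2 - a2)
  rows <- c(a1 + n1 - a1, a2 + n2 - a2)    # n1, n2
  cols <- c(a1 + a2, (n1 - a1) + (n2 - a2))
  total <- n1 + n2
  stat <- 0
  k <- 1
  for (i in 1:2) for (j in 1:2) {
    e <- rows[i] * cols[j] / total
    stat <- stat + (obs[k] - e)^2 / e
    k <- k + 1
  }
  stat
}

# Feature set that separates 8 classes perfectly: one indicator column per
# class plus noise columns.
separable_features <- function(labels, noise_cols = 5, seed = 1) {
  n <- length(labels)
  x <- matrix(0, n, 8 + noise_cols)
  for (i in seq_len(n)) x[i, match(labels[i], cats8)] <- 1
  set.seed(seed)
  x[, 8 + seq_len(noise_cols)] <- matrix(stats::rnorm(n * noise_cols, sd = 0.1), n)
  colnames(x) <- c(cats8, sprintf("noise%d", seq_len(noise_cols)))
  rownames(x) <- names(labels)
  x
}

random_labels <- function(n, seed) {
  set.seed(seed)
  stats::setNames(sample(cats8, n, replace = TRUE), sprintf("it%04d", 1:n))
}
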