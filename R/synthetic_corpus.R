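# Per-category template banks. The "keyworded" bank embeds at least one
# depressed/sad keyword phrase per template; the "neutral" bank carries the
# same category signal without any keyword, so the keyword_rate knob controls
# how much of a category's output survives keyword filtering.
category_templates <- function() {
  list(
    dysfunctional_thoughts = list(
      keyworded = c("i hate everything i hate life i hate myself",
                    "i hate myself so much im sad",
                    "i am worthless and i hate myself",
                    "im sad because i am such a failure",
                    "i am ashamed of myself and everything i do"),
      neutral = c("i am useless and a failure",
                  "nothing i do is ever good enough",
                  "i am a burden to everyone")),
    lifestyle_challenges = list(
      keyworded = c("i can't sleep at night because i'm so sad and stressed",
                    "too sad to eat anything today",
                    "i cannot sleep i feel sad and tired",
                    "im sad i lost my appetite again"),
      neutral = c("i cannot sleep at night anymore",
                  "i skip meals and stay in bed all day",
                  "getting out of bed is so hard lately")),
    social_struggles = list(
      keyworded = c("my friends make me sad",
                    "i told her about my depression and she called me crazy",
                    "i am so lonely and sad no one talks to me",
                    "everyone left me im sad and lonely"),
      neutral = c("nobody wants to talk to me anymore",
                  "my friends all left me alone",
                  "i feel so lonely at school")),
    hiding_behind_mask = list(
      keyworded = c("yeah i'm just a bit depressed i'll be okay",
                    "im happy on the outside but deep inside im sad",
                    "i smile at everyone but i am sad inside",
                    "i pretend to be fine but i feel gloomy"),
      neutral = c("i pretend everything is fine in front of them",
                  "i smile so nobody asks questions",
                  "they think i am okay but i am not")),
    apathy_sadness = list(
      keyworded = c("i'm sad and crying now",
                    "i feel so sad and empty",
                    "im sad",
                    "so sad right now",
                    "feeling very gloomy and sad today",
                    "im crying because im sad again"),
      neutral = c("i feel so empty inside",
                  "crying again for no reason",
                  "everything feels numb and grey")),
    suicidal_thoughts = list(
      keyworded = c("im sad i want to die but i don't kill myself because i don't like pain",
                    "i'm depressed and suicidal",
                    "i think about death when i am sad",
                    "im so sad i want to end it all"),
      neutral = c("i want to disappear forever",
                  "i think about ending it all the time",
                  "i keep thinking about death")),
    seeking_relief = list(
      keyworded = c("can you give advice to heal my sad",
                    "i have depression and anxiety what should i do",
                    "help me i am so depressed",
                    "how do i stop feeling so sad"),
      neutral = c("what should i do to feel better",
                  "please help me cope with this",
                  "any advice for getting through bad days")),
    etc = list(
      keyworded = c("why are you sad",
                    "that's sad",
                    "don't be sad",
                    "dont be sad little bot",
                    "sighs sadly",
                    "walks away sadly"),
      neutral = c("tell me a story",
                  "what are you doing right now bot",
                  "do you ever dream"))
  )
}

region_style_tokens <- function() {
  list(Eastern = c("feel", "right now", "pain", "hurt", "feelings", "now"),
       Western = c("damn", "hell", "my health", "sick", "therapy", "doctor"))
}

bot_replies <- c("i am here for you", "tell me more", "why do you feel that way",
                 "i am listening", "oh no", "cheer up", "")

region_countries <- list(
  Eastern = c("Malaysia", "Philippines", "India", "Indonesia", "Thailand"),
  Western = c("Canada", "United Kingdom", "United States"))

#' Configuration for the synthetic chat-log generator
#'
#' Defaults mirror the structure the analyses assume: per-region corpora with
#' region-specific mixtures over the 8 discourse categories (default mixtures
#' follow the published chatbot category shares, with the two unpublished
#' per-region cells -- lifestyle challenges and suicidal thoughts -- splitting
#' the leftover mass 2:1), evening-peaked diurnal timestamp distributions
#' (Western peak 19h, Eastern peak 21h, as a wrapped discretized Gaussian
#' mixed with a uniform background), a keyword embedding rate, a ~1% labeled
#' fraction annotated by 4 simulated raters, and a single master seed.
#'
#' @param n_users_per_region Users per region.
#' @param utterances_per_user List \code{(mean, dispersion)}; per-user counts
#'   are \code{1 + NegBinom(mu = mean - 1, size = dispersion)}.
#' @param category_mixture Named list \code{Eastern}/\code{Western}, each an
#'   8-simplex over \code{chatmood_categories()}.
#' @param diurnal Named list per region with \code{w} (weight of the evening
#'   peak component), \code{peak_hour} (0-23) and \code{spread} (hours).
#' @param keyword_rate Probability an utterance embeds a depressed/sad
#'   keyword phrase.
#' @param region_style_strength Probability an utterance gains a
#'   region-styled token (Eastern: present-tense feeling words; Western:
#'   health/swear tokens), creating recoverable lexicon contrasts.
#' @param labeled_fraction Fraction of records receiving simulated
#'   annotations.
#' @param rater_accuracy Probability a simulated rater emits the true
#'   category.
#' @param n_raters Number of simulated raters.
#' @param seed Master seed.
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(n_users_per_region = 1000,
                             utterances_per_user = list(mean = 2, dispersion = 1),
                             category_mixture = NULL,
                             diurnal = list(
                               Eastern = list(w = 0.6, peak_hour = 21, spread = 2),
                               Western = list(w = 0.6, peak_hour = 19, spread = 2)),
                             keyword_rate = 0.9,
                             region_style_strength = 0.5,
                             labeled_fraction = 0.01,
                             rater_accuracy = 0.95,
                             n_raters = 4,
                             seed = 1) {
  if (is.null(category_mixture)) {
    cats <- chatmood_categories()
    eastern <- c(0.0868, 0.0207, 0.0715, 0.0395, 0.5063, 0.0104, 0.0824, 0.1824)
    western <- c(0.1136, 0.0136, 0.0910, 0.0395, 0.4849, 0.0068, 0.0682, 0.1824)
    names(eastern) <- names(western) <- cats
    category_mixture <- list(Eastern = eastern, Western = western)
  }
  cfg <- structure(list(
    n_users_per_region = n_users_per_region,
    utterances_per_user = utterances_per_user,
    category_mixture = category_mixture,
    diurnal = diurnal,
    keyword_rate = keyword_rate,
    region_style_strength = region_style_strength,
    labeled_fraction = labeled_fraction,
    rater_accuracy = rater_accuracy,
    n_raters = n_raters,
    seed = seed), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param config A \code{generator_config}.
#' @export
validate_generator_config <- function(config) {
  cats <- chatmood_categories()
  stopifnot(config$n_users_per_region >= 1,
            config$utterances_per_user$mean >= 1,
            config$utterances_per_user$dispersion > 0,
            config$n_raters >= 1)
  probs <- c(config$keyword_rate, config$region_style_strength,
             config$labeled_fraction, config$rater_accuracy)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  for (region in c("Eastern", "Western")) {
    mix <- config$category_mixture[[region]]
    if (is.null(mix) || length(mix) != 8 || is.null(names(mix)) ||
        !setequal(names(mix), cats))
      stop(region, " category_mixture must be named over the 8 categories",
           call. = FALSE)
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      stop(region, " category_mixture must be a simplex (sum 1 +/- 1e-9)",
           call. = FALSE)
    d <- config$diurnal[[region]]
    if (is.null(d) || d$w < 0 || d$w > 1 || d$peak_hour < 0 ||
        d$peak_hour > 23 || d$spread <= 0)
      stop(region, " diurnal component invalid", call. = FALSE)
  }
  invisible(config)
}

# Wrapped, discretized Gaussian over hours 0..23 centred at peak_hour,
# mixed with a uniform background with weight (1 - w).
diurnal_pmf <- function(w, peak_hour, spread) {
  h <- 0:23
  d <- pmin(abs(h - peak_hour), 24 - abs(h - peak_hour))
  g <- exp(-0.5 * (d / spread)^2)
  g <- g / sum(g)
  w * g + (1 - w) / 24
}

sample_hours <- function(n, d) {
  sample(0:23, n, replace = TRUE, prob = diurnal_pmf(d$w, d$peak_hour, d$spread))
}

make_utterance <- function(category, region, keyworded, styled, banks, styles) {
  bank <- if (keyworded) banks[[category]]$keyworded else banks[[category]]$neutral
  text <- bank[sample.int(length(bank), 1)]
  if (styled) text <- paste(text, styles[[region]][sample.int(length(styles[[region]]), 1)])
  text
}

#' Generate a synthetic chat-log corpus with ground truth
#'
#' Builds per-region corpora of short English utterances assembled from
#' per-category template banks, with the configured category mixtures,
#' diurnal timestamp distributions, keyword embedding rate, and region-styled
#' lexical signals. A labeled subset of size
#' \code{ceiling(labeled_fraction * n)} receives simulated annotations from
#' \code{n_raters} independent raters. Deterministic for a fixed seed; all
#' randomness flows from sub-seeds derived from \code{config$seed}.
#'
#' @param config A \code{\link{generator_config}}.
#' @return Object of class \code{synthetic_corpus}: list with \code{records}
#'   (a \code{chat_corpus} data frame), \code{true_labels} (named character
#'   vector, utterance_id -> category), \code{annotations} (character matrix
#'   over the labeled subset), and \code{config}.
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  cats <- chatmood_categories()
  banks <- category_templates()
  styles <- region_style_tokens()

  records <- with_seed(derive_seed(config$seed, "records"), {
    rows <- vector("list", 2)
    uid0 <- 0L
    for (ri in 1:2) {
      region <- c("Eastern", "Western")[ri]
      n_users <- config$n_users_per_region
      mu <- config$utterances_per_user$mean
      size <- config$utterances_per_user$dispersion
      n_utt <- if (mu <= 1) rep(1L, n_users) else
        1L + stats::rnbinom(n_users, mu = mu - 1, size = size)
      n_tot <- sum(n_utt)
      user_id <- rep(sprintf("%s_user%05d", tolower(region), seq_len(n_users)),
                     times = n_utt)
      country <- rep(sample(region_countries[[region]], n_users, replace = TRUE),
                     times = n_utt)
      category <- sample(cats, n_tot, replace = TRUE,
                         prob = config$category_mixture[[region]])
      keyworded <- stats::runif(n_tot) < config$keyword_rate
      styled <- stats::runif(n_tot) < config$region_style_strength
      text <- vapply(seq_len(n_tot), function(i)
        make_utterance(category[i], region, keyworded[i], styled[i],
                       banks, styles), character(1))
      hour <- sample_hours(n_tot, config$diurnal[[region]])
      day <- sample(0:1705, n_tot, replace = TRUE)   # 2016-05-01 .. 2020-12-31
      ts <- sprintf("%s %02d:%02d:%02d",
                    as.character(as.Date("2016-05-01") + day),
                    hour,
                    sample(0:59, n_tot, replace = TRUE),
                    sample(0:59, n_tot, replace = TRUE))
      rows[[ri]] <- data.frame(
        utterance_id = sprintf("u%07d", uid0 + seq_len(n_tot)),
        user_id = user_id,
        country = country,
        region = region,
        timestamp = ts,
        user_text = text,
        bot_text = sample(bot_replies, n_tot, replace = TRUE),
        category = category,
        stringsAsFactors = FALSE)
      uid0 <- uid0 + n_tot
    }
    do.call(rbind, rows)
  })

  true_labels <- stats::setNames(records$category, records$utterance_id)
  corpus <- new_chat_corpus(records[, CORPUS_FIELDS])

  n_lab <- ceiling(config$labeled_fraction * nrow(corpus))
  lab_ids <- with_seed(derive_seed(config$seed, "labeled_subset"),
                       sample(corpus$utterance_id, n_lab))
  annotations <- simulate_raters(true_labels[lab_ids],
                                 n_raters = config$n_raters,
                                 rater_accuracy = config$rater_accuracy,
                                 seed = derive_seed(config$seed, "raters"))

  structure(list(records = corpus, true_labels = true_labels,
                 annotations = annotations, config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$records), " records, ",
      nrow(x$annotations), " annotated by ", ncol(x$annotations),
      " raters (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate a panel of independent raters
#'
#' Each rater independently reports the true category with probability
#' \code{rater_accuracy} and otherwise a uniform draw from the other 7
#' categories -- a symmetric-confusion error model whose chance-agreement
#' algebra makes the resulting Fleiss kappa analytically predictable.
#'
#' @param true_labels Named character vector (item id -> true category).
#' @param n_raters Number of raters.
#' @param rater_accuracy Per-rater probability of emitting the true label.
#' @param seed Integer seed.
#' @param categories Category universe.
#' @return Character matrix, items x raters, rownames = item ids.
#' @export
simulate_raters <- function(true_labels, n_raters = 4, rater_accuracy = 0.95,
                            seed = 1, categories = chatmood_categories()) {
  stopifnot(rater_accuracy >= 0, rater_accuracy <= 1, n_raters >= 1)
  n <- length(true_labels)
  m <- with_seed(seed, {
    out <- matrix(NA_character_, n, n_raters)
    for (j in seq_len(n_raters)) {
      correct <- stats::runif(n) < rater_accuracy
      wrong <- vapply(true_labels, function(truth) {
        others <- setdiff(categories, truth)
        others[sample.int(length(others), 1)]
      }, character(1))
      out[, j] <- ifelse(correct, true_labels, wrong)
    }
    out
  })
  rownames(m) <- names(true_labels)
  colnames(m) <- sprintf("rater%d", seq_len(n_raters))
  m
}
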