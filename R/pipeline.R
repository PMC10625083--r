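#' Pipeline configuration
#'
#' A run configuration bundles the generator settings, stage parameters and
#' a global seed; stage-level sub-seeds are derived by stable hashing so
#' stages rerun in isolation reproduce what the full pipeline did. Unknown
#' keys are rejected. Configurations can also be read from YAML with
#' \code{read_run_config()}.
#'
#' @param generator A \code{\link{generator_config}} (or a list of its
#'   arguments).
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed (overrides the generator seed).
#' @param lexicons Lexicon directory (default: the packaged demonstration
#'   set).
#' @param model Model family for classification stages.
#' @param threshold Pseudo-labeling / high-confidence threshold.
#' @param max_iters Self-training iteration cap.
#' @param embedding_dim Embedding dimension used by the feature stack.
#' @param min_count Vocabulary frequency cutoff.
#' @param vocab_scope \code{"train"} (default; vocabulary from training
#'   split only, the leakage-safe choice) or \code{"all"} (entire corpus).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(generator = generator_config(), out_dir = tempdir(),
                       seed = 1, lexicons = NULL, model = "mlp",
                       threshold = 0.9, max_iters = 3, embedding_dim = 64,
                       min_count = 5, vocab_scope = c("train", "all")) {
  if (!inherits(generator, "generator_config"))
    generator <- do.call(generator_config, generator)
  vocab_scope <- match.arg(vocab_scope)
  generator$seed <- derive_seed(seed, "generator")
  structure(list(generator = generator, out_dir = out_dir, seed = seed,
                 lexicons = lexicons, model = model, threshold = threshold,
                 max_iters = max_iters, embedding_dim = embedding_dim,
                 min_count = min_count, vocab_scope = vocab_scope),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose top-level keys are the arguments of
#'   \code{run_config} (generator settings under \code{generator:}).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$generator)) {
    gen_allowed <- names(formals(generator_config))
    gen_unknown <- setdiff(names(raw$generator), gen_allowed)
    if (length(gen_unknown) > 0)
      stop("unknown generator key(s): ", paste(gen_unknown, collapse = ", "),
           call. = FALSE)
    if (!is.null(raw$generator$category_mixture))
      raw$generator$category_mixture <-
        lapply(raw$generator$category_mixture, unlist)
  }
  do.call(run_config, raw)
}

PIPELINE_STAGES <- c("simulate", "filter", "sample", "lexstats", "ngrams",
                     "temporal", "agreement", "featurize", "train",
                     "selftrain", "distributions", "report")

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order: simulate a corpus,
#' keyword-filter it, sample one utterance per user, compute lexicon
#' contrasts / n-grams / diurnal profiles, score inter-rater agreement and
#' consensus labels, build the feature stack, train the supervised baseline,
#' run self-training, tabulate category distributions with chi-square
#' comparisons, and render the report. Artifacts are written under
#' \code{config$out_dir}, each stamped with the seed and configuration hash.
#' A stage failure stops the run with an error naming the stage.
#'
#' @param config A \code{\link{run_config}}.
#' @param stages Subset of stages to run (dependencies must be included;
#'   default: all).
#' @return Named list of stage outputs, invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(config = config)
  results <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage ", sQuote(name), " failed: ",
           conditionMessage(e), call. = FALSE))
  }

  for (stage in stages) {
    switch(stage,
      simulate = run_stage("simulate", {
        state$corpus <- generate_corpus(config$generator)
        write_corpus(state$corpus$records,
                     file.path(config$out_dir, "corpus.jsonl"), "jsonl")
        utils::write.table(
          data.frame(utterance_id = names(state$corpus$true_labels),
                     category = unname(state$corpus$true_labels)),
          file.path(config$out_dir, "labels.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        write_annotations(state$corpus$annotations,
                          file.path(config$out_dir, "annotations.tsv"))
      }),
      filter = run_stage("filter", {
        state$filtered <- filter_by_keywords(state$corpus$records,
                                              keyword_set("depressed_sad"))
      }),
      sample = run_stage("sample", {
        state$sampled <- sample_one_per_user(
          state$filtered, derive_seed(config$seed, "sample"))
      }),
      lexstats = run_stage("lexstats", {
        lex <- if (is.null(config$lexicons)) demo_lexicons()
               else read_lexicon_set(config$lexicons)
        dat <- state$sampled
        east <- dat$user_text[dat$region == "Eastern"]
        west <- dat$user_text[dat$region == "Western"]
        rows <- lapply(names(lex), function(cat) {
          se <- score_lexicon(east, lex[[cat]])
          sw <- score_lexicon(west, lex[[cat]])
          w <- tryCatch(welch_t_from_samples(se, sw), error = function(e) NULL)
          if (is.null(w))   # degenerate category (e.g. no matches at all)
            return(data.frame(category = cat, t = NA_real_, df = NA_real_,
                              p = NA_real_,
                              mean_eastern = mean(se, na.rm = TRUE),
                              sd_eastern = NA_real_,
                              mean_western = mean(sw, na.rm = TRUE),
                              sd_western = NA_real_,
                              stringsAsFactors = FALSE))
          data.frame(category = cat, t = w$t, df = w$df, p = w$p,
                     mean_eastern = w$group1$mean, sd_eastern = w$group1$sd,
                     mean_western = w$group2$mean, sd_western = w$group2$sd,
                     stringsAsFactors = FALSE)
        })
        results$welch <- do.call(rbind, rows)
      }),
      ngrams = run_stage("ngrams", {
        results$ngrams <- rbind(
          cbind(n = 1, top_ngrams(state$sampled$user_text, n = 1, k = 10)),
          cbind(n = 2, top_ngrams(state$sampled$user_text, n = 2, k = 10)))
      }),
      temporal = run_stage("temporal", {
        results$hourly <- hourly_profile(state$corpus$records)
      }),
      agreement = run_stage("agreement", {
        results$agreement <- fleiss_kappa(state$corpus$annotations)
        state$consensus <- consensus_filter(state$corpus$annotations)
      }),
      featurize = run_stage("featurize", {
        labeled_ids <- names(state$consensus$kept)
        texts <- stats::setNames(state$corpus$records$user_text,
                                 state$corpus$records$utterance_id)
        vocab_texts <- if (config$vocab_scope == "all") texts
                       else texts[labeled_ids]
        state$vocab <- build_vocab(vocab_texts, min_count = config$min_count)
        state$features <- feature_matrix(texts, state$vocab,
                                          dim = config$embedding_dim,
                                          ids = names(texts))
      }),
      train = run_stage("train", {
        labels <- state$consensus$kept
        split <- split_train_test(labels, 0.2,
                                  seed = derive_seed(config$seed, "split"))
        state$split <- split
        spec <- model_spec(config$model,
                           seed = derive_seed(config$seed, "model"))
        state$spec <- spec
        results$metrics <- train_and_evaluate(
          list(spec),
          state$features[split$train, , drop = FALSE], labels[split$train],
          state$features[split$test, , drop = FALSE], labels[split$test])
      }),
      selftrain = run_stage("selftrain", {
        labels <- state$consensus$kept
        split <- state$split
        pool_ids <- setdiff(state$corpus$records$utterance_id, names(labels))
        st <- self_train(state$spec,
                         state$features[split$train, , drop = FALSE],
                         labels[split$train],
                         state$features[pool_ids, , drop = FALSE],
                         threshold = config$threshold,
                         max_iters = config$max_iters,
                         test_ids = split$test)
        state$selftrain <- st
        m <- suppressWarnings(evaluate_predictions(
          labels[split$test],
          predict_proba(st$model,
                        state$features[split$test, , drop = FALSE])))
        results$metrics <- rbind(
          results$metrics,
          data.frame(family = paste0(config$model, "_selftrained"),
                     accuracy = m$accuracy, auroc = m$auroc, f1 = m$f1,
                     precision = m$precision, recall = m$recall,
                     n_eval = m$n_eval, note = st$stop_reason,
                     stringsAsFactors = FALSE))
      }),
      distributions = run_stage("distributions", {
        labels <- predict_label(state$selftrain$model, state$features)
        names(labels) <- rownames(state$features)
        groups <- stats::setNames(state$corpus$records$region,
                                  state$corpus$records$utterance_id)
        shares <- category_shares(labels, groups)
        results$shares <- shares
        results$chi_square <- per_category_chi_square(shares$Eastern,
                                                       shares$Western)
        pooled <- category_distribution(
          shares$Eastern$counts + shares$Western$counts, "all")
        results$reference <- compare_to_reference(pooled,
                                                   twitter_reference())
      }),
      report = run_stage("report", {
        render_report(results, seed = config$seed, config = config,
                      path = file.path(config$out_dir, "report"))
      }))
  }
  invisible(results)
}
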