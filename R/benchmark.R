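#' The packaged semisupervised-learning benchmark
#'
#' A fixed synthetic benchmark for the self-training classifier: 8,000
#' single-utterance users (4,000 per region) drawn from a uniform mixture
#' over the 8 categories, 1% of records labeled through the simulated-rater
#' and consensus pipeline, and a 1,000-item held-out ground-truth evaluation
#' set. Features are multi-hot bag-of-words over a vocabulary built from the
#' text available at training time (labeled plus unlabeled pool, never
#' evaluation text; frequency cutoff 5 -- in semisupervised learning the
#' unlabeled pool is legitimately available for representation building),
#' part-of-speech counts, and a 64-dimensional hashing embedding. A
#' multilayer perceptron is self-trained at threshold 0.9 for up to 3
#' rounds. Returns supervised-baseline and self-trained metrics on the same
#' evaluation set, plus high-confidence evaluations of both models.
#'
#' @param seed Integer seed controlling generation, splits and fits.
#' @param n_users_per_region Users per region (default 4000).
#' @param n_eval Held-out evaluation items (default 1000).
#' @param threshold Pseudo-labeling / high-confidence threshold.
#' @param max_iters Self-training round cap.
#' @return List with \code{supervised} and \code{selftrained} metric lists
#'   (see \code{\link{evaluate_predictions}}), \code{high_confidence} and
#'   \code{high_confidence_supervised} (see
#'   \code{\link{high_confidence_eval}}), \code{stop_reason},
#'   \code{n_labeled}, \code{n_pool}, and \code{n_pseudo}.
#' @export
ssl_benchmark <- function(seed, n_users_per_region = 4000, n_eval = 1000,
                          threshold = 0.9, max_iters = 3) {
  mix <- stats::setNames(rep(1 / 8, 8), chatmood_categories())
  cfg <- generator_config(
    n_users_per_region = n_users_per_region,
    utterances_per_user = list(mean = 1, dispersion = 1),
    category_mixture = list(Eastern = mix, Western = mix),
    labeled_fraction = 0.01,
    seed = seed)
  syn <- generate_corpus(cfg)
  texts <- stats::setNames(syn$records$user_text, syn$records$utterance_id)
  lab_ids <- rownames(syn$annotations)
  labels <- consensus_filter(syn$annotations)$kept
  rest <- setdiff(names(texts), lab_ids)
  eval_ids <- with_seed(derive_seed(seed, "benchmark_eval"),
                        sample(rest, n_eval))
  pool_ids <- setdiff(rest, eval_ids)
  vocab <- build_vocab(texts[c(names(labels), pool_ids)], min_count = 5)
  x <- feature_matrix(texts, vocab, dim = 64, ids = names(texts))
  truth <- syn$true_labels[eval_ids]
  spec <- model_spec("mlp", seed = derive_seed(seed, "benchmark_model"))

  base <- fit_model(spec, x[names(labels), , drop = FALSE], labels)
  supervised <- suppressWarnings(
    evaluate_predictions(truth, predict_proba(base, x[eval_ids, , drop = FALSE])))
  hc_base <- high_confidence_eval(base, x[eval_ids, , drop = FALSE], truth,
                                  threshold = threshold)
  st <- self_train(spec, x[names(labels), , drop = FALSE], labels,
                   x[pool_ids, , drop = FALSE], threshold = threshold,
                   max_iters = max_iters, test_ids = eval_ids)
  selftrained <- suppressWarnings(
    evaluate_predictions(truth,
                         predict_proba(st$model, x[eval_ids, , drop = FALSE])))
  hc <- high_confidence_eval(st$model, x[eval_ids, , drop = FALSE], truth,
                             threshold = threshold)
  list(supervised = supervised, selftrained = selftrained,
       high_confidence = hc, high_confidence_supervised = hc_base,
       stop_reason = st$stop_reason,
       n_labeled = length(labels), n_pool = length(pool_ids),
       n_pseudo = nrow(st$pseudo_labels))
}
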