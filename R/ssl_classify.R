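#' Specify a classification model
#'
#' Five families are supported: a multilayer perceptron (\code{nnet}), a
#' radial-kernel support vector machine with probability calibration
#' (\code{e1071}), a random forest, Gaussian naive Bayes, and gradient
#' boosted trees (\code{xgboost}). Every family exposes class probabilities
#' for all 8 categories. Default hyperparameters are fixed and seeded.
#'
#' @param family One of \code{"mlp"}, \code{"svm"}, \code{"random_forest"},
#'   \code{"naive_bayes"}, \code{"gradient_boosted_trees"}.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed used for the fit.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(family = c("mlp", "svm", "random_forest",
                                  "naive_bayes", "gradient_boosted_trees"),
                       params = list(), seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    mlp = list(size = 8, decay = 1e-4, maxit = 60),
    svm = list(cost = 1, kernel = "radial"),
    random_forest = list(ntree = 200),
    naive_bayes = list(),
    gradient_boosted_trees = list(nrounds = 50, max_depth = 4, eta = 0.3))
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults, seed = seed),
            class = "model_spec")
}

#' Stratified train/test split of a labeled set
#'
#' Disjoint and exhaustive; stratified by category by default (each
#' category's items are split in the configured proportion), deterministic
#' for a fixed seed.
#'
#' @param labels Named character vector (item id -> category).
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param seed Integer seed.
#' @param stratified Stratify by category?
#' @return List with \code{train} and \code{test} (character vectors of ids).
#' @export
split_train_test <- function(labels, test_fraction = 0.2, seed = 1,
                             stratified = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1, !is.null(names(labels)))
  ids <- names(labels)
  with_seed(seed, {
    if (stratified) {
      test <- character(0)
      for (cat in sort(unique(labels))) {
        members <- ids[labels == cat]
        if (length(members) < 2)
          stop("category ", sQuote(cat),
               " has <2 items; cannot stratify", call. = FALSE)
        n_test <- max(1L, round(length(members) * test_fraction))
        test <- c(test, sample(members, n_test))
      }
    } else {
      test <- sample(ids, round(length(ids) * test_fraction))
    }
    list(train = setdiff(ids, test), test = sort(test))
  })
}

#' Fit a classifier on a feature matrix
#'
#' @param spec A \code{\link{model_spec}}.
#' @param x Numeric feature matrix (rows = items).
#' @param y Character/factor labels aligned with rows of \code{x}.
#' @param categories Full category universe (probability columns always cover
#'   all of these, with zeros for categories absent from training).
#' @return Object of class \code{chatmood_model}.
#' @export
fit_model <- function(spec, x, y, categories = chatmood_categories()) {
  stopifnot(inherits(spec, "model_spec"), nrow(x) == length(y))
  y <- factor(as.character(y), levels = intersect(categories, unique(as.character(y))))
  p <- spec$params
  fit <- with_seed(spec$seed, switch(spec$family,
    mlp = {
      if (nlevels(y) < 2) list(single_class = levels(y))
      else nnet::nnet(x, nnet::class.ind(y), size = p$size, decay = p$decay,
                      maxit = p$maxit, softmax = TRUE, trace = FALSE,
                      MaxNWts = 1e6)
    },
    svm = e1071::svm(x, y, probability = TRUE, cost = p$cost,
                     kernel = p$kernel),
    random_forest = randomForest::randomForest(x, y, ntree = p$ntree),
    naive_bayes = {
      keep <- apply(x, 2, stats::sd) > 0
      list(fit = e1071::naiveBayes(as.data.frame(x[, keep, drop = FALSE]), y),
           keep = keep)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = nlevels(y),
                                       max_depth = p$max_depth, eta = p$eta,
                                       nthread = 1, seed = spec$seed),
                         data = dtrain, nrounds = p$nrounds, verbose = 0)
    }))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 categories = categories, n_features = ncol(x)),
            class = "chatmood_model")
}

#' Predicted class probabilities
#'
#' One row per item, one column per category (all 8, in fixed order); rows
#' sum to 1.
#'
#' @param model A fitted \code{chatmood_model}.
#' @param x Feature matrix.
#' @return Numeric matrix, \code{nrow(x)} x 8.
#' @export
predict_proba <- function(model, x) {
  if (!inherits(model, "chatmood_model"))
    stop("model is not a fitted chatmood_model", call. = FALSE)
  stopifnot(ncol(x) == model$n_features)
  lv <- model$levels
  raw <- switch(model$spec$family,
    mlp = {
      if (!is.null(model$fit$single_class))
        matrix(1, nrow(x), 1, dimnames = list(NULL, lv))
      else {
        pr <- stats::predict(model$fit, x)
        colnames(pr) <- lv
        pr
      }
    },
    svm = {
      pr <- attr(stats::predict(model$fit, x, probability = TRUE),
                 "probabilities")
      pr[, lv, drop = FALSE]
    },
    random_forest = {
      pr <- stats::predict(model$fit, x, type = "prob")
      pr[, lv, drop = FALSE]
    },
    naive_bayes = {
      xd <- as.data.frame(x[, model$fit$keep, drop = FALSE])
      pr <- stats::predict(model$fit$fit, xd, type = "raw")
      pr[, lv, drop = FALSE]
    },
    gradient_boosted_trees = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      matrix(pr, ncol = length(lv), byrow = TRUE,
             dimnames = list(NULL, lv))
    })
  out <- matrix(0, nrow(x), length(model$categories),
                dimnames = list(rownames(x), model$categories))
  out[, lv] <- as.matrix(raw)
  # guard against tiny numeric drift in backends
  out / rowSums(out)
}

#' Predicted labels (argmax of class probabilities)
#'
#' @param model A fitted \code{chatmood_model}.
#' @param x Feature matrix.
#' @return Character vector of categories.
#' @export
predict_label <- function(model, x) {
  proba <- predict_proba(model, x)
  colnames(proba)[max.col(proba, ties.method = "first")]
}

#' Macro one-vs-rest area under the ROC curve
#'
#' For each category present in \code{truth} with at least one positive and
#' one negative item, the one-vs-rest AUC is computed by the rank (Mann-
#' Whitney) method with mid-ranks for ties, then averaged with equal class
#' weight. Classes that cannot be scored are excluded and reported.
#'
#' @param truth Character vector of true categories.
#' @param proba Probability matrix (columns named by category).
#' @return List with \code{auroc} (macro average), \code{per_class}, and
#'   \code{skipped} (classes without both a positive and a negative).
#' @export
macro_auroc <- function(truth, proba) {
  per <- c(); skipped <- character(0)
  for (cat in colnames(proba)) {
    pos <- truth == cat
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) { skipped <- c(skipped, cat); next }
    r <- rank(proba[, cat])
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    per[[cat]] <- auc
  }
  if (length(skipped) > 0)
    warning("AUROC skipped for class(es) absent from evaluation: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  list(auroc = if (length(per) > 0) mean(unlist(per)) else NA_real_,
       per_class = unlist(per), skipped = skipped)
}

#' Evaluation metrics for multi-class predictions
#'
#' Accuracy, macro one-vs-rest AUROC, and macro F1/precision/recall with
#' equal class weight over the categories present in \code{truth}
#' (a class with no predicted positives contributes precision 0).
#'
#' @param truth Character vector of true categories.
#' @param proba Probability matrix from \code{\link{predict_proba}}.
#' @return List with \code{accuracy}, \code{auroc}, \code{f1},
#'   \code{precision}, \code{recall}, \code{n_eval}, \code{per_class},
#'   \code{auroc_skipped}.
#' @export
evaluate_predictions <- function(truth, proba) {
  stopifnot(length(truth) == nrow(proba))
  pred <- colnames(proba)[max.col(proba, ties.method = "first")]
  classes <- sort(unique(truth))
  per_class <- lapply(classes, function(cat) {
    tp <- sum(pred == cat & truth == cat)
    fp <- sum(pred == cat & truth != cat)
    fn <- sum(pred != cat & truth == cat)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  names(per_class) <- classes
  pc <- do.call(rbind, per_class)
  au <- macro_auroc(truth, proba)
  list(accuracy = mean(pred == truth),
       auroc = au$auroc,
       f1 = mean(pc[, "f1"]),
       precision = mean(pc[, "precision"]),
       recall = mean(pc[, "recall"]),
       n_eval = length(truth),
       per_class = pc,
       auroc_skipped = au$skipped)
}

#' Train and evaluate a set of supervised models
#'
#' One metrics row per model, computed on the test items only. A model that
#' fails to fit is flagged (\code{note} column) and the run continues.
#'
#' @param specs List of \code{\link{model_spec}}s.
#' @param x_train,y_train Training features and labels.
#' @param x_test,y_test Test features and labels.
#' @return Data frame: family, accuracy, auroc, f1, precision, recall,
#'   n_eval, note.
#' @export
train_and_evaluate <- function(specs, x_train, y_train, x_test, y_test) {
  rows <- lapply(specs, function(spec) {
    res <- tryCatch({
      model <- fit_model(spec, x_train, y_train)
      m <- suppressWarnings(evaluate_predictions(y_test,
                                                 predict_proba(model, x_test)))
      data.frame(family = spec$family, accuracy = m$accuracy,
                 auroc = m$auroc, f1 = m$f1, precision = m$precision,
                 recall = m$recall, n_eval = m$n_eval, note = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(family = spec$family, accuracy = NA_real_,
                 auroc = NA_real_, f1 = NA_real_, precision = NA_real_,
                 recall = NA_real_, n_eval = 0L,
                 note = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Semisupervised self-training with pseudo-labeling
#'
#' Implements the four-step loop: (1) train on the labeled data, (2) assign
#' pseudo-labels to unlabeled pool items whose maximum predicted class
#' probability exceeds \code{threshold} (strictly), (3) retrain from scratch
#' on labeled plus pseudo-labeled data, (4) repeat until no new labels reach
#' the threshold, the pool empties, or \code{max_iters} is hit. Pseudo-labels
#' are frozen once assigned and never revisited.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param x_labeled,y_labeled Labeled features and labels.
#' @param x_pool Feature matrix of the unlabeled pool; rownames are item ids.
#' @param threshold Pseudo-labeling confidence threshold (default 0.9,
#'   exclusive; \code{threshold = 1} is the degenerate never-label case).
#' @param max_iters Maximum number of pseudo-labeling rounds.
#' @param test_ids Ids that must never be pseudo-labeled (leakage guard);
#'   any pool rows with these ids are dropped with a warning.
#' @return List with \code{model} (trained on the final augmented set),
#'   \code{history} (one record per round: \code{iteration}, \code{n_new},
#'   \code{pool_remaining}, \code{pseudo} = data frame of id/label/
#'   confidence), \code{stop_reason} (\code{"no_new_labels"},
#'   \code{"pool_empty"}, or \code{"max_iters"}), and
#'   \code{pseudo_labels} (all frozen pseudo-labels).
#' @export
self_train <- function(spec, x_labeled, y_labeled, x_pool,
                       threshold = 0.9, max_iters = 10, test_ids = NULL) {
  stopifnot(nrow(x_labeled) >= 1, threshold > 0, threshold <= 1)
  if (is.null(rownames(x_pool)))
    rownames(x_pool) <- sprintf("pool%06d", seq_len(nrow(x_pool)))
  if (!is.null(test_ids)) {
    clash <- intersect(rownames(x_pool), test_ids)
    if (length(clash) > 0) {
      warning(length(clash), " test item(s) removed from the unlabeled pool",
              call. = FALSE)
      x_pool <- x_pool[!(rownames(x_pool) %in% test_ids), , drop = FALSE]
    }
  }
  x_train <- x_labeled
  y_train <- as.character(y_labeled)
  history <- list()
  pseudo_all <- data.frame(id = character(), label = character(),
                           confidence = numeric(), stringsAsFactors = FALSE)
  stop_reason <- NULL
  model <- fit_model(spec, x_train, y_train)
  iter <- 0L
  while (is.null(stop_reason)) {
    if (nrow(x_pool) == 0) { stop_reason <- "pool_empty"; break }
    if (iter >= max_iters) { stop_reason <- "max_iters"; break }
    iter <- iter + 1L
    proba <- predict_proba(model, x_pool)
    conf <- apply(proba, 1, max)
    new <- conf > threshold
    if (!any(new)) { stop_reason <- "no_new_labels"; break }
    labels <- colnames(proba)[max.col(proba, ties.method = "first")]
    batch <- data.frame(id = rownames(x_pool)[new], label = labels[new],
                        confidence = conf[new], stringsAsFactors = FALSE)
    x_train <- rbind(x_train, x_pool[new, , drop = FALSE])
    y_train <- c(y_train, batch$label)
    x_pool <- x_pool[!new, , drop = FALSE]
    pseudo_all <- rbind(pseudo_all, batch)
    history[[iter]] <- list(iteration = iter, n_new = nrow(batch),
                            pool_remaining = nrow(x_pool), pseudo = batch)
    model <- fit_model(spec, x_train, y_train)
  }
  list(model = model, history = history, stop_reason = stop_reason,
       pseudo_labels = pseudo_all, n_train_final = nrow(x_train))
}

#' Evaluation restricted to high-confidence predictions
#'
#' Metrics over only those test items whose maximum predicted class
#' probability is at least \code{threshold} (inclusive); the retained count
#' is reported. If nothing is retained, an explicit empty-result signal is
#' returned instead of NaN metrics.
#'
#' @param model A fitted \code{chatmood_model}.
#' @param x_test,y_test Test features and labels.
#' @param threshold Confidence threshold (default 0.9).
#' @return Metrics list as \code{\link{evaluate_predictions}} plus
#'   \code{n_total} and \code{retained_fraction}; or, when no item reaches
#'   the threshold, \code{list(empty = TRUE, n_eval = 0, n_total = ...)}.
#' @export
high_confidence_eval <- function(model, x_test, y_test, threshold = 0.9) {
  proba <- predict_proba(model, x_test)
  conf <- apply(proba, 1, max)
  keep <- conf >= threshold
  if (!any(keep))
    return(list(empty = TRUE, n_eval = 0L, n_total = length(y_test)))
  m <- suppressWarnings(
    evaluate_predictions(y_test[keep], proba[keep, , drop = FALSE]))
  m$n_total <- length(y_test)
  m$retained_fraction <- mean(keep)
  m$empty <- FALSE
  m
}
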