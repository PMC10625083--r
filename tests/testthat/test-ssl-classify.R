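test_that("train/test splits are disjoint, exhaustive and stratified", {
  labels <- stats::setNames(rep(cats8, each = 25), sprintf("i%03d", 1:200))
  sp <- split_train_test(labels, test_fraction = 0.2, seed = 1)
  expect_length(sp$train, 160)
  expect_length(sp$test, 40)
  expect_setequal(c(sp$train, sp$test), names(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # per-stratum arithmetic: 20 train / 5 test per category
  for (cat in cats8) {
    expect_equal(sum(labels[sp$test] == cat), 5)
    expect_equal(sum(labels[sp$train] == cat), 20)
  }
  expect_identical(sp, split_train_test(labels, 0.2, seed = 1))
  expect_false(identical(sp$test, split_train_test(labels, 0.2, seed = 2)$test))

  tiny <- stats::setNames(c("etc", "apathy_sadness"), c("a", "b"))
  expect_error(split_train_test(tiny, 0.2, 1, stratified = TRUE), "<2")
})

test_that("probability predictions are proper distributions over all 8 classes", {
  labels <- random_labels(120, seed = 4)
  x <- separable_features(labels, seed = 4)
  for (family in c("mlp", "svm", "random_forest", "naive_bayes",
                   "gradient_boosted_trees")) {
    model <- fit_model(model_spec(family, seed = 2), x, labels)
    p <- predict_proba(model, x[1:20, , drop = FALSE])
    expect_equal(dim(p), c(20, 8))
    expect_equal(colnames(p), cats8)
    expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-6)
    expect_true(all(p >= 0))
    # argmax consistency and repeat-call determinism
    expect_equal(predict_label(model, x[1:20, , drop = FALSE]),
                 colnames(p)[max.col(p, ties.method = "first")])
    expect_equal(predict_proba(model, x[1:20, , drop = FALSE]), p)
  }
  expect_error(predict_proba(list(), x), "chatmood_model")
})

test_that("macro AUROC matches the brute-force pairwise oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 40
    truth <- sample(cats8[1:4], n, replace = TRUE)
    proba <- matrix(runif(n * 8), n, 8, dimnames = list(NULL, cats8))
    proba <- proba / rowSums(proba)
    mine <- suppressWarnings(macro_auroc(truth, proba))
    for (cat in names(mine$per_class)) {
      expect_equal(mine$per_class[[cat]],
                   auc_oracle(proba[, cat], truth == cat),
                   tolerance = 1e-9)
    }
    expect_equal(mine$auroc, mean(unlist(mine$per_class)), tolerance = 1e-12)
  }
  # classes absent from truth are skipped with a warning
  expect_warning(macro_auroc(rep("etc", 5),
                             matrix(1 / 8, 5, 8,
                                    dimnames = list(NULL, cats8))),
                 "absent")
})

test_that("supervised evaluation behaves at the separable and chance extremes", {
  labels <- random_labels(200, seed = 5)
  x <- separable_features(labels, seed = 5)
  sp <- split_train_test(labels, 0.2, seed = 5)
  res <- train_and_evaluate(list(model_spec("mlp", seed = 1)),
                            x[sp$train, ], labels[sp$train],
                            x[sp$test, ], labels[sp$test])
  expect_equal(res$accuracy, 1)
  expect_equal(res$f1, 1)

  # chance level: labels independent of features
  set.seed(6)
  y_tr <- random_labels(400, seed = 7)
  x_tr <- matrix(rnorm(400 * 10), 400)
  y_te <- random_labels(800, seed = 8)
  x_te <- matrix(rnorm(800 * 10), 800)
  colnames(x_tr) <- colnames(x_te) <- sprintf("f%d", 1:10)
  res2 <- train_and_evaluate(list(model_spec("mlp", seed = 2)),
                             x_tr, y_tr, x_te, y_te)
  ci <- 4 * sqrt(0.125 * 0.875 / 800)
  expect_lt(abs(res2$accuracy - 0.125), ci)

  # a failing model is flagged while the run continues
  res3 <- train_and_evaluate(list(model_spec("svm", params = list(cost = -1),
                                             seed = 1),
                                  model_spec("mlp", seed = 1)),
                             x[sp$train, ], labels[sp$train],
                             x[sp$test, ], labels[sp$test])
  expect_match(res3$note[1], "failed")
  expect_equal(res3$accuracy[2], 1)
})

test_that("self-training honors thresholds, freezes pseudo-labels and guards leakage", {
  labels <- random_labels(160, seed = 12)
  x <- separable_features(labels, seed = 12)
  lab_ids <- names(labels)[1:40]
  pool_ids <- names(labels)[41:140]
  test_ids <- names(labels)[141:160]
  spec <- model_spec("mlp", seed = 3)

  # threshold 1: nothing can exceed it; model equals the supervised baseline
  st1 <- self_train(spec, x[lab_ids, ], labels[lab_ids], x[pool_ids, ],
                    threshold = 1, max_iters = 5)
  expect_equal(st1$stop_reason, "no_new_labels")
  expect_equal(nrow(st1$pseudo_labels), 0)
  expect_length(st1$history, 0)

  # normal run: confidences exceed the threshold, ids disjoint per iteration
  st <- self_train(spec, x[lab_ids, ], labels[lab_ids], x[pool_ids, ],
                   threshold = 0.9, max_iters = 5)
  expect_true(all(st$pseudo_labels$confidence > 0.9))
  expect_false(anyDuplicated(st$pseudo_labels$id) > 0)
  expect_true(all(st$pseudo_labels$id %in% pool_ids))
  # pseudo-label accuracy on separable data is at least the baseline's
  agree <- mean(st$pseudo_labels$label == labels[st$pseudo_labels$id])
  expect_gte(agree, 0.95)

  # max_iters bounds the history
  st2 <- self_train(spec, x[lab_ids, ], labels[lab_ids], x[pool_ids, ],
                    threshold = 0.9, max_iters = 1)
  expect_lte(length(st2$history), 1)

  # leakage guard: test ids are expelled from the pool with a warning
  expect_warning(
    st3 <- self_train(spec, x[lab_ids, ], labels[lab_ids],
                      x[c(pool_ids[1:10], test_ids), ],
                      threshold = 0.9, max_iters = 2, test_ids = test_ids),
    "test item")
  expect_length(intersect(st3$pseudo_labels$id, test_ids), 0)
})

test_that("high-confidence evaluation filters by maximum predicted probability", {
  labels <- random_labels(150, seed = 20)
  x <- separable_features(labels, seed = 20)
  sp <- split_train_test(labels, 0.3, seed = 20)
  model <- fit_model(model_spec("mlp", seed = 1),
                     x[sp$train, ], labels[sp$train])
  full <- suppressWarnings(
    evaluate_predictions(labels[sp$test], predict_proba(model, x[sp$test, ])))

  # threshold 0 retains everything and reproduces the plain evaluation
  hc0 <- high_confidence_eval(model, x[sp$test, ], labels[sp$test], 0)
  expect_equal(hc0$accuracy, full$accuracy)
  expect_equal(hc0$n_eval, full$n_eval)

  # an unreachable threshold gives the explicit empty signal, not NaNs
  hc1 <- high_confidence_eval(model, x[sp$test, ], labels[sp$test],
                              threshold = 1 + 1e-9)
  expect_true(hc1$empty)
  expect_equal(hc1$n_eval, 0L)
})
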