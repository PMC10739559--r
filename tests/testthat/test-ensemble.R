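test_that("soft vote averages probabilities with ties called case", {
  v <- soft_vote(c(0.6, 0.8, 0.7, 0.9, 0.55))
  expect_equal(v$probability, 0.71)
  expect_equal(v$label, 1L)
  tie <- soft_vote(rep(0.5, 4))
  expect_equal(tie$probability, 0.5)
  expect_equal(tie$label, 1L) # >= 0.5 convention
  expect_equal(soft_vote(0.2)$label, 0L)
  expect_error(soft_vote(numeric()), "no member")
  expect_error(soft_vote(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hard vote takes the majority with ties going to control", {
  expect_equal(hard_vote(c(1, 1, 1, 0, 0)), 1L)
  expect_equal(hard_vote(c(0, 0, 0, 0, 0)), 0L)
  expect_message(tie <- hard_vote(c(1, 0)), "tie", class = "igenes_tie")
  expect_equal(tie, 0L)
  expect_error(hard_vote(integer()), "no member")
  expect_error(hard_vote(c(1, 2)), "0/1")
})

test_that("every base classifier separates a strong synthetic signal", {
  sf <- small_fit()
  preds <- predict(sf$model, sf$parts$train)
  y <- cigt_labels(sf$parts$train)
  for (m in sf$model$enabled) {
    expect_gte(mean(preds[[paste0(m, "_label")]] == y), 0.95)
  }
})

test_that("a singleton ensemble's voters equal its only member", {
  sf <- small_fit()
  solo <- train_ensemble(sf$parts$train, sf$model$feature_names,
                         members = "rf", seed = 11)
  expect_equal(solo$enabled, "rf")
  preds <- predict(solo, sf$parts$test)
  expect_equal(preds$soft_vote_prob, preds$rf_prob)
  expect_equal(preds$hard_vote_label, preds$rf_label)
})

test_that("refitting with identical inputs and seed reproduces predictions", {
  sf <- small_fit()
  m2 <- train_ensemble(sf$parts$train, sf$model$feature_names, seed = 11,
                       control = ensemble_control(mlp_size = 10))
  p1 <- predict(sf$model, sf$parts$test)
  p2 <- predict(m2, sf$parts$test)
  expect_identical(p1, p2)
})

test_that("the scaler is fitted on training rows only and invertible", {
  sf <- small_fit()
  x <- cigt_matrix(sf$parts$train)[, sf$model$feature_names]
  expect_equal(sf$model$scaler$center, colMeans(x))
  expect_equal(sf$model$scaler$scale, apply(x, 2, sd))
  xs <- scale(x, sf$model$scaler$center, sf$model$scaler$scale)
  back <- sweep(sweep(unclass(xs), 2, sf$model$scaler$scale, "*"),
                2, sf$model$scaler$center, "+")
  expect_equal(max(abs(back - x)), 0, tolerance = 1e-9)
})

test_that("voters agree with unanimous members across a prediction table", {
  sf <- small_fit()
  preds <- predict(sf$model, sf$parts$test)
  labels <- as.matrix(preds[paste0(sf$model$enabled, "_label")])
  unanimous <- apply(labels, 1, function(r) length(unique(r)) == 1)
  expect_gt(sum(unanimous), 0)
  expect_equal(preds$hard_vote_label[unanimous], labels[unanimous, 1])
  expect_equal(preds$soft_vote_label[unanimous], labels[unanimous, 1])
})

test_that("degenerate inputs raise named errors", {
  sf <- small_fit()
  one_class <- sf$parts$train[cigt_labels(sf$parts$train) == 1, ]
  one_class <- as_cigt(as.data.frame(one_class)) |> suppressWarnings()
  expect_error(train_ensemble(one_class, sf$model$feature_names, seed = 1),
               "2 samples per class")
  expect_error(train_ensemble(sf$parts$train, c("gene_001", "ghost"), seed = 1),
               "ghost")
  dropped <- as_cigt(as.data.frame(sf$parts$test)[
    setdiff(names(sf$parts$test), "gene_001")])
  expect_error(predict(sf$model, dropped), "missing")
})

test_that("evaluation metrics match hand counts and degenerate AUC is NA", {
  sf <- small_fit()
  ev <- evaluate_ensemble(sf$model, sf$parts$test)
  expect_setequal(ev$metrics$classifier,
                  c(sf$model$enabled, "soft_vote", "hard_vote"))
  expect_true(all(ev$metrics$accuracy >= 0 & ev$metrics$accuracy <= 1))
  expect_true(all(ev$metrics$auc >= 0 & ev$metrics$auc <= 1))
  expect_equal(unique(ev$metrics$n_eval), nrow(sf$parts$test))

  # hand oracle: accuracy 0.5 when half the predictions match
  expect_equal(mean(c(1, 1, 0, 0) == c(1, 0, 1, 0)), 0.5)
  y <- cigt_labels(sf$parts$test)
  acc_rf <- mean(ev$predictions$rf_label == y)
  expect_equal(ev$metrics$accuracy[ev$metrics$classifier == "rf"], acc_rf)
  # perfect prediction gives perfect metrics
  sep <- ev$metrics[ev$metrics$accuracy == 1, ]
  if (nrow(sep) > 0) expect_true(all(sep$f1 == 1))

  single <- sf$parts$test[cigt_labels(sf$parts$test) == 1, ]
  single <- suppressWarnings(as_cigt(as.data.frame(single)))
  expect_warning(ev1 <- evaluate_ensemble(sf$model, single), "single class")
  expect_true(all(is.na(ev1$metrics$auc)))
  expect_true(all(!is.na(ev1$metrics$accuracy)))
})

test_that("tidy and glance summarize a fit", {
  sf <- small_fit()
  td <- generics::tidy(sf$model)
  expect_equal(nrow(td), length(sf$model$enabled) + 2)
  expect_equal(sum(td$role == "voter"), 2)
  gl <- generics::glance(sf$model)
  expect_equal(gl$n_features, length(sf$model$feature_names))
  expect_equal(gl$seed, 11)
})
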