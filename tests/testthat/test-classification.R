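test_that("KNN with k = 1 reproduces training labels on a separable toy set", {
  toy <- toy_features()
  model <- fit_emotion_model(toy, method = "knn", k = 1)
  expect_equal(predict(model, toy), toy$label)
})

test_that("training validates its inputs", {
  toy <- toy_features()
  one_class <- dplyr::filter(toy, label == "happy")
  expect_error(fit_emotion_model(one_class, method = "svm"), "single class")

  bad <- toy
  bad$f1[3] <- NaN
  expect_error(fit_emotion_model(bad, method = "svm"), "f1")

  expect_error(
    fit_emotion_model(toy, labels = c("happy", "sad"), method = "svm"),
    "match"
  )
})

test_that("prediction validates feature shape and names the sizes", {
  model <- fit_emotion_model(toy_features(), method = "svm")
  err <- expect_error(predict(model, matrix(rnorm(5), 1)), "expected 2")
  expect_match(conditionMessage(err), "5")
  expect_error(
    predict(model, tibble::tibble(bogus = 1, other = 2)),
    "mismatch"
  )
})

test_that("a persisted-then-loaded model predicts identically", {
  feats <- synthetic_features(6, seed = 300, channels = frontal_channels())
  for (method in c("svm", "knn")) {
    model <- fit_emotion_model(feats, method = method, seed = 1)
    path <- withr::local_tempfile(fileext = ".json")
    write_emotion_model(model, path)
    restored <- read_emotion_model(path)
    probe <- matrix(rnorm(100 * 72), 100)
    expect_identical(predict(model, probe), predict(restored, probe))
    expect_equal(restored$classes, model$classes)
    expect_equal(restored$hyperparameters, model$hyperparameters)
  }
  # version mismatch is refused
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(version = 99), path2, auto_unbox = TRUE)
  expect_error(read_emotion_model(path2), "version")
})

test_that("stratified folds are disjoint, covering, and balanced", {
  labels <- rep(emotion_labels(), times = c(13, 12, 12, 11))
  fold <- affectr:::make_stratified_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), length(labels))
  # per-class balance within one
  for (cl in emotion_labels()) {
    per <- table(factor(fold[labels == cl], levels = 1:10))
    expect_lte(max(per) - min(per), 1)
  }
  # reproducible given the seed
  expect_identical(fold, affectr:::make_stratified_folds(labels, 10, seed = 3))
})

test_that("cross-validation reports are seed-stable and sum correctly", {
  set.seed(77)
  n <- 120
  labels <- rep(emotion_labels(), each = n / 4)
  feats <- tibble::tibble(
    label = labels,
    coded = as.numeric(factor(labels)) + rnorm(n, sd = 0.05),
    noise = rnorm(n)
  )
  r1 <- cross_validate(feats, method = "svm", folds = 10, seed = 5)
  r2 <- cross_validate(feats, method = "svm", folds = 10, seed = 5)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$confusion, r2$confusion)

  expect_equal(r1$n_folds, 10)
  expect_equal(sum(r1$confusion), n)
  expect_equal(
    unname(rowSums(r1$confusion)),
    as.vector(table(labels)[rownames(r1$confusion)], mode = "double")
  )
  expect_true(all(r1$fold_accuracy >= 0 & r1$fold_accuracy <= 1))

  # a class-coded feature is essentially perfectly separable
  expect_gte(r1$mean_accuracy, 0.99)
  r3 <- cross_validate(feats, method = "svm", folds = 10, seed = 1234)
  expect_gte(r3$mean_accuracy, 0.95) # other shuffle seeds stay separable

  expect_error(cross_validate(feats[1:5, ], folds = 10), "folds")
})

test_that("tidy and glance summarize models and CV reports", {
  feats <- toy_features()
  model <- fit_emotion_model(feats, method = "knn", k = 1)
  td <- tidy(model)
  expect_equal(td$class, c("happy", "sad"))
  expect_equal(td$n_train, c(4L, 4L))
  gl <- glance(model)
  expect_equal(gl$n_features, 2L)
  expect_equal(gl$method, "knn")

  r <- cross_validate(rbind(feats, feats), method = "knn", folds = 4, seed = 1, k = 1)
  expect_equal(nrow(tidy(r)), 4)
  expect_equal(glance(r)$mean_accuracy, r$mean_accuracy)
})

test_that("a calm epoch is recognized as calm on well-separated synthetic classes", {
  train <- synthetic_features(12, seed = 500)
  model <- fit_emotion_model(train, method = "svm", seed = 1)
  hits <- vapply(1:50, function(i) {
    ep <- segment_epochs(simulate_recording("calm", 1.5, seed = 7000 + i))
    predict(model, hjorth_features(ep)) == "calm"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
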