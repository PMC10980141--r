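test_that("cross-validation splits have the right shape, no leakage, and are seeded", {
  ids <- sprintf("d%03d", 1:100)
  splits <- make_cv_splits(ids, folds = 10, test_fraction = 0.2, seed = 5)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_length(sp$test, 20L)
    expect_length(sp$train, 80L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_true(all(c(sp$train, sp$test) %in% ids))
  }
  expect_identical(splits, make_cv_splits(ids, folds = 10,
                                          test_fraction = 0.2, seed = 5))
  expect_false(identical(splits, make_cv_splits(ids, folds = 10,
                                                test_fraction = 0.2,
                                                seed = 6)))

  # disjoint mode: test folds partition the ids
  dj <- make_cv_splits(ids, folds = 10, seed = 5, method = "disjoint")
  all_test <- unlist(lapply(dj, `[[`, "test"))
  expect_identical(sort(all_test), sort(ids))
  expect_identical(anyDuplicated(all_test), 0L)

  expect_error(make_cv_splits(c("a", "b"), folds = 2), "at least 5")
})

test_that("reference backend separates token-distinguishable classes and honors its contract", {
  corp <- make_clean_corpus(n_patients = 80, seed = 31)
  ds <- build_span_dataset(corp$notes,
                           data.frame(note_id = corp$notes$note_id,
                                      label = corp$notes$psh_label),
                           n = 16, scope = "psh")
  cfg <- train_config(seed = 12, folds = 5)
  model <- backend_fit(reference_backend(), ds$text, ds$label, cfg)
  pred <- backend_predict(model, ds$text)
  expect_true(all(pred$labels %in% c("POSITIVE", "NEGATIVE")))
  expect_equal(unname(rowSums(pred$scores)), rep(1, nrow(ds)))
  # prediction is defined for records never seen in training
  unseen <- backend_predict(model, c("entirely novel wording here", ""))
  expect_length(unseen$labels, 2L)
  # single-class training data is rejected
  expect_error(backend_fit(reference_backend(), ds$text,
                           rep("POSITIVE", nrow(ds)), cfg), "two classes")
})

test_that("run_cv reports per-fold and summary metrics deterministically", {
  corp <- make_clean_corpus(n_patients = 80, seed = 31)
  ds <- build_span_dataset(corp$notes,
                           data.frame(note_id = corp$notes$note_id,
                                      label = corp$notes$psh_label),
                           n = 16, scope = "psh")
  cfg <- train_config(seed = 12, folds = 5)
  cv <- run_cv(ds, reference_backend(), cfg)
  expect_s3_class(cv, "stb_cv")
  expect_length(cv$folds, 5L)
  # summary mean lies between per-fold min and max for every metric
  for (m in names(cv$per_fold)) {
    mu <- cv$summary$mean[cv$summary$metric == m]
    expect_gte(mu, min(cv$per_fold[[m]]))
    expect_lte(mu, max(cv$per_fold[[m]]))
  }
  # sample (n-1) standard deviation
  expect_equal(cv$summary$sd[cv$summary$metric == "f1_weighted"],
               stats::sd(cv$per_fold$f1_weighted))
  # identical config + seed -> identical reports
  cv2 <- run_cv(ds, reference_backend(), cfg)
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_identical(cv$summary, cv2$summary)
})

test_that("majority-class prediction on balanced data scores near one half", {
  # a backend that learns nothing and predicts one class
  majority_backend <- structure(list(), class = "test_majority_backend")
  registerS3method("backend_fit", "test_majority_backend",
                   function(backend, texts, labels, config) {
                     tab <- sort(table(labels), decreasing = TRUE)
                     structure(list(lab = names(tab)[1]),
                               class = "test_majority_model")
                   }, envir = asNamespace("stbhistory"))
  registerS3method("backend_predict", "test_majority_model",
                   function(model, texts) {
                     list(labels = rep(model$lab, length(texts)),
                          scores = matrix(1, length(texts), 1,
                                          dimnames = list(NULL, model$lab)))
                   }, envir = asNamespace("stbhistory"))
  set.seed(88)
  n <- 200
  ds <- data.frame(
    doc_id = sprintf("d%03d", 1:n),
    text = replicate(n, paste(sample(letters, 8), collapse = " ")),
    label = rep(c("POSITIVE", "NEGATIVE"), n / 2),
    stringsAsFactors = FALSE)
  cv <- run_cv(ds, majority_backend, train_config(seed = 2, folds = 10))
  acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  # 3 binomial sigma around 0.5 over 10 x 40 held-out predictions
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / (10 * 40)) + 0.05)
})
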