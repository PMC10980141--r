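#' Training configuration
#'
#' Hyperparameters of the span classifier.  The transformer-oriented fields
#' (`batch_size`, `learning_rate`, `dropout`, `epochs`, `optimizer`,
#' `freeze_early_layers`) are part of the backend contract and are passed
#' through to whatever backend is in use; the shipped reference backend (a
#' ridge-penalised logistic regression over token counts) only consumes
#' `lambda` and `seed`, and ignores the rest.
#'
#' @param batch_size Mini-batch size (default 16).
#' @param learning_rate Fixed learning rate (default 1e-5).
#' @param dropout Dropout probability (default 0.3).
#' @param epochs Training epochs (default 5).
#' @param optimizer Optimizer name (default "adamw", the decoupled
#'   weight-decay Adam variant).
#' @param freeze_early_layers Keep early encoder layers unchanged and tune
#'   only the last layers (default TRUE).
#' @param window_n Context window size in words (default 16; the sweep
#'   studied is 8, 16, 24, 32).
#' @param seed RNG seed for splits and backend fitting.
#' @param folds Number of cross-validation evaluations (default 10).
#' @param test_fraction Held-out fraction per evaluation (default 0.2).
#' @param lambda Ridge penalty of the reference backend (default 0.01).
#' @return Object of class `stb_train_config`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-5,
                         dropout = 0.3, epochs = 5L, optimizer = "adamw",
                         freeze_early_layers = TRUE, window_n = 16L,
                         seed = 1L, folds = 10L, test_fraction = 0.2,
                         lambda = 0.01) {
  stopifnot(batch_size >= 1, epochs >= 1, folds >= 1,
            dropout >= 0, dropout < 1,
            test_fraction > 0, test_fraction < 1, lambda > 0)
  structure(list(
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    dropout = dropout, epochs = as.integer(epochs), optimizer = optimizer,
    freeze_early_layers = isTRUE(freeze_early_layers),
    window_n = as.integer(window_n), seed = as.integer(seed),
    folds = as.integer(folds), test_fraction = test_fraction,
    lambda = lambda
  ), class = "stb_train_config")
}

#' Cross-validation splits
#'
#' Default method `"subsample"` draws `folds` independent random
#' train/test partitions, each holding out `round(test_fraction * N)`
#' documents (repeated random sub-sampling, e.g. ten 80/20 splits).
#' Method `"disjoint"` is conventional k-fold: a seeded permutation split
#' into `folds` disjoint test folds that partition the ids.
#'
#' @param doc_ids Vector of document ids (N >= 5).
#' @param folds Number of splits.
#' @param test_fraction Held-out fraction (ignored for `"disjoint"`).
#' @param seed RNG seed; identical seeds give identical splits.
#' @param method `"subsample"` or `"disjoint"`.
#' @return List of `folds` lists, each with `fold`, `train`, `test`.
#' @export
make_cv_splits <- function(doc_ids, folds = 10L, test_fraction = 0.2,
                           seed = 1L, method = c("subsample", "disjoint")) {
  method <- match.arg(method)
  n <- length(doc_ids)
  if (n < 5L) stopf("need at least 5 documents for cross-validation, got %d", n)
  if (anyDuplicated(doc_ids)) stopf("doc_ids must be unique")
  with_seed(seed, {
    if (method == "subsample") {
      n_test <- max(1L, round(test_fraction * n))
      lapply(seq_len(folds), function(k) {
        test <- sort(sample(doc_ids, n_test))
        list(fold = k, train = setdiff(doc_ids, test), test = test)
      })
    } else {
      perm <- sample(doc_ids)
      assign_fold <- sort(rep(seq_len(folds), length.out = n))
      lapply(seq_len(folds), function(k) {
        test <- sort(perm[assign_fold == k])
        list(fold = k, train = setdiff(doc_ids, test), test = test)
      })
    }
  })
}

#' Reference classifier backend
#'
#' A deterministic, desk-scale backend satisfying the backend contract:
#' lower-cased token counts as features and a ridge-penalised logistic
#' regression (glmnet, `alpha = 0`, fixed `lambda`) as the model.  It is a
#' first-class classifier in its own right and doubles as the
#' cross-validation harness's default backend; heavier encoder backends
#' plug in through the same two generics.
#'
#' @return Object of classes `stb_backend_reference`/`stb_backend`.
#' @seealso [backend_fit()], [backend_predict()], [run_cv()]
#' @export
reference_backend <- function() {
  structure(list(name = "reference"),
            class = c("stb_backend_reference", "stb_backend"))
}

#' Fit a classifier backend
#'
#' Backend contract: `backend_fit(backend, texts, labels, config)` returns
#' a fitted model object; [backend_predict()] on that object returns
#' predicted labels and per-class scores for any texts, including ones
#' never seen in training.  Fitting must be deterministic given
#' `config$seed`.
#'
#' @param backend A backend object, e.g. [reference_backend()].
#' @param texts Character vector of span texts.
#' @param labels Binary label vector aligned with `texts`.
#' @param config A [train_config()].
#' @return A fitted model object.
#' @export
backend_fit <- function(backend, texts, labels, config = train_config()) {
  UseMethod("backend_fit")
}

#' Predict with a fitted backend model
#'
#' @param model Fitted model from [backend_fit()].
#' @param texts Character vector of span texts.
#' @return List with `labels` (character vector) and `scores` (matrix, one
#'   column per class, rows summing to 1).
#' @export
backend_predict <- function(model, texts) {
  UseMethod("backend_predict")
}

span_tokens <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
}

span_dtm <- function(texts, vocab = NULL) {
  toks <- lapply(texts, span_tokens)
  if (is.null(vocab)) vocab <- sort(unique(unlist(toks)))
  if (length(vocab) < 2L) vocab <- c(vocab, ".dummy1", ".dummy2")[1:2]
  i <- integer(); j <- integer(); x <- numeric()
  for (d in seq_along(toks)) {
    hit <- match(toks[[d]], vocab)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) next
    cnt <- table(hit)
    i <- c(i, rep(d, length(cnt)))
    j <- c(j, as.integer(names(cnt)))
    x <- c(x, as.numeric(cnt))
  }
  list(m = Matrix::sparseMatrix(i = i, j = j, x = x,
                                dims = c(length(texts), length(vocab))),
       vocab = vocab)
}

#' @rdname backend_fit
#' @export
backend_fit.stb_backend_reference <- function(backend, texts, labels,
                                              config = train_config()) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    stopf("reference backend needs two classes in training data, got: %s",
          paste(lev, collapse = ", "))
  }
  dtm <- span_dtm(texts)
  y <- factor(labels, levels = lev)
  fit <- with_seed(config$seed, {
    glmnet::glmnet(dtm$m, y, family = "binomial", alpha = 0,
                   lambda = c(10, 1, 0.1, config$lambda),
                   standardize = FALSE)
  })
  structure(list(fit = fit, vocab = dtm$vocab, levels = lev,
                 lambda = config$lambda),
            class = "stb_reference_model")
}

#' @rdname backend_predict
#' @export
backend_predict.stb_reference_model <- function(model, texts) {
  dtm <- span_dtm(texts, vocab = model$vocab)
  p2 <- as.numeric(stats::predict(model$fit, dtm$m, s = model$lambda,
                                  type = "response"))
  scores <- cbind(1 - p2, p2)
  colnames(scores) <- model$levels
  labels <- model$levels[(p2 > 0.5) + 1L]
  list(labels = labels, scores = scores)
}

#' @export
print.stb_reference_model <- function(x, ...) {
  cat(sprintf(
    "<stb_reference_model> ridge logistic regression: %d features, classes %s (lambda=%g)\n",
    length(x$vocab), paste(x$levels, collapse = "/"), x$lambda))
  invisible(x)
}

#' @export
predict.stb_reference_model <- function(object, newdata, ...) {
  backend_predict(object, newdata)
}

#' Cross-validated evaluation of a span classifier
#'
#' For each split: fit the backend on the training documents, predict the
#' held-out documents, and score accuracy plus macro/weighted
#' precision/recall/F1.  The summary reports the mean and sample (n-1)
#' standard deviation of each metric across folds.  Folds whose training
#' half contains a single class are skipped with a warning and recorded.
#'
#' @param dataset Span dataset from [build_span_dataset()] (`doc_id`,
#'   `text`, `label`).
#' @param backend Backend object; default [reference_backend()].
#' @param config A [train_config()] (folds, test_fraction, seed, ...).
#' @param method Split method, see [make_cv_splits()].
#' @return Object of class `stb_cv`: `folds` (list of per-fold `stb_eval`
#'   reports), `summary` (data.frame metric/mean/sd), `skipped`, `config`.
#' @export
run_cv <- function(dataset, backend = reference_backend(),
                   config = train_config(), method = "subsample") {
  stopifnot(all(c("doc_id", "text", "label") %in% names(dataset)))
  if (length(unique(dataset$label)) < 2L) {
    stopf("dataset must contain at least two classes")
  }
  splits <- make_cv_splits(dataset$doc_id, folds = config$folds,
                           test_fraction = config$test_fraction,
                           seed = config$seed, method = method)
  reports <- list(); skipped <- integer()
  for (sp in splits) {
    tr <- dataset[dataset$doc_id %in% sp$train, , drop = FALSE]
    te <- dataset[dataset$doc_id %in% sp$test, , drop = FALSE]
    if (length(unique(tr$label)) < 2L) {
      warnf("fold %d skipped: single-class training split", sp$fold)
      skipped <- c(skipped, sp$fold)
      next
    }
    fold_config <- config
    fold_config$seed <- config$seed + sp$fold
    model <- backend_fit(backend, tr$text, tr$label, fold_config)
    pred <- backend_predict(model, te$text)
    rep <- eval_report(te$label, pred$labels,
                       labels = sort(unique(dataset$label)))
    rep$fold <- sp$fold
    reports[[length(reports) + 1L]] <- rep
  }
  if (!length(reports)) stopf("all folds were skipped")
  metric_rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(accuracy = r$accuracy,
               precision_macro = r$macro["precision"],
               recall_macro = r$macro["recall"],
               f1_macro = r$macro["f1"],
               precision_weighted = r$weighted["precision"],
               recall_weighted = r$weighted["recall"],
               f1_weighted = r$weighted["f1"],
               row.names = NULL)
  }))
  summary <- data.frame(
    metric = names(metric_rows),
    mean = vapply(metric_rows, mean, numeric(1)),
    sd = vapply(metric_rows, function(v) {
      if (length(v) > 1) stats::sd(v) else NA_real_
    }, numeric(1)),
    row.names = NULL
  )
  structure(list(folds = reports, per_fold = metric_rows, summary = summary,
                 skipped = skipped, config = config),
            class = "stb_cv")
}

#' @export
print.stb_cv <- function(x, digits = 2, ...) {
  cat(sprintf("<stb_cv> %d evaluated fold(s)%s\n", length(x$folds),
              if (length(x$skipped))
                sprintf(" (%d skipped)", length(x$skipped)) else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-19s %.*f ± %.*f\n", s$metric[i], digits, s$mean[i],
                digits, s$sd[i]))
  }
  invisible(x)
}
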