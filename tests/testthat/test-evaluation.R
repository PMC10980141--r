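test_that("confusion counts are exact and reject malformed input", {
  gold <- c("P", "P", "P", "N", "N")
  pred <- c("P", "P", "N", "N", "N")
  cc <- compute_confusion(gold, pred)
  p <- cc[cc$class == "P", ]
  expect_identical(c(p$tp, p$fn, p$fp), c(2L, 1L, 0L))
  n <- cc[cc$class == "N", ]
  expect_identical(c(n$tp, n$fn, n$fp), c(2L, 0L, 1L))

  same <- compute_confusion(gold, gold)
  expect_true(all(same$fp == 0L) && all(same$fn == 0L))

  expect_error(compute_confusion(gold, pred[-1]), "length")
  expect_error(compute_confusion(gold, c("P", "P", "X", "N", "N"),
                                 labels = c("P", "N")), "label set")
})

test_that("precision/recall/F1 and averages match the formula oracle exactly", {
  gold <- c("P", "P", "P", "N", "N")
  pred <- c("P", "P", "N", "N", "N")
  rep <- eval_report(gold, pred)
  expect_equal(rep$accuracy, 0.8)
  expect_equal(unname(rep$macro["f1"]), 0.8)
  expect_equal(unname(rep$weighted["f1"]), 0.8)

  perfect <- eval_report(gold, gold)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))

  wrong <- eval_report(c("P", "N"), c("N", "P"))
  expect_equal(wrong$accuracy, 0)
  expect_true(all(wrong$per_class$f1 == 0))

  # 100 random label configurations against the independent formula oracle
  set.seed(1234)
  for (trial in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(20:100, 1)
    classes <- LETTERS[1:k]
    g <- sample(classes, n, replace = TRUE)
    p <- sample(classes, n, replace = TRUE)
    got <- eval_report(g, p, labels = classes)
    want <- oracle_prf(g, p, classes)
    expect_lt(max(abs(got$per_class$precision - want$per_class[, "precision"])), 1e-12)
    expect_lt(max(abs(got$per_class$recall - want$per_class[, "recall"])), 1e-12)
    expect_lt(max(abs(got$per_class$f1 - want$per_class[, "f1"])), 1e-12)
    expect_lt(max(abs(got$macro - want$macro)), 1e-12)
    expect_lt(max(abs(got$weighted - want$weighted)), 1e-12)
    expect_equal(got$accuracy, want$accuracy)
    # micro-consistency: weighted recall equals accuracy
    expect_lt(abs(got$weighted[["recall"]] - got$accuracy), 1e-12)
  }
})

test_that("Cohen's kappa reproduces closed-form values and its symmetries", {
  a <- c("P", "N", "P", "N", "P", "P")
  expect_equal(cohens_kappa(a, a), 1.0)

  tab <- matrix(c(40, 5, 5, 50), 2, byrow = TRUE)
  expect_equal(cohens_kappa(tab), oracle_kappa(tab))
  expect_equal(cohens_kappa(tab), (0.90 - 0.505) / (1 - 0.505))

  dis <- matrix(c(0, 5, 5, 0), 2, byrow = TRUE)
  expect_equal(cohens_kappa(dis), -1.0)

  # symmetry in arguments and invariance under label renaming
  set.seed(7)
  x <- sample(c("P", "N"), 50, replace = TRUE)
  y <- sample(c("P", "N"), 50, replace = TRUE)
  expect_equal(cohens_kappa(x, y), cohens_kappa(y, x))
  ren <- c(P = "yes", N = "no")
  expect_equal(cohens_kappa(ren[x], ren[y]), cohens_kappa(x, y))

  # degenerate marginals: complete agreement on a single label
  expect_equal(cohens_kappa(rep("P", 4), rep("P", 4)), 1.0)
})

test_that("ICD baseline counts qualifying codes on or before the index date only", {
  gold <- data.frame(patient_id = sprintf("p%02d", 1:10), label = "POSITIVE")
  idx <- data.frame(patient_id = gold$patient_id, index_date = "2018-06-01")
  cls <- data.frame(patient_id = gold$patient_id,
                    label = c(rep("POSITIVE", 9), "NEGATIVE"))
  icd <- data.frame(
    patient_id = c("p01", "p02", "p03", "p04"),
    code = c("R45.851", "X71.0", "I10", "T14.91"),
    date = c("2017-05-01", "2018-06-01", "2017-01-01", "2018-06-02"),
    stringsAsFactors = FALSE)
  cmp <- icd_baseline_compare(gold, icd, cls, idx)
  # p01 prior code; p02 code exactly on the index date (inclusive);
  # p03 non-qualifying code; p04 code after index -> not counted
  expect_identical(cmp$n_gold_positive, 10L)
  expect_identical(cmp$n_coded, 2L)
  expect_equal(cmp$coded_fraction, 0.2)
  expect_identical(cmp$n_detected, 9L)

  empty <- icd_baseline_compare(gold, icd[0, ], cls, idx)
  expect_equal(empty$coded_fraction, 0)

  # unparseable dates are skipped with a warning, not fatal
  bad <- rbind(icd, data.frame(patient_id = "p05", code = "R45.851",
                               date = "06/01/2017"))
  expect_warning(cmp2 <- icd_baseline_compare(gold, bad, cls, idx),
                 "unparseable")
  expect_identical(cmp2$n_coded, 2L)

  # ICD-9 E-range and V codes qualify by prefix
  icd9 <- data.frame(patient_id = c("p01", "p02"),
                     code = c("E950.3", "V62.84"),
                     date = "2017-01-01", stringsAsFactors = FALSE)
  cmp3 <- icd_baseline_compare(gold, icd9, cls, idx)
  expect_identical(cmp3$n_coded, 2L)
})
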