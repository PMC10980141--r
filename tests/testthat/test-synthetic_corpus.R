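test_that("generation is deterministic per seed and respects forced configurations", {
  cfg <- synthetic_config(n_patients = 20, seed = 99)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$instances, c2$instances)
  expect_identical(c1$icd, c2$icd)
  c3 <- generate_corpus(synthetic_config(n_patients = 20, seed = 100))
  expect_false(identical(c1$notes$text, c3$notes$text))

  # zero prevalence means zero positive patients and notes
  c0 <- generate_corpus(synthetic_config(n_patients = 30, psh_prevalence = 0,
                                         fsh_prevalence = 0, seed = 5))
  expect_identical(sum(c0$patients$psh_label == "POSITIVE"), 0L)
  expect_identical(sum(c0$notes$psh_label == "POSITIVE"), 0L)

  # forced single affirmed instance per note
  cf <- generate_corpus(synthetic_config(
    n_patients = 10, notes_per_patient = 1L, psh_prevalence = 1,
    fsh_prevalence = 0, negation_rate = 0, multi_instance_rate = 0,
    timestamp_style_rate = 0, seed = 8))
  per_note <- table(cf$instances$note_id)
  expect_true(all(per_note == 1))
  expect_true(all(cf$instances$polarity == "AFFIRMED"))
  expect_true(all(cf$instances$scope == "PERSONAL"))
  expect_true(all(cf$notes$psh_label == "POSITIVE"))

  # timestamp-style surface forms carry a date and no explicit modifier
  ct <- generate_corpus(synthetic_config(
    n_patients = 10, notes_per_patient = 1L, psh_prevalence = 1,
    fsh_prevalence = 0, negation_rate = 0, multi_instance_rate = 0,
    timestamp_style_rate = 1, seed = 8))
  expect_true(all(ct$instances$template_family == "timestamp_style"))
  carrier <- vapply(seq_len(nrow(ct$instances)), function(i) {
    txt <- ct$notes$text[ct$notes$note_id == ct$instances$note_id[i]]
    line <- regmatches(txt, regexpr("[^\n]*suicid[^\n]*", txt,
                                    ignore.case = TRUE))
    line
  }, character(1))
  expect_true(all(grepl("\\d", carrier)))
  expect_false(any(grepl("history of|h/o|prior|past", carrier,
                         ignore.case = TRUE)))
})

test_that("planted offsets point at the planted surface strings", {
  corp <- make_clean_corpus(n_patients = 30, seed = 17)
  for (i in seq_len(nrow(corp$instances))) {
    txt <- corp$notes$text[corp$notes$note_id == corp$instances$note_id[i]]
    expect_identical(substring(txt, corp$instances$start[i] + 1,
                               corp$instances$end[i]),
                     corp$instances$surface[i])
  }
})

test_that("stored gold labels are re-derivable from planted instances via the document rule", {
  corp <- generate_corpus(synthetic_config(n_patients = 40, seed = 23,
                                           timestamp_style_rate = 0.3))
  for (i in seq_len(nrow(corp$notes))) {
    nid <- corp$notes$note_id[i]
    for (sc in c("PERSONAL", "FAMILY")) {
      sub <- corp$instances[corp$instances$note_id == nid &
                              corp$instances$scope == sc, , drop = FALSE]
      want <- oracle_doc_label(sub$polarity[order(sub$start)])
      col <- if (sc == "PERSONAL") "psh_label" else "fsh_label"
      expect_identical(corp$notes[[col]][i], want)
    }
  }
})

test_that("positive fraction tracks the configured prevalence within binomial error", {
  corp <- generate_corpus(synthetic_config(n_patients = 1000,
                                           psh_prevalence = 0.3, seed = 61))
  frac <- mean(corp$patients$psh_label == "POSITIVE")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("distractor-only notes contain the string 'suicide' but no instances", {
  corp <- generate_corpus(synthetic_config(
    n_patients = 15, notes_per_patient = 1L, psh_prevalence = 0,
    fsh_prevalence = 0, negation_rate = 0, distractor_rate = 1, seed = 3))
  expect_identical(nrow(corp$instances), 0L)
  expect_true(all(grepl("suicide", corp$notes$text, ignore.case = TRUE)))
  expect_true(all(corp$notes$psh_label == "NEGATIVE"))
  # and the rule engine finds nothing in them
  rep <- extraction_report(corp)
  expect_equal(rep$psh$accuracy, 1)
  expect_equal(rep$fsh$accuracy, 1)
})
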