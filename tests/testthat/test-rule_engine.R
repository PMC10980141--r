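setup_note <- function(text, lexicon = default_lexicon()) {
  tokens <- tokenize_clinical(text)
  list(text = text, tokens = tokens,
       sentences = segment_sentences(text, tokens), lexicon = lexicon)
}

test_that("concept matching hits lexicon targets, honors exclusions, case and longest-match", {
  lex <- default_lexicon()
  f <- function(text) {
    s <- setup_note(text, lex)
    find_concept_mentions(s$text, s$tokens, s$sentences, lex)
  }
  m1 <- f("endorses suicidal ideation")
  expect_identical(nrow(m1), 1L)
  expect_identical(m1$category, "SI")

  expect_identical(nrow(f("pt reports cutting behavior")), 0L)

  m2 <- f("SUICIDE ATTEMPT x2")
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$category, "SA")

  # longest match wins: "suicide attempt" beats the bare "suicide" pattern
  m3 <- f("suicide attempt by overdose")
  expect_identical(m3$matched_text, "suicide attempt")

  # offset integrity
  m4 <- f("He denies suicidal ideation today.")
  expect_identical(substring("He denies suicidal ideation today.",
                             m4$start + 1, m4$end), m4$matched_text)
})

test_that("adding a matched phrase to exclusions never increases instance count", {
  texts <- c("history of suicide attempt",
             "h/o suicidal ideation and prior suicide attempt",
             "mother has a history of suicidal behavior")
  lex <- default_lexicon()
  for (text in texts) {
    base <- extract_instances(text, lex)
    lex2 <- unclass(lex)
    lex2$exclusions <- c(lex2$exclusions, "suicide attempts?")
    lex2$target_concepts$SA <-
      setdiff(lex2$target_concepts$SA, "suicide attempts?")
    lex2 <- validate_lexicon(lex2)
    expect_lte(nrow(extract_instances(text, lex2)), nrow(base))
  }
})

test_that("history modifiers are found by kind, temporal patterns switchable", {
  lex <- default_lexicon()
  f <- function(text, temporal = TRUE) {
    s <- setup_note(text, lex)
    find_history_modifiers(s$text, s$tokens, s$sentences, lex,
                           use_temporal = temporal)
  }
  m1 <- f("history of SA")
  expect_identical(m1$matched_text[1], "history of")
  expect_identical(m1$kind[1], "explicit_history")

  m2 <- f("h/o SI")
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$matched_text, "h/o")

  expect_identical(nrow(f("suicidal ideation today")), 0L)

  m3 <- f("suicide attempt in 2014")
  expect_identical(m3$kind, "temporal")
  expect_identical(m3$matched_text, "in 2014")
  expect_identical(nrow(f("suicide attempt in 2014", temporal = FALSE)), 0L)
})

test_that("concepts pair with the nearest same-sentence modifier within range", {
  lex <- default_lexicon()
  pair_for <- function(text, max_d = 10L) {
    s <- setup_note(text, lex)
    con <- find_concept_mentions(s$text, s$tokens, s$sentences, lex)
    mod <- find_history_modifiers(s$text, s$tokens, s$sentences, lex)
    list(pairs = pair_concept_modifier(con, mod, max_d), con = con, mod = mod)
  }
  expect_identical(nrow(pair_for("history of suicide attempt")$pairs), 1L)

  # modifier in another sentence does not pair
  p2 <- pair_for("suicidal ideation. History of depression.")
  expect_identical(nrow(p2$pairs), 0L)

  # nearest of two modifiers wins (brute-force nearest-neighbour check)
  p3 <- pair_for("past psych hx notable for remote chronic insomnia and suicidal ideation")
  expect_identical(nrow(p3$pairs), 1L)
  dists <- vapply(seq_len(nrow(p3$mod)), function(j) {
    abs(p3$con$first_token[1] - p3$mod$last_token[j])
  }, integer(1))
  expect_identical(p3$mod$matched_text[p3$pairs$modifier],
                   p3$mod$matched_text[which.min(dists)])

  # out of range: no pair
  p4 <- pair_for("history of many long standing untreated chronic recurrent severe daily migraine headaches and also suicidal ideation",
                 max_d = 5L)
  expect_identical(nrow(p4$pairs), 0L)
})

test_that("negation follows cue scope, termination cues and pseudo-negations", {
  lex <- default_lexicon()
  polarity_of <- function(text, category = NULL, scope_tokens = 6L) {
    s <- setup_note(text, lex)
    con <- find_concept_mentions(s$text, s$tokens, s$sentences, lex)
    if (!is.null(category)) con <- con[con$category == category, , drop = FALSE]
    assign_polarity(s$text, s$tokens, s$sentences, con[1, ], lex, scope_tokens)
  }
  expect_identical(polarity_of("denies any history of suicidal ideation"),
                   "NEGATED")
  expect_identical(polarity_of("history of suicide attempt in 2005"),
                   "AFFIRMED")
  # "but" terminates the scope of "denies" before the SA concept
  expect_identical(
    polarity_of("denies SI but endorses prior suicide attempt", "SA"),
    "AFFIRMED")
  expect_identical(
    polarity_of("denies SI but endorses prior suicide attempt", "SI"),
    "NEGATED")
  # cue beyond the scope window does not negate
  expect_identical(
    polarity_of("no acute distress noted on exam today regarding prior suicidal ideation",
                scope_tokens = 6L),
    "AFFIRMED")
  # pseudo-negation does not negate
  expect_identical(
    polarity_of("no change in prior suicidal ideation"), "AFFIRMED")
})

test_that("family scope requires a kinship term within the proximity window", {
  lex <- default_lexicon()
  scope_of <- function(text, proximity = 5L) {
    s <- setup_note(text, lex)
    con <- find_concept_mentions(s$text, s$tokens, s$sentences, lex)
    mod <- find_history_modifiers(s$text, s$tokens, s$sentences, lex)
    pr <- pair_concept_modifier(con, mod, 10L)
    attribute_scope(s$text, s$tokens, s$sentences, con[pr$concept[1], ],
                    mod[pr$modifier[1], ], lex, proximity)
  }
  expect_identical(scope_of("father with history of suicide attempt"),
                   "FAMILY")
  expect_identical(scope_of("history of suicide attempt"), "PERSONAL")
  far <- "mother was present at the long visit today and we discussed at length the ongoing treatment plan including prior suicide attempt"
  expect_identical(scope_of(far, proximity = 5L), "PERSONAL")
})

test_that("extract_instances composes the rules deterministically", {
  text <- "Pt denies SI. Mother has a history of suicide attempt."
  inst <- extract_instances(text)
  # default config: bare negated "SI" is not a history instance
  expect_identical(nrow(inst), 1L)
  expect_identical(inst$category, "SA")
  expect_identical(inst$polarity, "AFFIRMED")
  expect_identical(inst$scope, "FAMILY")

  # config flag admits the negated unmodified mention as well
  cfg <- extractor_config(treat_negated_unmodified_as_history = TRUE)
  inst2 <- extract_instances(text, config = cfg)
  expect_identical(nrow(inst2), 2L)
  expect_identical(inst2$category, c("SI", "SA"))
  expect_identical(inst2$polarity, c("NEGATED", "AFFIRMED"))
  expect_identical(inst2$scope, c("PERSONAL", "FAMILY"))

  expect_identical(nrow(extract_instances("")), 0L)
  expect_identical(nrow(extract_instances("suicide precautions reviewed")), 0L)

  # determinism: byte-identical serialization on repeated runs
  s1 <- paste(capture.output(dput(extract_instances(text))), collapse = "\n")
  s2 <- paste(capture.output(dput(extract_instances(text))), collapse = "\n")
  expect_identical(s1, s2)

  # offset integrity on every extracted mention
  for (i in seq_len(nrow(inst2))) {
    expect_identical(substring(text, inst2$concept_start[i] + 1,
                               inst2$concept_end[i]), inst2$concept_text[i])
  }
})

test_that("intrinsically past family events are caught without an explicit modifier", {
  inst <- extract_instances("Her father died by suicide.")
  expect_identical(nrow(inst), 1L)
  expect_identical(inst$scope, "FAMILY")
  expect_identical(inst$polarity, "AFFIRMED")
  expect_true(is.na(inst$modifier_text))
  # the relaxation is family-only: no kinship term, no instance
  expect_identical(nrow(extract_instances("He died by suicide.")), 0L)
  # and switchable
  cfg <- extractor_config(family_verb_concepts = FALSE)
  expect_identical(nrow(extract_instances("Her father died by suicide.",
                                          config = cfg)), 0L)
})
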