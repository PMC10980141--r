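#' Extractor configuration
#'
#' Tunable parameters of the rule-based extractor.  All distances are in
#' tokens.
#'
#' @param max_pair_distance Maximum token gap between a target concept and a
#'   historical modifier for them to pair (same sentence only).  Default 10.
#' @param negation_scope Maximum token gap between a negation cue and the
#'   concept it negates.  Default 6, in line with common ConText practice.
#' @param family_proximity Maximum token gap between a kinship term and the
#'   concept-modifier span for family attribution.  Default 5.
#' @param use_temporal_modifiers Treat date/year phrasings ("suicide attempt
#'   2014") as historical modifiers.  Default TRUE; switch off to study the
#'   timestamp-style documentation failure mode.
#' @param treat_negated_unmodified_as_history Count a negated bare concept
#'   with no historical modifier ("denies SI") as a (negated) personal
#'   history instance.  Default FALSE: a bare current-tense mention is not
#'   history.
#' @param family_verb_concepts Allow a kinship term next to an intrinsically
#'   past concept ("her father died by suicide") to form a family instance
#'   without an explicit modifier.  Default TRUE: completed-suicide
#'   phrasings carry their own pastness.
#' @return An object of class `stb_config`.
#' @export
extractor_config <- function(max_pair_distance = 10L,
                             negation_scope = 6L,
                             family_proximity = 5L,
                             use_temporal_modifiers = TRUE,
                             treat_negated_unmodified_as_history = FALSE,
                             family_verb_concepts = TRUE) {
  stopifnot(max_pair_distance >= 0, negation_scope >= 0, family_proximity >= 0)
  structure(list(
    max_pair_distance = as.integer(max_pair_distance),
    negation_scope = as.integer(negation_scope),
    family_proximity = as.integer(family_proximity),
    use_temporal_modifiers = isTRUE(use_temporal_modifiers),
    treat_negated_unmodified_as_history = isTRUE(treat_negated_unmodified_as_history),
    family_verb_concepts = isTRUE(family_verb_concepts)
  ), class = "stb_config")
}

empty_mentions <- function(extra = character()) {
  base <- data.frame(start = integer(), end = integer(),
                     matched_text = character(), pattern_id = integer(),
                     sentence_index = integer(), first_token = integer(),
                     last_token = integer(), stringsAsFactors = FALSE)
  for (col in extra) base[[col]] <- character()
  base
}

annotate_positions <- function(matches, tokens, sentences) {
  n <- nrow(matches)
  matches$sentence_index <- rep(NA_integer_, n)
  matches$first_token <- rep(NA_integer_, n)
  matches$last_token <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rng <- span_token_range(tokens, matches$start[i], matches$end[i])
    matches$first_token[i] <- rng[1]
    matches$last_token[i] <- rng[2]
    matches$sentence_index[i] <- sentence_at(sentences, matches$start[i])
  }
  matches
}

#' Find target STB concept mentions
#'
#' Matches every target-concept pattern in the lexicon against the note,
#' suppresses matches overlapping an exclusion phrase (so "suicide
#' precautions" never yields a concept), and resolves remaining overlaps
#' longest-match-wins (ties to the leftmost start).
#'
#' @param text Note text.
#' @param tokens,sentences Output of [tokenize_clinical()] and
#'   [segment_sentences()] for `text`.
#' @param lexicon A validated `stb_lexicon`.
#' @return data.frame of mentions: `category` (SI/SB/SA), `start`, `end`,
#'   `matched_text`, `sentence_index`, `first_token`, `last_token`,
#'   `intrinsic_past`.
#' @export
find_concept_mentions <- function(text, tokens, sentences,
                                  lexicon = default_lexicon()) {
  all <- list()
  for (cat in c("SI", "SB", "SA")) {
    m <- match_patterns(text, lexicon$target_concepts[[cat]])
    if (nrow(m)) {
      m$category <- cat
      m$intrinsic_past <-
        lexicon$target_concepts[[cat]][m$pattern_id] %in%
          (lexicon$intrinsic_past_concepts %||% character())
      all[[cat]] <- m
    }
  }
  if (!length(all)) {
    out <- empty_mentions()
    out$category <- character(); out$intrinsic_past <- logical()
    return(out)
  }
  m <- do.call(rbind, all)
  rownames(m) <- NULL
  excl <- match_patterns(text, lexicon$exclusions)
  m <- m[!overlaps_any(m$start, m$end, excl$start, excl$end), , drop = FALSE]
  # give category a deterministic role in tie-breaking via pattern_id order
  m <- m[order(m$start, m$end, m$category), , drop = FALSE]
  m$pattern_id <- seq_len(nrow(m))
  m <- resolve_overlaps(m)
  annotate_positions(m, tokens, sentences)
}

#' Find historical modifier mentions
#'
#' Matches explicit history modifiers ("history of", "h/o", "prior", ...)
#' and, when enabled, temporal phrasings ("in 2014", "03/12/2019", "three
#' years ago") that imply pastness.  Overlaps are resolved
#' longest-match-wins.
#'
#' @inheritParams find_concept_mentions
#' @param use_temporal Include temporal modifier patterns.
#' @return data.frame with `kind` in `{explicit_history, temporal}` plus the
#'   positional columns of [find_concept_mentions()].
#' @export
find_history_modifiers <- function(text, tokens, sentences,
                                   lexicon = default_lexicon(),
                                   use_temporal = TRUE) {
  explicit <- match_patterns(text, lexicon$history_modifiers)
  if (nrow(explicit)) explicit$kind <- "explicit_history"
  temporal <- if (use_temporal) {
    match_patterns(text, lexicon$temporal_modifiers)
  } else {
    match_patterns(text, character())
  }
  if (nrow(temporal)) temporal$kind <- "temporal"
  m <- rbind(
    if (nrow(explicit)) explicit else NULL,
    if (nrow(temporal)) temporal else NULL
  )
  if (is.null(m) || !nrow(m)) {
    out <- empty_mentions()
    out$kind <- character()
    return(out)
  }
  m <- m[order(m$start, m$end, m$kind), , drop = FALSE]
  m$pattern_id <- seq_len(nrow(m))
  m <- resolve_overlaps(m)
  annotate_positions(m, tokens, sentences)
}

# Token gap between two token ranges (0 when adjacent or overlapping).
token_gap <- function(first1, last1, first2, last2) {
  if (first2 > last1) return(first2 - last1 - 1L)
  if (first1 > last2) return(first1 - last2 - 1L)
  0L
}

#' Pair concepts with their nearest historical modifier
#'
#' Each concept is paired with the nearest modifier in the same sentence
#' within `max_pair_distance` tokens (ties to the earlier modifier).  A
#' concept with no eligible modifier yields no pair; a modifier may serve
#' several concepts ("history of SI and SA").
#'
#' @param concepts,modifiers Frames from [find_concept_mentions()] and
#'   [find_history_modifiers()].
#' @param max_pair_distance Maximum token gap.
#' @return data.frame with `concept` and `modifier` row indices plus the
#'   token `distance`.
#' @export
pair_concept_modifier <- function(concepts, modifiers, max_pair_distance = 10L) {
  out <- data.frame(concept = integer(), modifier = integer(),
                    distance = integer())
  if (!nrow(concepts) || !nrow(modifiers)) return(out)
  for (i in seq_len(nrow(concepts))) {
    if (is.na(concepts$first_token[i])) next
    best <- NA_integer_; best_d <- NA_integer_
    for (j in seq_len(nrow(modifiers))) {
      if (is.na(modifiers$first_token[j])) next
      if (!identical(modifiers$sentence_index[j], concepts$sentence_index[i])) next
      d <- token_gap(concepts$first_token[i], concepts$last_token[i],
                     modifiers$first_token[j], modifiers$last_token[j])
      if (d > max_pair_distance) next
      if (is.na(best_d) || d < best_d ||
          (d == best_d && modifiers$start[j] < modifiers$start[best])) {
        best <- j; best_d <- d
      }
    }
    if (!is.na(best)) {
      out <- rbind(out, data.frame(concept = i, modifier = best,
                                   distance = best_d))
    }
  }
  out
}

# Cue mentions eligible to negate a concept: same sentence, within scope,
# not pseudo-negated, no termination cue strictly between cue and concept.
find_negation <- function(text, tokens, sentences, concept_first,
                          concept_last, concept_sentence, lexicon,
                          negation_scope) {
  pseudo <- match_patterns(text, lexicon$pseudo_negation_cues)
  term <- annotate_positions(match_patterns(text, lexicon$termination_cues),
                             tokens, sentences)
  eligible <- function(cues, side) {
    cues <- annotate_positions(cues, tokens, sentences)
    for (k in seq_len(nrow(cues))) {
      if (is.na(cues$first_token[k])) next
      if (!identical(cues$sentence_index[k], concept_sentence)) next
      if (overlaps_any(cues$start[k], cues$end[k], pseudo$start, pseudo$end)) next
      if (side == "pre") {
        if (cues$last_token[k] >= concept_first) next
        gap <- concept_first - cues$last_token[k] - 1L
        between <- term$first_token > cues$last_token[k] &
          term$last_token < concept_first
      } else {
        if (cues$first_token[k] <= concept_last) next
        gap <- cues$first_token[k] - concept_last - 1L
        between <- term$first_token > concept_last &
          term$last_token < cues$first_token[k]
      }
      if (gap > negation_scope) next
      if (nrow(term) && any(between, na.rm = TRUE)) next
      return(TRUE)
    }
    FALSE
  }
  eligible(match_patterns(text, lexicon$negation_cues$pre), "pre") ||
    eligible(match_patterns(text, lexicon$negation_cues$post), "post")
}

#' Assign polarity to a concept (ConText-style negation)
#'
#' A concept is NEGATED iff a negation cue lies in the same sentence within
#' `negation_scope` tokens (pre-scope cues before the concept, post-scope
#' cues after), the cue is not part of a pseudo-negation phrase ("no
#' increase in"), and no termination cue ("but", "however", ";") intervenes
#' between cue and concept.  Otherwise AFFIRMED.
#'
#' @inheritParams find_concept_mentions
#' @param concept One row of the frame from [find_concept_mentions()].
#' @param negation_scope Maximum token gap cue-to-concept.
#' @return `"NEGATED"` or `"AFFIRMED"`.
#' @export
assign_polarity <- function(text, tokens, sentences, concept,
                            lexicon = default_lexicon(), negation_scope = 6L) {
  neg <- find_negation(text, tokens, sentences, concept$first_token,
                       concept$last_token, concept$sentence_index,
                       lexicon, negation_scope)
  if (neg) "NEGATED" else "AFFIRMED"
}

#' Attribute personal vs family scope
#'
#' FAMILY iff a kinship term occurs within `family_proximity` tokens of the
#' concept-modifier span, on either side, in the same sentence; otherwise
#' PERSONAL.
#'
#' @inheritParams assign_polarity
#' @param concept,modifier Rows of the mention frames; `modifier` may be
#'   `NULL` for modifier-less (intrinsically past) concepts.
#' @param family_proximity Maximum token gap.
#' @return `"FAMILY"` or `"PERSONAL"`.
#' @export
attribute_scope <- function(text, tokens, sentences, concept, modifier = NULL,
                            lexicon = default_lexicon(), family_proximity = 5L) {
  fam <- annotate_positions(match_patterns(text, lexicon$family_terms),
                            tokens, sentences)
  if (!nrow(fam)) return("PERSONAL")
  span_first <- concept$first_token
  span_last <- concept$last_token
  if (!is.null(modifier) && !is.na(modifier$first_token)) {
    span_first <- min(span_first, modifier$first_token)
    span_last <- max(span_last, modifier$last_token)
  }
  for (k in seq_len(nrow(fam))) {
    if (is.na(fam$first_token[k])) next
    if (!identical(fam$sentence_index[k], concept$sentence_index)) next
    d <- token_gap(span_first, span_last, fam$first_token[k], fam$last_token[k])
    if (d <= family_proximity) return("FAMILY")
  }
  "PERSONAL"
}

empty_instances <- function() {
  data.frame(
    category = character(), polarity = character(), scope = character(),
    concept_start = integer(), concept_end = integer(),
    concept_text = character(),
    modifier_start = integer(), modifier_end = integer(),
    modifier_text = character(), modifier_kind = character(),
    sentence_index = integer(), stringsAsFactors = FALSE
  )
}

#' Extract suicidal-history instances from one note
#'
#' Full rule-based pipeline for a single note: tokenize, segment, match
#' target concepts (with exclusions), match historical modifiers, pair each
#' concept with its nearest same-sentence modifier, assign polarity by
#' ConText-style negation, and attribute personal vs family scope by
#' kinship-term proximity.  Two optional relaxations (see
#' [extractor_config()]) admit modifier-less instances: intrinsically past
#' family events ("her father died by suicide") and negated bare mentions
#' ("denies SI").
#'
#' @param text Note text (single string).
#' @param lexicon A validated `stb_lexicon`.
#' @param config An [extractor_config()].
#' @return data.frame of instances sorted by concept start offset (ties:
#'   concept end, then category): `category`, `polarity`
#'   (AFFIRMED/NEGATED), `scope` (PERSONAL/FAMILY), `concept_start`,
#'   `concept_end`, `concept_text`, `modifier_start`, `modifier_end`,
#'   `modifier_text`, `modifier_kind` (NA for modifier-less instances), and
#'   `sentence_index`.  Offsets are 0-based half-open.
#' @examples
#' extract_instances("Mother has a history of suicide attempt.")
#' @export
extract_instances <- function(text, lexicon = default_lexicon(),
                              config = extractor_config()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  tokens <- tokenize_clinical(text)
  sentences <- segment_sentences(text, tokens)
  concepts <- find_concept_mentions(text, tokens, sentences, lexicon)
  if (!nrow(concepts)) return(empty_instances())
  modifiers <- find_history_modifiers(text, tokens, sentences, lexicon,
                                      use_temporal = config$use_temporal_modifiers)
  pairs <- pair_concept_modifier(concepts, modifiers, config$max_pair_distance)

  rows <- list()
  paired <- rep(FALSE, nrow(concepts))
  add_instance <- function(ci, mi) {
    concept <- concepts[ci, ]
    modifier <- if (!is.null(mi)) modifiers[mi, ] else NULL
    polarity <- assign_polarity(text, tokens, sentences, concept, lexicon,
                                config$negation_scope)
    scope <- attribute_scope(text, tokens, sentences, concept, modifier,
                             lexicon, config$family_proximity)
    data.frame(
      category = concept$category, polarity = polarity, scope = scope,
      concept_start = concept$start, concept_end = concept$end,
      concept_text = concept$matched_text,
      modifier_start = if (is.null(modifier)) NA_integer_ else modifier$start,
      modifier_end = if (is.null(modifier)) NA_integer_ else modifier$end,
      modifier_text = if (is.null(modifier)) NA_character_ else modifier$matched_text,
      modifier_kind = if (is.null(modifier)) NA_character_ else modifier$kind,
      sentence_index = concept$sentence_index,
      stringsAsFactors = FALSE
    )
  }
  for (p in seq_len(nrow(pairs))) {
    ci <- pairs$concept[p]
    paired[ci] <- TRUE
    rows[[length(rows) + 1L]] <- add_instance(ci, pairs$modifier[p])
  }
  for (ci in which(!paired)) {
    concept <- concepts[ci, ]
    if (config$family_verb_concepts && isTRUE(concept$intrinsic_past)) {
      scope <- attribute_scope(text, tokens, sentences, concept, NULL,
                               lexicon, config$family_proximity)
      if (scope == "FAMILY") {
        rows[[length(rows) + 1L]] <- add_instance(ci, NULL)
        next
      }
    }
    if (config$treat_negated_unmodified_as_history) {
      pol <- assign_polarity(text, tokens, sentences, concept, lexicon,
                             config$negation_scope)
      if (pol == "NEGATED") rows[[length(rows) + 1L]] <- add_instance(ci, NULL)
    }
  }
  if (!length(rows)) return(empty_instances())
  out <- do.call(rbind, rows)
  out <- out[order(out$concept_start, out$concept_end, out$category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
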