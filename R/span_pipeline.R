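# Context-window span pipeline: anchors -> n-word windows -> combined text.
# This is the preprocessing path that feeds the trainable classifier; it
# reuses the rule engine's concept-modifier dictionary as its target rules.

SPAN_SEPARATOR <- "[SEP]"
SPAN_PLACEHOLDER <- "[EMPTY]"

#' Anchor target rules derived from a lexicon
#'
#' Builds the anchor-matching rules from the same concept and modifier
#' dictionary the rule engine uses: each target-concept pattern, optionally
#' prefixed by an explicit historical modifier, so "history of suicide
#' attempt" matches as a single anchor phrase.
#'
#' @param lexicon A validated `stb_lexicon`.
#' @return Character vector of regex patterns.
#' @export
anchor_rules <- function(lexicon = default_lexicon()) {
  mods <- lexicon$history_modifiers
  mods <- mods[order(-nchar(mods))]  # longest alternative first
  prefix <- paste0("(?:(?:", paste(mods, collapse = "|"), ")\\s+)?")
  concepts <- unlist(lexicon$target_concepts, use.names = FALSE)
  paste0(prefix, "(?:", concepts, ")")
}

#' Match anchor phrases in a note
#'
#' @param text Note text.
#' @param tokens Token frame from [tokenize_clinical()].
#' @param lexicon Lexicon from which target rules are derived.
#' @return data.frame of anchors sorted by start (longest match wins on
#'   overlap): `start`, `end`, `matched_text`, `pattern_id`, `first_token`,
#'   `last_token`.
#' @export
match_anchors <- function(text, tokens = tokenize_clinical(text),
                          lexicon = default_lexicon()) {
  m <- match_patterns(text, anchor_rules(lexicon))
  m <- resolve_overlaps(m)
  n <- nrow(m)
  m$first_token <- rep(NA_integer_, n)
  m$last_token <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rng <- span_token_range(tokens, m$start[i], m$end[i])
    m$first_token[i] <- rng[1]
    m$last_token[i] <- rng[2]
  }
  m[!is.na(m$first_token), , drop = FALSE]
}

#' Extract the n-word context window around an anchor
#'
#' Takes `n` word tokens to the left and `n` to the right of the anchor,
#' truncated at the document bounds.  The count is in word tokens:
#' punctuation tokens do not consume window budget but are included in the
#' rendered text when they fall inside the selected interval.  Windows
#' deliberately cross sentence boundaries.
#'
#' @param tokens Token frame for the document.
#' @param anchor_first,anchor_last 1-based token indices of the anchor.
#' @param n Window size in words per side (the supported sweep is 8, 16,
#'   24, 32, but any positive integer works).
#' @return `c(first, last)` 1-based token indices of the window interval
#'   (inclusive of the anchor).
#' @export
extract_context_window <- function(tokens, anchor_first, anchor_last, n) {
  stopifnot(n >= 1, anchor_first >= 1, anchor_last <= nrow(tokens),
            anchor_first <= anchor_last)
  word_idx <- which(tokens$is_word)
  left <- word_idx[word_idx < anchor_first]
  right <- word_idx[word_idx > anchor_last]
  left_take <- if (length(left)) utils::tail(left, n) else integer()
  right_take <- if (length(right)) utils::head(right, n) else integer()
  first <- if (length(left_take)) min(left_take) else anchor_first
  last <- if (length(right_take)) max(right_take) else anchor_last
  c(first, last)
}

# Merge sorted token intervals that overlap or are adjacent.
merge_intervals <- function(intervals) {
  if (!length(intervals)) return(list())
  ord <- order(vapply(intervals, `[`, numeric(1), 1))
  intervals <- intervals[ord]
  merged <- list(intervals[[1]])
  for (iv in intervals[-1]) {
    cur <- merged[[length(merged)]]
    if (iv[1] <= cur[2] + 1L) {
      merged[[length(merged)]] <- c(cur[1], max(cur[2], iv[2]))
    } else {
      merged[[length(merged) + 1L]] <- iv
    }
  }
  merged
}

#' Combine window intervals into one text representation
#'
#' Merges overlapping/adjacent token intervals, renders each merged span
#' verbatim from the source text, and joins the spans in document order
#' with a single reserved separator token.  A document with no windows
#' yields the reserved placeholder token, so anchor-free notes still enter
#' training and evaluation.
#'
#' @param intervals List of `c(first, last)` token intervals.
#' @param tokens Token frame for the document.
#' @param text Source text.
#' @param separator,placeholder Reserved tokens.
#' @return A single string.
#' @export
combine_windows <- function(intervals, tokens, text,
                            separator = SPAN_SEPARATOR,
                            placeholder = SPAN_PLACEHOLDER) {
  merged <- merge_intervals(intervals)
  if (!length(merged)) return(placeholder)
  spans <- vapply(merged, function(iv) {
    slice_text(text, tokens$start[iv[1]], tokens$end[iv[2]])
  }, character(1))
  paste(spans, collapse = paste0(" ", separator, " "))
}

#' Build the span dataset for classifier training
#'
#' One record per document: anchors are matched, an n-word context window is
#' extracted around each, windows are merged and combined, and the
#' document's gold label for the requested scope is attached unchanged.
#' Anchor-free documents are kept with the placeholder text (set
#' `drop_anchor_free = TRUE` to drop them instead).
#'
#' @param notes data.frame with `note_id` and `text`.
#' @param labels data.frame with `note_id` and `label`
#'   (POSITIVE/NEGATIVE), or a vector named by note_id.
#' @param n Window size in words per side.
#' @param scope Scope tag carried into the records ("psh" or "fsh").
#' @param lexicon Lexicon for anchor rules.
#' @param drop_anchor_free Drop documents with no anchor instead of keeping
#'   a placeholder record.
#' @return data.frame: `doc_id`, `scope`, `n`, `text`, `label`,
#'   `n_anchors`.
#' @export
build_span_dataset <- function(notes, labels, n = 16L, scope = "psh",
                               lexicon = default_lexicon(),
                               drop_anchor_free = FALSE) {
  stopifnot(all(c("note_id", "text") %in% names(notes)))
  if (is.data.frame(labels)) {
    lab <- labels$label
    names(lab) <- labels$note_id
  } else {
    lab <- labels
  }
  missing <- setdiff(notes$note_id, names(lab))
  if (length(missing)) {
    stopf("missing gold label for document(s): %s",
          paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(notes)), function(i) {
    text <- notes$text[i]
    tokens <- tokenize_clinical(text)
    anchors <- if (nrow(tokens)) match_anchors(text, tokens, lexicon) else
      data.frame(first_token = integer(), last_token = integer())
    intervals <- lapply(seq_len(nrow(anchors)), function(a) {
      extract_context_window(tokens, anchors$first_token[a],
                             anchors$last_token[a], n)
    })
    if (!nrow(anchors) && drop_anchor_free) return(NULL)
    data.frame(
      doc_id = notes$note_id[i],
      scope = scope,
      n = as.integer(n),
      text = combine_windows(intervals, tokens, text),
      label = unname(lab[notes$note_id[i]]),
      n_anchors = nrow(anchors),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), scope = character(),
                      n = integer(), text = character(), label = character(),
                      n_anchors = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
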