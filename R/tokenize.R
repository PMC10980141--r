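#' Clinical tokenizer
#'
#' Splits raw note text into offset-faithful tokens.  Tokens are maximal
#' alphanumeric runs (apostrophes allowed word-internally, so "patient's" is
#' one token); every other non-whitespace character is emitted as its own
#' punctuation token.  A small whitelist of slash-joined clinical
#' abbreviations ("h/o", "s/p", "c/o", "w/o", "f/u", "b/l") is kept intact as
#' single tokens because they carry clinical meaning (e.g. "h/o" = history
#' of) that would be destroyed by splitting on "/".
#'
#' Character offsets are 0-based half-open throughout the package, matching
#' BRAT standoff conventions, so `substr(text, start + 1, end)` recovers the
#' token surface.
#'
#' @param text A single character string (may be empty).
#' @return A data.frame with columns `text`, `start`, `end` (0-based
#'   half-open character offsets), `index` (1-based ordinal), and `is_word`
#'   (TRUE for alphanumeric/abbreviation tokens, FALSE for punctuation).
#' @examples
#' tokenize_clinical("h/o SI.")
#' @export
tokenize_clinical <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      index = integer(), is_word = logical(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  abbrevs <- c("h/o", "s/p", "c/o", "w/o", "f/u", "b/l")
  pattern <- sprintf(
    "(?i)(?<![A-Za-z0-9])(?:%s)(?![A-Za-z0-9])|[A-Za-z0-9]+(?:'[A-Za-z]+)*|[^\\sA-Za-z0-9]",
    paste(abbrevs, collapse = "|"))
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  surface <- slice_text(text, starts, starts + lens)
  data.frame(
    text = surface,
    start = starts,
    end = starts + lens,
    index = seq_along(starts),
    is_word = grepl("^[A-Za-z0-9]", surface),
    stringsAsFactors = FALSE
  )
}

#' Sentence segmentation
#'
#' Splits a note into sentences at (a) sentence-final punctuation (`.`, `!`,
#' `?`) followed by whitespace and an upper-case letter, and (b) newline
#' boundaries.  Sentences partition the text, so every token belongs to
#' exactly one sentence.  This is deliberately conservative plumbing: its
#' only job is to bound negation scopes and concept-modifier pairing.
#'
#' @param text The note text.
#' @param tokens Token frame from [tokenize_clinical()] for the same text.
#' @return A data.frame with columns `start`, `end` (character offsets),
#'   `first_token`, `last_token` (1-based token indices, NA when a sentence
#'   holds no token).
#' @export
segment_sentences <- function(text, tokens = tokenize_clinical(text)) {
  empty <- data.frame(start = integer(), end = integer(),
                      first_token = integer(), last_token = integer())
  if (!nzchar(text)) return(empty)
  # Boundary = character position *after* which a new sentence starts.
  m <- gregexpr("[.!?](?=\\s+[A-Z])|\\n", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1L) cuts <- as.integer(m) - 1L + attr(m, "match.length")
  bounds <- sort(unique(c(0L, cuts, nchar(text))))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  # Drop "sentences" that contain no token (e.g. runs of blank lines): they
  # carry nothing and would break the token-partition invariant.
  ft <- lt <- rep(NA_integer_, length(starts))
  for (i in seq_along(starts)) {
    hit <- which(tokens$start >= starts[i] & tokens$start < ends[i])
    if (length(hit)) { ft[i] <- min(hit); lt[i] <- max(hit) }
  }
  keep <- !is.na(ft)
  data.frame(start = starts[keep], end = ends[keep],
             first_token = ft[keep], last_token = lt[keep])
}
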