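# Internal helpers shared across modules.

# All character offsets in this package are 0-based half-open [start, end),
# matching BRAT standoff conventions.  slice_text() is the one place that
# converts to R's 1-based substr().
slice_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a lexicon pattern so it only matches at word-ish boundaries.  Patterns
# made purely of punctuation (e.g. the ";" termination cue) are left as-is:
# a boundary assertion next to punctuation would never hold.
boundary_wrap <- function(pattern) {
  punct_only <- !grepl("[A-Za-z0-9\\\\]", pattern)
  ifelse(punct_only,
         pattern,
         paste0("(?<![A-Za-z0-9])(?:", pattern, ")(?![A-Za-z0-9])"))
}

# Match every pattern in `patterns` against `text`; returns a data.frame with
# 0-based half-open offsets, the matched surface, and the index of the source
# pattern.  Case-insensitive unless a pattern opts out inline with (?-i:...).
match_patterns <- function(text, patterns) {
  out <- list()
  for (i in seq_along(patterns)) {
    pat <- boundary_wrap(patterns[[i]])
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    out[[length(out) + 1L]] <- data.frame(
      start = starts,
      end = starts + lens,
      matched_text = slice_text(text, starts, starts + lens),
      pattern_id = i,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      matched_text = character(), pattern_id = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$pattern_id), , drop = FALSE]
}

# Longest-match-wins overlap resolution; ties broken by leftmost start, then
# lowest pattern id.  Input/output: data.frame with start/end columns.
resolve_overlaps <- function(matches) {
  if (nrow(matches) < 2L) return(matches)
  len <- matches$end - matches$start
  ord <- order(-len, matches$start, matches$pattern_id %||% seq_len(nrow(matches)))
  keep <- logical(nrow(matches))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    s <- matches$start[i]; e <- matches$end[i]
    if (nrow(taken) == 0L || all(e <= taken[, 1] | s >= taken[, 2])) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(s, e))
    }
  }
  out <- matches[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# TRUE where [s1,e1) overlaps any interval in (s2,e2) vectors.
overlaps_any <- function(start, end, starts2, ends2) {
  if (!length(starts2)) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] < ends2 & end[i] > starts2)
  }, logical(1))
}

# Map a character span onto token indices (1-based rows of a token frame).
# Returns c(NA, NA) when no token intersects the span.
span_token_range <- function(tokens, start, end) {
  hit <- which(tokens$end > start & tokens$start < end)
  if (!length(hit)) return(c(NA_integer_, NA_integer_))
  c(min(hit), max(hit))
}

# Sentence index (1-based) containing a character position, or NA.
sentence_at <- function(sentences, pos) {
  hit <- which(sentences$start <= pos & sentences$end > pos)
  if (!length(hit)) NA_integer_ else hit[1]
}

# Strict ISO-8601 calendar date (YYYY-MM-DD) that actually parses.
parse_iso_date <- function(d) {
  if (is.na(d) || !grepl("^\\d{4}-\\d{2}-\\d{2}$", d)) return(as.Date(NA))
  tryCatch(as.Date(d), error = function(e) as.Date(NA))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
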