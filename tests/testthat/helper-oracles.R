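# Independent oracles used across the suite.  Each is written as a direct,
# naive transcription of the rule it checks, deliberately avoiding the code
# paths of the implementation.

# Document rule: majority of instance polarities; exact tie decided by the
# polarity of the instance with the greatest anchor offset.  Brute force
# over a +1/-1 tally.
oracle_doc_label <- function(polarities) {
  if (!length(polarities)) return("NEGATIVE")
  tally <- sum(ifelse(polarities == "AFFIRMED", 1L, -1L))
  if (tally > 0L) return("POSITIVE")
  if (tally < 0L) return("NEGATIVE")
  if (polarities[length(polarities)] == "AFFIRMED") "POSITIVE" else "NEGATIVE"
}

# Every polarity sequence of length 1..max_len (62 sequences for max_len 5).
all_polarity_sequences <- function(max_len = 5L) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- expand.grid(rep(list(c("AFFIRMED", "NEGATED")), len),
                        stringsAsFactors = FALSE)
    out <- c(out, lapply(seq_len(nrow(grid)), function(i)
      unname(unlist(grid[i, ]))))
  }
  out
}

# Context window by naive slicing: enumerate word-token positions, take the
# last n before / first n after the anchor, span the raw token range.
oracle_window <- function(tokens, anchor_first, anchor_last, n) {
  words <- which(tokens$is_word)
  left <- words[words < anchor_first]
  right <- words[words > anchor_last]
  if (length(left) > n) left <- left[(length(left) - n + 1):length(left)]
  if (length(right) > n) right <- right[1:n]
  c(min(c(left, anchor_first)), max(c(right, anchor_last)))
}

# Precision/recall/F1 straight from the defining formulas on raw label
# vectors, one class at a time.
oracle_prf <- function(gold, pred, classes = sort(unique(c(gold, pred)))) {
  per <- t(vapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f, support = sum(gold == cl))
  }, numeric(4)))
  w <- per[, "support"] / sum(per[, "support"])
  list(per_class = per,
       accuracy = mean(gold == pred),
       macro = colMeans(per[, 1:3, drop = FALSE]),
       weighted = colSums(per[, 1:3, drop = FALSE] * w))
}

# Cohen's kappa straight from the agreement-matrix formula.
oracle_kappa <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# Small fixed corpora for reuse (kept small so the suite stays fast).
make_clean_corpus <- function(n_patients = 60, seed = 42, ...) {
  generate_corpus(synthetic_config(
    n_patients = n_patients, psh_prevalence = 0.3, fsh_prevalence = 0.1,
    timestamp_style_rate = 0, seed = seed, ...))
}
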