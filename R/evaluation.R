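#' Per-class confusion counts
#'
#' @param gold,pred Equal-length label vectors over the same label set.
#' @param labels Label set; defaults to the sorted union of values seen.
#' @return data.frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `tn`, `support`.
#' @export
compute_confusion <- function(gold, pred, labels = NULL) {
  if (length(gold) != length(pred)) {
    stopf("gold and predicted label vectors differ in length (%d vs %d)",
          length(gold), length(pred))
  }
  gold <- as.character(gold); pred <- as.character(pred)
  if (is.null(labels)) labels <- sort(unique(c(gold, pred)))
  bad <- setdiff(unique(c(gold, pred)), labels)
  if (length(bad)) {
    stopf("labels outside the declared label set: %s",
          paste(bad, collapse = ", "))
  }
  rows <- lapply(labels, function(cl) {
    data.frame(
      class = cl,
      tp = sum(gold == cl & pred == cl),
      fp = sum(gold != cl & pred == cl),
      fn = sum(gold == cl & pred != cl),
      tn = sum(gold != cl & pred != cl),
      support = sum(gold == cl),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Precision, recall and F1 from confusion counts
#'
#' Zero denominators yield 0 (flagged via the `zero_division` attribute) so
#' macro averages stay defined when a class is never predicted.
#'
#' @param counts Frame from [compute_confusion()].
#' @return data.frame with per-class `precision`, `recall`, `f1`,
#'   `support`.
#' @export
compute_prf <- function(counts) {
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  out <- data.frame(class = counts$class, precision = precision,
                    recall = recall, f1 = f1, support = counts$support,
                    stringsAsFactors = FALSE)
  attr(out, "zero_division") <-
    any(counts$tp + counts$fp == 0) || any(counts$tp + counts$fn == 0)
  out
}

#' Full evaluation report
#'
#' Accuracy plus per-class, macro-averaged (unweighted mean over classes,
#' including the negative class) and weighted-averaged (support-weighted
#' mean) precision/recall/F1.
#'
#' @inheritParams compute_confusion
#' @return Object of class `stb_eval`: list with `accuracy`, `per_class`
#'   (data.frame), `macro` and `weighted` (named numeric vectors
#'   precision/recall/f1), `n`, `labels`.
#' @export
eval_report <- function(gold, pred, labels = NULL) {
  counts <- compute_confusion(gold, pred, labels)
  prf <- compute_prf(counts)
  w <- prf$support / sum(prf$support)
  res <- list(
    accuracy = mean(as.character(gold) == as.character(pred)),
    per_class = prf,
    macro = c(precision = mean(prf$precision), recall = mean(prf$recall),
              f1 = mean(prf$f1)),
    weighted = c(precision = sum(w * prf$precision),
                 recall = sum(w * prf$recall),
                 f1 = sum(w * prf$f1)),
    n = length(gold),
    labels = counts$class,
    zero_division = attr(prf, "zero_division")
  )
  class(res) <- "stb_eval"
  res
}

#' @export
print.stb_eval <- function(x, digits = 3, ...) {
  cat(sprintf("<stb_eval> n=%d  accuracy=%.*f\n", x$n, digits, x$accuracy))
  print(cbind(x$per_class[1],
              round(x$per_class[c("precision", "recall", "f1")], digits),
              x$per_class["support"]), row.names = FALSE)
  cat(sprintf("  macro    P=%.*f R=%.*f F1=%.*f\n", digits, x$macro["precision"],
              digits, x$macro["recall"], digits, x$macro["f1"]))
  cat(sprintf("  weighted P=%.*f R=%.*f F1=%.*f\n", digits,
              x$weighted["precision"], digits, x$weighted["recall"],
              digits, x$weighted["f1"]))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two annotators:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal products.  When both marginals are degenerate (`p_e = 1`),
#' returns 1 for perfect observed agreement and `NaN` otherwise.
#'
#' @param a,b Equal-length label vectors, or `a` may be a square agreement
#'   matrix (rows = annotator A, columns = annotator B) with `b` omitted.
#' @return Kappa in `[-1, 1]` (or `NaN` in the degenerate undefined case).
#' @examples
#' cohens_kappa(matrix(c(40, 5, 5, 50), 2, byrow = TRUE))
#' @export
cohens_kappa <- function(a, b = NULL) {
  if (is.matrix(a)) {
    stopifnot(is.null(b), nrow(a) == ncol(a))
    tab <- a
  } else {
    if (length(a) != length(b)) stopf("annotation vectors differ in length")
    lev <- sort(unique(c(as.character(a), as.character(b))))
    tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  }
  n <- sum(tab)
  if (n == 0) stopf("no annotations")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-12) {
    return(if (p_o >= 1 - 1e-12) 1.0 else NaN)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Default ICD-9/10 code set for suicidal thoughts and behaviors
#'
#' A reconstruction of a typical STB phenotyping code set, shipped both
#' here and as an editable CSV (`system.file("extdata",
#' "icd_stb_codes.csv", package = "stbhistory")`): ICD-10 R45.851
#' (suicidal ideation), T14.91 (suicide attempt), X71-X83 (intentional
#' self-harm), Z91.5 (personal history of self-harm); ICD-9 V62.84
#' (suicidal ideation), E950-E959 (suicide and self-inflicted injury).
#' Codes are matched by prefix after removing dots, so "X71" covers
#' "X71.0" etc.
#'
#' @return Character vector of code prefixes.
#' @export
default_icd_codes <- function() {
  c("R45.851", "T14.91", "Z91.5", paste0("X", 71:83),
    "V62.84", paste0("E", 950:959))
}

normalize_icd <- function(code) gsub("\\.", "", toupper(trimws(code)))

icd_qualifies <- function(code, code_set) {
  code <- normalize_icd(code)
  prefixes <- normalize_icd(code_set)
  any(vapply(prefixes, function(p) startsWith(code, p), logical(1)))
}

#' ICD-code baseline comparison
#'
#' Benchmarks note-based detection against the traditional structured-data
#' approach: among gold-positive patients, how many carry a qualifying ICD
#' diagnosis code dated on or before their index date (earliest analyzed
#' note date, date-inclusive), versus how many the note-based classifier
#' detects.
#'
#' @param gold_patients data.frame `patient_id`, `label`
#'   (POSITIVE/NEGATIVE).
#' @param icd_records data.frame `patient_id`, `code`, `date` (ISO-8601).
#'   Records with unparseable dates are skipped with a warning.
#' @param classifier_patients data.frame `patient_id`, `label` from the
#'   note-based tool.
#' @param index_dates data.frame `patient_id`, `index_date` (ISO-8601).
#' @param code_set Qualifying code prefixes; default [default_icd_codes()].
#' @return Object of class `stb_icd_comparison`: `n_gold_positive`,
#'   `n_coded`, `coded_fraction`, `n_detected`, `detected_fraction`.
#' @export
icd_baseline_compare <- function(gold_patients, icd_records,
                                 classifier_patients, index_dates,
                                 code_set = default_icd_codes()) {
  stopifnot(all(c("patient_id", "label") %in% names(gold_patients)),
            all(c("patient_id", "code", "date") %in% names(icd_records)),
            all(c("patient_id", "label") %in% names(classifier_patients)),
            all(c("patient_id", "index_date") %in% names(index_dates)))
  pos <- gold_patients$patient_id[gold_patients$label == "POSITIVE"]
  idx <- as.Date(index_dates$index_date)
  names(idx) <- index_dates$patient_id

  dates <- do.call(c, lapply(icd_records$date, parse_iso_date))
  if (!length(dates)) dates <- as.Date(character())
  bad <- which(is.na(dates) | is.na(icd_records$date))
  if (length(bad)) {
    warnf("skipping %d ICD record(s) with unparseable dates (rows: %s)",
          length(bad), paste(utils::head(bad, 10), collapse = ", "))
  }
  recs <- icd_records[setdiff(seq_len(nrow(icd_records)), bad), , drop = FALSE]
  rec_dates <- dates[setdiff(seq_len(nrow(icd_records)), bad)]

  qualifies <- vapply(recs$code, icd_qualifies, logical(1),
                      code_set = code_set)
  coded <- vapply(pos, function(pid) {
    if (is.na(idx[pid])) return(FALSE)
    any(recs$patient_id == pid & qualifies & rec_dates <= idx[pid])
  }, logical(1))
  detected <- pos %in% classifier_patients$patient_id[
    classifier_patients$label == "POSITIVE"]

  res <- list(
    n_gold_positive = length(pos),
    n_coded = sum(coded),
    coded_fraction = if (length(pos)) sum(coded) / length(pos) else 0,
    n_detected = sum(detected),
    detected_fraction = if (length(pos)) sum(detected) / length(pos) else 0
  )
  class(res) <- "stb_icd_comparison"
  res
}

#' @export
print.stb_icd_comparison <- function(x, ...) {
  cat("<stb_icd_comparison>\n")
  cat(sprintf("  gold-positive patients: %d\n", x$n_gold_positive))
  cat(sprintf("  with prior/concurrent ICD code: %d (%.1f%%)\n",
              x$n_coded, 100 * x$coded_fraction))
  cat(sprintf("  detected from notes:            %d (%.1f%%)\n",
              x$n_detected, 100 * x$detected_fraction))
  invisible(x)
}
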