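#' End-to-end evaluation of the rule engine on a gold-annotated corpus
#'
#' Runs [extract_instances()] + [classify_note()] over every note and
#' scores the predicted document labels against the corpus gold labels for
#' both scopes.  When the corpus carries planted instance-level gold (a
#' synthetic `stb_corpus`), also reports instance-level recall broken down
#' by template family -- the per-failure-mode view used for error analysis
#' (e.g. how much of the loss comes from timestamp-style documentation) --
#' and instance-level precision (fraction of extracted instances matching a
#' planted one).
#'
#' A planted instance counts as recovered when an extracted instance in the
#' same note has the same scope and polarity and overlapping concept
#' offsets.
#'
#' @param corpus An `stb_corpus`, or a list with `notes` (note_id, text,
#'   psh_label, fsh_label) and optionally `instances`.
#' @param lexicon,config Passed to [extract_instances()].
#' @return Object of class `stb_extraction_report`: `doc_class` (note-level
#'   predictions), `psh`, `fsh` (document-level `stb_eval` reports),
#'   `family_recall` (data.frame template_family/n/recovered/recall or
#'   NULL), `instance_precision`.
#' @export
extraction_report <- function(corpus, lexicon = default_lexicon(),
                              config = extractor_config()) {
  notes <- corpus$notes
  stopifnot(all(c("note_id", "text", "psh_label", "fsh_label") %in%
                  names(notes)))
  extracted <- lapply(seq_len(nrow(notes)), function(i) {
    inst <- extract_instances(notes$text[i], lexicon, config)
    if (nrow(inst)) inst$note_id <- notes$note_id[i]
    inst
  })
  doc_class <- do.call(rbind, lapply(seq_len(nrow(notes)), function(i) {
    classify_note(notes$note_id[i], extracted[[i]])
  }))
  if ("patient_id" %in% names(notes)) {
    doc_class$patient_id <- notes$patient_id[match(doc_class$note_id,
                                                   notes$note_id)]
  }
  labs <- c("NEGATIVE", "POSITIVE")
  res <- list(
    doc_class = doc_class,
    psh = eval_report(notes$psh_label, doc_class$psh_label, labels = labs),
    fsh = eval_report(notes$fsh_label, doc_class$fsh_label, labels = labs),
    family_recall = NULL,
    instance_precision = NA_real_
  )

  gold <- corpus$instances
  if (!is.null(gold) && nrow(gold)) {
    all_ext <- do.call(rbind, Filter(nrow, extracted))
    matched_gold <- vapply(seq_len(nrow(gold)), function(g) {
      if (is.null(all_ext) || !nrow(all_ext)) return(FALSE)
      sub <- all_ext[all_ext$note_id == gold$note_id[g] &
                       all_ext$scope == gold$scope[g] &
                       all_ext$polarity == gold$polarity[g], , drop = FALSE]
      any(sub$concept_start < gold$end[g] & sub$concept_end > gold$start[g])
    }, logical(1))
    fams <- sort(unique(gold$template_family))
    res$family_recall <- do.call(rbind, lapply(fams, function(f) {
      sel <- gold$template_family == f
      data.frame(template_family = f, n = sum(sel),
                 recovered = sum(matched_gold[sel]),
                 recall = mean(matched_gold[sel]),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(all_ext) && nrow(all_ext)) {
      matched_ext <- vapply(seq_len(nrow(all_ext)), function(e) {
        sub <- gold[gold$note_id == all_ext$note_id[e] &
                      gold$scope == all_ext$scope[e] &
                      gold$polarity == all_ext$polarity[e], , drop = FALSE]
        any(sub$start < all_ext$concept_end[e] &
              sub$end > all_ext$concept_start[e])
      }, logical(1))
      res$instance_precision <- mean(matched_ext)
    }
  }
  class(res) <- "stb_extraction_report"
  res
}

#' @export
print.stb_extraction_report <- function(x, digits = 3, ...) {
  cat("<stb_extraction_report>\n")
  cat(sprintf("  PSH: accuracy %.*f, macro F1 %.*f\n", digits,
              x$psh$accuracy, digits, x$psh$macro["f1"]))
  cat(sprintf("  FSH: accuracy %.*f, macro F1 %.*f\n", digits,
              x$fsh$accuracy, digits, x$fsh$macro["f1"]))
  if (!is.null(x$family_recall)) {
    cat(sprintf("  instance precision: %.*f\n", digits,
                x$instance_precision))
    cat("  per-template-family recall:\n")
    print(x$family_recall, row.names = FALSE)
  }
  invisible(x)
}

#' Positive-class F1 helper
#'
#' Convenience accessor for the F1 of the POSITIVE class in an `stb_eval`
#' report (the scale used when a single per-outcome F1 is quoted).
#'
#' @param report An `stb_eval` object.
#' @param class Class of interest (default `"POSITIVE"`).
#' @return Scalar F1.
#' @export
positive_f1 <- function(report, class = "POSITIVE") {
  stopifnot(inherits(report, "stb_eval"))
  i <- match(class, report$per_class$class)
  if (is.na(i)) stopf("class %s not present in report", class)
  report$per_class$f1[i]
}
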