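#' Aggregate instance polarities into a note-level label
#'
#' Implements the annotation guideline's aggregation rule for one scope
#' (personal or family): no instances means NEGATIVE; a single instance
#' decides the note by its own polarity; with several instances the
#' majority polarity wins; an exact tie is resolved by the polarity of the
#' last-mentioned instance (greatest concept start offset).
#'
#' @param instances data.frame with at least `polarity` and `concept_start`
#'   columns, as produced by [extract_instances()]; all rows must share one
#'   `scope` if that column is present.
#' @return `"POSITIVE"` or `"NEGATIVE"`.
#' @examples
#' classify_instances(data.frame(polarity = c("AFFIRMED", "NEGATED"),
#'                               concept_start = c(10L, 50L)))  # tie -> last
#' @export
classify_instances <- function(instances) {
  if (is.null(instances) || !nrow(instances)) return("NEGATIVE")
  if ("scope" %in% names(instances) &&
      length(unique(instances$scope)) > 1L) {
    stopf("classify_instances() requires instances of a single scope; got: %s",
          paste(unique(instances$scope), collapse = ", "))
  }
  stopifnot(all(instances$polarity %in% c("AFFIRMED", "NEGATED")))
  ord <- order(instances$concept_start)
  pol <- instances$polarity[ord]
  n_aff <- sum(pol == "AFFIRMED")
  n_neg <- sum(pol == "NEGATED")
  if (n_aff > n_neg) return("POSITIVE")
  if (n_neg > n_aff) return("NEGATIVE")
  if (pol[length(pol)] == "AFFIRMED") "POSITIVE" else "NEGATIVE"
}

#' Classify one note for personal and family suicidal history
#'
#' Partitions a note's extracted instances by scope and applies
#' [classify_instances()] to each partition.
#'
#' @param note_id Identifier carried into the result.
#' @param instances Instances extracted from this note.
#' @return One-row data.frame: `note_id`, `psh_label`, `fsh_label`,
#'   `n_psh_instances`, `n_fsh_instances`.
#' @export
classify_note <- function(note_id, instances) {
  psh <- instances[instances$scope == "PERSONAL", , drop = FALSE]
  fsh <- instances[instances$scope == "FAMILY", , drop = FALSE]
  data.frame(
    note_id = note_id,
    psh_label = classify_instances(psh),
    fsh_label = classify_instances(fsh),
    n_psh_instances = nrow(psh),
    n_fsh_instances = nrow(fsh),
    stringsAsFactors = FALSE
  )
}

#' Run extraction and note classification over a corpus
#'
#' @param notes data.frame with `note_id`, `text`, and optionally
#'   `patient_id` (carried through).
#' @param lexicon,config Passed to [extract_instances()].
#' @return data.frame with one row per note: `note_id`, `patient_id` (if
#'   present), `psh_label`, `fsh_label`, instance counts.
#' @export
classify_corpus <- function(notes, lexicon = default_lexicon(),
                            config = extractor_config()) {
  stopifnot(all(c("note_id", "text") %in% names(notes)))
  rows <- lapply(seq_len(nrow(notes)), function(i) {
    inst <- extract_instances(notes$text[i], lexicon, config)
    classify_note(notes$note_id[i], inst)
  })
  out <- do.call(rbind, rows)
  if ("patient_id" %in% names(notes)) {
    out$patient_id <- notes$patient_id[match(out$note_id, notes$note_id)]
    out <- out[, c("note_id", "patient_id", "psh_label", "fsh_label",
                   "n_psh_instances", "n_fsh_instances")]
  }
  out
}

#' Roll note labels up to the patient level
#'
#' A patient is POSITIVE for a scope iff at least one contributing note is
#' POSITIVE for that scope.
#'
#' @param classifications Note-level frame with `patient_id`, `psh_label`,
#'   `fsh_label` (e.g. from [classify_corpus()]).
#' @return data.frame: `patient_id`, `psh_label`, `fsh_label`, `n_notes`.
#' @export
aggregate_patients <- function(classifications) {
  stopifnot(all(c("patient_id", "psh_label", "fsh_label") %in%
                  names(classifications)))
  ids <- unique(classifications$patient_id)
  rows <- lapply(ids, function(pid) {
    sub <- classifications[classifications$patient_id == pid, , drop = FALSE]
    data.frame(
      patient_id = pid,
      psh_label = if (any(sub$psh_label == "POSITIVE")) "POSITIVE" else "NEGATIVE",
      fsh_label = if (any(sub$fsh_label == "POSITIVE")) "POSITIVE" else "NEGATIVE",
      n_notes = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
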