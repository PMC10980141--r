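# Readers/writers: JSONL and CSV corpora, BRAT standoff pairs, synthetic
# corpus bundles, instance serialisation.  All readers reject malformed
# records rather than silently coercing them.

CORPUS_FIELDS <- c("note_id", "patient_id", "date", "note_type", "text")

validate_notes <- function(notes, where = "corpus") {
  missing <- setdiff(CORPUS_FIELDS, names(notes))
  if (length(missing)) {
    stopf("%s is missing required field(s): %s", where,
          paste(missing, collapse = ", "))
  }
  dup <- notes$note_id[duplicated(notes$note_id)]
  if (length(dup)) {
    stopf("%s contains duplicate note_id(s): %s", where,
          paste(unique(dup), collapse = ", "))
  }
  bad <- which(is.na(notes$note_id) | !nzchar(notes$note_id))
  if (length(bad)) stopf("%s: record(s) %s have empty note_id", where,
                         paste(bad, collapse = ", "))
  parses <- vapply(notes$date, function(d) {
    if (is.na(d) || !nzchar(d)) return(TRUE)
    !is.na(parse_iso_date(d))
  }, logical(1), USE.NAMES = FALSE)
  bad_date <- which(!parses)
  if (length(bad_date)) {
    stopf("%s: record(s) %s have non-ISO-8601 date(s): %s", where,
          paste(bad_date, collapse = ", "),
          paste(unique(notes$date[bad_date]), collapse = ", "))
  }
  notes$text[is.na(notes$text)] <- ""
  notes
}

#' Read a clinical-note corpus
#'
#' @param path File path.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"`; guessed
#'   from the extension by default.  Required fields: `note_id`,
#'   `patient_id`, `date` (ISO-8601), `note_type`, `text`.
#' @return data.frame of notes; duplicate note ids or malformed records are
#'   rejected with an error naming the record.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "jsonl"
  }
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  notes <- if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stopf("line %d: invalid JSON", i))
      miss <- setdiff(CORPUS_FIELDS, names(rec))
      if (length(miss)) {
        stopf("line %d: missing required field(s): %s", i,
              paste(miss, collapse = ", "))
      }
      as.data.frame(rec[CORPUS_FIELDS], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  validate_notes(notes, where = path)
}

#' Write a clinical-note corpus
#'
#' Round-trips byte-exactly through [read_corpus()] (including multi-line
#' note text, which JSONL escapes and CSV quotes).
#'
#' @param notes Note frame with the required fields.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(notes, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  notes <- validate_notes(notes[, CORPUS_FIELDS, drop = FALSE], "notes")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(as.list(notes[i, , drop = FALSE]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(notes, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a BRAT standoff document
#'
#' Parses a `.txt`/`.ann` pair.  Only entity ("T") lines are supported;
#' relation/attribute/note lines are skipped with a warning, and
#' discontinuous spans (offsets containing ";") are rejected.  Every
#' entity's stored surface string must equal the corresponding text slice.
#'
#' @param txt_path,ann_path Paths to the text and annotation files.
#' @return List of class `stb_brat`: `text`, `entities` data.frame (`id`,
#'   `type`, `start`, `end`, `surface`; 0-based half-open offsets).
#' @export
read_brat <- function(txt_path, ann_path) {
  if (!file.exists(txt_path)) stopf("BRAT text file not found: %s", txt_path)
  if (!file.exists(ann_path)) stopf("BRAT ann file not found: %s", ann_path)
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  ents <- list()
  for (ln in lines) {
    if (!startsWith(ln, "T")) {
      warnf("skipping non-entity annotation line: %s",
            substr(ln, 1, 40))
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stopf("malformed entity line: %s", ln)
    span <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (grepl(";", parts[2], fixed = TRUE)) {
      stopf("discontinuous spans are not supported (entity %s)", parts[1])
    }
    if (length(span) != 3L) stopf("malformed entity span: %s", parts[2])
    start <- as.integer(span[2]); end <- as.integer(span[3])
    surface <- parts[3]
    slice <- slice_text(text, start, end)
    if (!identical(slice, surface)) {
      stopf("entity %s: surface %s does not match text slice %s",
            parts[1], dQuote(surface), dQuote(slice))
    }
    ents[[length(ents) + 1L]] <- data.frame(
      id = parts[1], type = span[1], start = start, end = end,
      surface = surface, stringsAsFactors = FALSE)
  }
  entities <- if (length(ents)) do.call(rbind, ents) else
    data.frame(id = character(), type = character(), start = integer(),
               end = integer(), surface = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(entities$id)) {
    stopf("duplicate entity id(s): %s",
          paste(unique(entities$id[duplicated(entities$id)]), collapse = ", "))
  }
  structure(list(text = text, entities = entities), class = "stb_brat")
}

#' Write a BRAT standoff document
#'
#' Write-then-[read_brat()] is the identity.
#'
#' @param doc List with `text` and `entities` as in [read_brat()].
#' @param txt_path,ann_path Output paths.
#' @return Invisibly, `c(txt_path, ann_path)`.
#' @export
write_brat <- function(doc, txt_path, ann_path) {
  writeLines(doc$text, txt_path, useBytes = TRUE, sep = "\n")
  ents <- doc$entities
  lines <- vapply(seq_len(NROW(ents)), function(i) {
    sprintf("%s\t%s %d %d\t%s", ents$id[i], ents$type[i], ents$start[i],
            ents$end[i], ents$surface[i])
  }, character(1))
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(c(txt_path, ann_path))
}

#' Convert extracted instances to a BRAT document
#'
#' Entity type encodes category, polarity and scope (e.g.
#' `SA_AFFIRMED_FAMILY`) for side-by-side review with gold annotations.
#'
#' @param text Note text.
#' @param instances Frame from [extract_instances()].
#' @return An `stb_brat` document.
#' @export
instances_to_brat <- function(text, instances) {
  n <- nrow(instances)
  entities <- data.frame(
    id = if (n) paste0("T", seq_len(n)) else character(),
    type = if (n) paste(instances$category, instances$polarity,
                        instances$scope, sep = "_") else character(),
    start = instances$concept_start %||% integer(),
    end = instances$concept_end %||% integer(),
    surface = instances$concept_text %||% character(),
    stringsAsFactors = FALSE
  )
  structure(list(text = text, entities = entities), class = "stb_brat")
}

#' Write extracted instances as JSONL
#'
#' One instance per line: note_id, category, polarity, scope, offsets and
#' matched strings.
#'
#' @param instances Instance frame with a `note_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instances_jsonl <- function(instances, path) {
  lines <- vapply(seq_len(nrow(instances)), function(i) {
    jsonlite::toJSON(as.list(instances[i, , drop = FALSE]),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a synthetic corpus bundle to disk
#'
#' Layout: `notes/<note_id>.txt` + `ann/<note_id>.ann` (BRAT pairs with the
#' planted gold instances), `corpus.jsonl`, `gold.csv` (note-level labels),
#' `patients.csv`, `icd.csv`, and `config.yaml` recording the exact
#' generator configuration for provenance.
#'
#' @param corpus An `stb_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_bundle <- function(corpus, dir) {
  stopifnot(inherits(corpus, "stb_corpus"))
  dir.create(file.path(dir, "notes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ann"), recursive = TRUE, showWarnings = FALSE)
  write_corpus(corpus$notes, file.path(dir, "corpus.jsonl"), "jsonl")
  utils::write.csv(
    corpus$notes[, c("note_id", "patient_id", "psh_label", "fsh_label")],
    file.path(dir, "gold.csv"), row.names = FALSE)
  utils::write.csv(corpus$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$icd, file.path(dir, "icd.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(corpus$config), file.path(dir, "config.yaml"))
  for (i in seq_len(nrow(corpus$notes))) {
    nid <- corpus$notes$note_id[i]
    sub <- corpus$instances[corpus$instances$note_id == nid, , drop = FALSE]
    n <- nrow(sub)
    doc <- structure(list(
      text = corpus$notes$text[i],
      entities = data.frame(
        id = if (n) paste0("T", seq_len(n)) else character(),
        type = if (n) paste(sub$category, sub$polarity, sub$scope, sep = "_")
               else character(),
        start = sub$start, end = sub$end, surface = sub$surface,
        stringsAsFactors = FALSE)), class = "stb_brat")
    write_brat(doc, file.path(dir, "notes", paste0(nid, ".txt")),
               file.path(dir, "ann", paste0(nid, ".ann")))
  }
  invisible(dir)
}
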