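#' Default lexicon for suicidal-history extraction
#'
#' The extraction rules are driven by a dual lexicon: target concepts for
#' suicidal thoughts and behaviors (STB) split into suicidal ideation (SI),
#' suicidal behavior (SB) and suicide attempt (SA), and historical modifiers
#' that mark a mention as past rather than current.  Around those sit the
#' ConText-style apparatus (negation cues, pseudo-negation cues, termination
#' cues), kinship terms for family attribution, and an exclusion list of
#' phrases that must never be read as a target concept (non-life-threatening
#' self-harm such as cutting or burning, and administrative boilerplate like
#' "suicide precautions").
#'
#' The shipped default is a curated reconstruction: it was assembled from
#' the concept categories the underlying method defines, not copied from any
#' institution's production dictionary, and every category can be overridden
#' from a YAML/JSON file via [read_lexicon()].
#'
#' Patterns are Perl-compatible regular expressions matched
#' case-insensitively; a pattern may opt out of case folding inline (the
#' `SI`/`SB`/`SA` abbreviations use `(?-i:...)` so that the Spanish word
#' "si" or a stray "sa" never fire).  Plain phrases are just regexes without
#' metacharacters.  Word-boundary anchoring is added automatically at match
#' time.
#'
#' @return An object of class `stb_lexicon`: a named list with fields
#'   `lexicon_version`, `target_concepts` (named list SI/SB/SA),
#'   `intrinsic_past_concepts`, `history_modifiers`, `temporal_modifiers`,
#'   `family_terms`, `negation_cues` (list with `pre` and `post`),
#'   `pseudo_negation_cues`, `termination_cues`, `exclusions`.
#' @seealso [read_lexicon()], [write_lexicon()], [validate_lexicon()]
#' @export
default_lexicon <- function() {
  lex <- list(
    lexicon_version = "stbhistory-default-1",
    target_concepts = list(
      SI = c(
        "suicidal ideations?",
        "suicidal thoughts?",
        "suicidal thinking",
        "thoughts? of suicide",
        "thoughts? of killing (?:him|her|them)sel(?:f|ves)",
        "wish(?:es|ed)? to die",
        "(?-i:SI)"
      ),
      SB = c(
        "suicidal behaviou?rs?",
        "suicidal gestures?",
        "self-?directed violence",
        "suicidality",
        "suicide",
        "(?-i:SB)"
      ),
      SA = c(
        "suicide attempts?",
        "attempted suicide",
        "tried to kill (?:him|her|them)sel(?:f|ves)",
        "committed suicide",
        "died by suicide",
        "(?-i:SA)"
      )
    ),
    # SA phrasings that denote a completed/past event by themselves; in
    # relaxed family mode these can form a family-history instance without
    # an explicit historical modifier ("her father died by suicide").
    intrinsic_past_concepts = c("committed suicide", "died by suicide"),
    history_modifiers = c(
      "history of",
      "hx of",
      "h/o",
      "history",
      "hx",
      "prior",
      "past",
      "previous(?:ly)?",
      "remote",
      "s/p",
      "status post",
      "in the past"
    ),
    # Date/age phrasings that imply pastness without an explicit modifier
    # ("suicide attempt 2014").  Kept as a separate category so they can be
    # switched off (use_temporal_modifiers = FALSE) to study the
    # timestamp-style failure mode.
    temporal_modifiers = c(
      "in (?:19|20)\\d{2}",
      "(?:19|20)\\d{2}",
      "\\d{1,2}/\\d{1,2}/\\d{2,4}",
      "\\d{1,2}/\\d{4}",
      "\\d{1,2}/\\d{1,2}",
      "(?:\\d+|a|several|many|few|a few) (?:years?|months?|weeks?) ago",
      "last (?:year|month|week)",
      "as a (?:child|teenager|adolescent)"
    ),
    family_terms = c(
      "mother", "father", "mom", "dad", "parent",
      "brother", "sister", "sibling", "son", "daughter",
      "grandmother", "grandfather", "grandparent", "grandma", "grandpa",
      "aunt", "uncle", "cousin", "nephew", "niece",
      "maternal", "paternal", "family", "familial", "relative"
    ),
    negation_cues = list(
      pre = c(
        "no", "denies", "denied", "denying", "without", "never",
        "negative for", "no evidence of", "no known"
      ),
      post = c(
        "unlikely", "(?:was|were|is|are) ruled out", "not present", "absent"
      )
    ),
    pseudo_negation_cues = c(
      "no increase in", "no change in", "no further", "not only",
      "unable to", "no significant change", "cannot rule out"
    ),
    termination_cues = c(
      "but", "however", "although", "though", "except",
      "aside from", "apart from", ";"
    ),
    exclusions = c(
      "cutting", "burning", "self-harm",
      "suicide precautions?", "suicide prevention", "suicide risk",
      "suicide hotline", "suicide screening", "suicide severity",
      "suicide safety"
    )
  )
  class(lex) <- "stb_lexicon"
  validate_lexicon(lex)
}

#' Validate a lexicon
#'
#' Checks the structural invariants every lexicon must satisfy: all
#' categories present and non-empty, no empty pattern, exclusions disjoint
#' from target concepts as literal strings, and every pattern compiling as a
#' Perl regex.
#'
#' @param lexicon A list with the fields of [default_lexicon()].
#' @return The validated lexicon (classed `stb_lexicon`), invisibly usable
#'   in pipelines; errors name the offending field.
#' @export
validate_lexicon <- function(lexicon) {
  required <- c("lexicon_version", "target_concepts", "history_modifiers",
                "temporal_modifiers", "family_terms", "negation_cues",
                "pseudo_negation_cues", "termination_cues", "exclusions")
  missing <- setdiff(required, names(lexicon))
  if (length(missing)) {
    stopf("lexicon is missing field(s): %s", paste(missing, collapse = ", "))
  }
  if (!all(c("SI", "SB", "SA") %in% names(lexicon$target_concepts))) {
    stopf("lexicon field 'target_concepts' must contain SI, SB and SA")
  }
  if (!all(c("pre", "post") %in% names(lexicon$negation_cues))) {
    stopf("lexicon field 'negation_cues' must contain 'pre' and 'post'")
  }
  flat <- list(
    target_concepts.SI = lexicon$target_concepts$SI,
    target_concepts.SB = lexicon$target_concepts$SB,
    target_concepts.SA = lexicon$target_concepts$SA,
    history_modifiers = lexicon$history_modifiers,
    temporal_modifiers = lexicon$temporal_modifiers,
    family_terms = lexicon$family_terms,
    negation_cues.pre = lexicon$negation_cues$pre,
    negation_cues.post = lexicon$negation_cues$post,
    pseudo_negation_cues = lexicon$pseudo_negation_cues,
    termination_cues = lexicon$termination_cues,
    exclusions = lexicon$exclusions
  )
  for (field in names(flat)) {
    pats <- flat[[field]]
    if (!length(pats) || !is.character(pats)) {
      stopf("lexicon field '%s' is empty", field)
    }
    if (any(!nzchar(pats)) || anyNA(pats)) {
      stopf("lexicon field '%s' contains an empty pattern", field)
    }
    for (p in pats) {
      ok <- tryCatch({
        suppressWarnings(grepl(boundary_wrap(p), "x", perl = TRUE))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stopf("lexicon field '%s': pattern does not compile: %s", field, p)
    }
  }
  clash <- intersect(tolower(lexicon$exclusions),
                     tolower(unlist(lexicon$target_concepts, use.names = FALSE)))
  if (length(clash)) {
    stopf("exclusions overlap target_concepts: %s", paste(clash, collapse = ", "))
  }
  extra <- lexicon$intrinsic_past_concepts %||% character()
  if (length(extra)) {
    if (!all(extra %in% unlist(lexicon$target_concepts, use.names = FALSE))) {
      stopf("intrinsic_past_concepts must be a subset of target_concepts")
    }
  }
  class(lexicon) <- "stb_lexicon"
  lexicon
}

#' Load a lexicon from file or the built-in default
#'
#' @param source `"default"` for the curated built-in lexicon, or a path to
#'   a YAML or JSON file following the documented schema (top-level keys as
#'   in [default_lexicon()]; format chosen by file extension).
#' @return A validated `stb_lexicon`.
#' @export
load_lexicon <- function(source = "default") {
  if (identical(source, "default")) return(default_lexicon())
  read_lexicon(source)
}

#' Read a lexicon file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` lexicon file.
#' @return A validated `stb_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stopf("lexicon file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("unsupported lexicon format '%s' (use yaml or json)", ext)
  }
  # YAML/JSON scalars come back length-1; coerce category vectors to character
  raw$target_concepts <- lapply(raw$target_concepts, as.character)
  raw$negation_cues <- lapply(raw$negation_cues, as.character)
  for (f in c("history_modifiers", "temporal_modifiers", "family_terms",
              "pseudo_negation_cues", "termination_cues", "exclusions",
              "intrinsic_past_concepts")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.character(raw[[f]])
  }
  validate_lexicon(raw)
}

#' Write a lexicon to file
#'
#' Write-then-[read_lexicon()] round-trips to an identical lexicon.
#'
#' @param lexicon A validated `stb_lexicon`.
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  lexicon <- validate_lexicon(lexicon)
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(lexicon)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    stopf("unsupported lexicon format '%s' (use yaml or json)", ext)
  }
  invisible(path)
}

#' @export
print.stb_lexicon <- function(x, ...) {
  cat("<stb_lexicon>", x$lexicon_version, "\n")
  cat(sprintf("  target concepts: SI=%d SB=%d SA=%d patterns\n",
              length(x$target_concepts$SI), length(x$target_concepts$SB),
              length(x$target_concepts$SA)))
  cat(sprintf("  history modifiers: %d explicit + %d temporal\n",
              length(x$history_modifiers), length(x$temporal_modifiers)))
  cat(sprintf("  family terms: %d; negation cues: %d pre / %d post\n",
              length(x$family_terms), length(x$negation_cues$pre),
              length(x$negation_cues$post)))
  cat(sprintf("  pseudo-negations: %d; terminations: %d; exclusions: %d\n",
              length(x$pseudo_negation_cues), length(x$termination_cues),
              length(x$exclusions)))
  invisible(x)
}
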