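# Seeded synthetic clinical-note generator with instance-level ground
# truth.  Emulates the documentation phenomena relevant to suicidal-history
# detection -- affirmed/negated history statements, family-history
# statements, timestamp-style mentions ("suicide attempt 2014"), and
# distractor boilerplate containing the string "suicide" -- embedded in
# innocuous clinical filler.  It makes no attempt at realistic clinical
# language; its job is a controllable benchmark with exact gold.

#' Synthetic corpus configuration
#'
#' All probabilities are in `[0, 1]`; the same config (including `seed`)
#' always yields a byte-identical corpus.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer count or range (e.g. `1:3`) of notes
#'   drawn per patient.
#' @param psh_prevalence,fsh_prevalence Patient-level probabilities of a
#'   true personal / family suicidal history.
#' @param negation_rate Probability that a note of a history-negative
#'   patient documents an explicit denial, and that an extra mention in a
#'   multi-instance note is negated.
#' @param multi_instance_rate Probability a mention-bearing note carries a
#'   second mention.
#' @param timestamp_style_rate Probability an affirmed personal mention
#'   uses date-only phrasing (no explicit "history of" modifier) -- the
#'   documentation style behind most rule-based false negatives.
#' @param distractor_rate Probability a note contains non-history
#'   "suicide"-string boilerplate (safety planning, risk screening).
#' @param icd_coding_rate Probability a truly history-positive patient has
#'   a qualifying ICD code dated before the earliest note.
#' @param mention_note_rate Probability that each note after the first of
#'   a history-positive patient also documents the history (the first note
#'   always does).
#' @param seed Integer RNG seed.
#' @return Object of class `stb_synth_config`.
#' @export
synthetic_config <- function(n_patients = 100L, notes_per_patient = 1:3,
                             psh_prevalence = 0.3, fsh_prevalence = 0.1,
                             negation_rate = 0.3, multi_instance_rate = 0.2,
                             timestamp_style_rate = 0.1,
                             distractor_rate = 0.3, icd_coding_rate = 0.05,
                             mention_note_rate = 0.8, seed = 1L) {
  probs <- c(psh_prevalence, fsh_prevalence, negation_rate,
             multi_instance_rate, timestamp_style_rate, distractor_rate,
             icd_coding_rate, mention_note_rate)
  stopifnot(n_patients >= 1, all(notes_per_patient >= 1),
            all(probs >= 0 & probs <= 1))
  structure(list(
    n_patients = as.integer(n_patients),
    notes_per_patient = as.integer(notes_per_patient),
    psh_prevalence = psh_prevalence, fsh_prevalence = fsh_prevalence,
    negation_rate = negation_rate,
    multi_instance_rate = multi_instance_rate,
    timestamp_style_rate = timestamp_style_rate,
    distractor_rate = distractor_rate, icd_coding_rate = icd_coding_rate,
    mention_note_rate = mention_note_rate,
    template_set = "stbhistory-templates-1",
    seed = as.integer(seed)
  ), class = "stb_synth_config")
}

# Template bank.  Each template records the sentence, the exact concept
# surface string (for offset bookkeeping), its category, and the planted
# polarity/scope.  Family ids mirror the documentation phenomena studied:
# affirmed_history, negated_history, family_affirmed, family_negated,
# timestamp_style, distractor.
stb_templates <- function() {
  t <- function(s, concept, category, polarity, scope) {
    list(sentence = s, concept = concept, category = category,
         polarity = polarity, scope = scope)
  }
  list(
    affirmed_history = list(
      t("Patient reports a history of suicide attempt several years ago.",
        "suicide attempt", "SA", "AFFIRMED", "PERSONAL"),
      t("H/o suicidal ideation with one prior hospitalization.",
        "suicidal ideation", "SI", "AFFIRMED", "PERSONAL"),
      t("Past suicidal behavior documented in outpatient chart.",
        "suicidal behavior", "SB", "AFFIRMED", "PERSONAL"),
      t("Endorses prior suicidal ideation during college.",
        "suicidal ideation", "SI", "AFFIRMED", "PERSONAL")
    ),
    negated_history = list(
      t("Denies any history of suicide attempt.",
        "suicide attempt", "SA", "NEGATED", "PERSONAL"),
      t("No prior suicide attempts.",
        "suicide attempts", "SA", "NEGATED", "PERSONAL"),
      t("Denies past suicidal ideation.",
        "suicidal ideation", "SI", "NEGATED", "PERSONAL"),
      t("No previous suicidal behavior reported.",
        "suicidal behavior", "SB", "NEGATED", "PERSONAL")
    ),
    family_affirmed = list(
      t("Mother has a history of suicide attempt.",
        "suicide attempt", "SA", "AFFIRMED", "FAMILY"),
      t("Family history significant for suicide attempt in her mother.",
        "suicide attempt", "SA", "AFFIRMED", "FAMILY"),
      t("Her father died by suicide.",
        "died by suicide", "SA", "AFFIRMED", "FAMILY"),
      t("Family history of suicidal ideation reported.",
        "suicidal ideation", "SI", "AFFIRMED", "FAMILY")
    ),
    family_negated = list(
      t("No family history of suicide attempt.",
        "suicide attempt", "SA", "NEGATED", "FAMILY"),
      t("Denies any family history of suicidal ideation.",
        "suicidal ideation", "SI", "NEGATED", "FAMILY")
    ),
    timestamp_style = list(
      t("Suicidal ideation 03/12/2019.",
        "Suicidal ideation", "SI", "AFFIRMED", "PERSONAL"),
      t("Suicide attempt 2014.",
        "Suicide attempt", "SA", "AFFIRMED", "PERSONAL"),
      t("On 04/22 was hospitalized x wk for suicide attempt by overdose.",
        "suicide attempt", "SA", "AFFIRMED", "PERSONAL")
    ),
    distractor = list(
      t("Suicide precautions reviewed with patient.", NA, NA, NA, NA),
      t("Provided the national suicide prevention lifeline number.",
        NA, NA, NA, NA),
      t("Routine suicide risk screening completed at intake.",
        NA, NA, NA, NA)
    )
  )
}

stb_filler <- function() {
  c("Medications were reviewed and reconciled at this visit.",
    "Vital signs stable and afebrile today.",
    "Sleep and appetite are adequate.",
    "Continue current medication regimen as prescribed.",
    "Reviewed laboratory results with the patient.",
    "Patient ambulating independently and participating in care.",
    "Follow up with primary care provider as scheduled.",
    "Discussed diet and exercise recommendations.")
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

# Assemble one note.  `plan` is a list of (family, template) picks in the
# order they will appear; returns text plus the planted-instance frame.
assemble_note <- function(note_id, patient_id, plan, distract, rng_unused) {
  filler <- stb_filler()
  sents <- list()
  planted <- list()
  n_lead <- sample.int(3L, 1L)
  for (k in seq_len(n_lead)) sents[[length(sents) + 1L]] <- list(s = pick(as.list(filler)))
  for (p in plan) {
    sents[[length(sents) + 1L]] <- list(s = p$tpl$sentence, plant = p)
  }
  if (distract) {
    sents[[length(sents) + 1L]] <- list(s = pick(stb_templates()$distractor)$sentence)
  }
  sents[[length(sents) + 1L]] <- list(s = pick(as.list(filler)))

  offset <- 0L
  texts <- character(length(sents))
  for (i in seq_along(sents)) {
    s <- sents[[i]]$s
    texts[i] <- s
    if (!is.null(sents[[i]]$plant)) {
      p <- sents[[i]]$plant
      rel <- regexpr(p$tpl$concept, s, fixed = TRUE)
      stopifnot(rel > 0)
      planted[[length(planted) + 1L]] <- data.frame(
        note_id = note_id, patient_id = patient_id,
        template_family = p$family,
        category = p$tpl$category, polarity = p$tpl$polarity,
        scope = p$tpl$scope,
        start = offset + as.integer(rel) - 1L,
        end = offset + as.integer(rel) - 1L + attr(rel, "match.length"),
        surface = p$tpl$concept,
        stringsAsFactors = FALSE
      )
    }
    offset <- offset + nchar(s) + 1L  # sentences joined by "\n"
  }
  list(text = paste(texts, collapse = "\n"),
       planted = if (length(planted)) do.call(rbind, planted) else NULL)
}

# Plan the planted mentions of one note for one scope.
plan_scope <- function(positive, carries, config, families) {
  tpls <- stb_templates()
  plan <- list()
  if (positive && carries) {
    main_family <- if (families$scope == "PERSONAL" &&
                       stats::runif(1) < config$timestamp_style_rate) {
      "timestamp_style"
    } else {
      families$affirmed
    }
    extra <- NULL
    if (stats::runif(1) < config$multi_instance_rate) {
      extra_family <- if (stats::runif(1) < config$negation_rate)
        families$negated else families$affirmed
      extra <- list(family = extra_family, tpl = pick(tpls[[extra_family]]))
    }
    # extra mention (if any) precedes the main affirmed mention, so the
    # majority/last-mention rule always derives POSITIVE for this note
    if (!is.null(extra)) plan[[length(plan) + 1L]] <- extra
    plan[[length(plan) + 1L]] <- list(family = main_family,
                                      tpl = pick(tpls[[main_family]]))
  } else if (!positive && stats::runif(1) < config$negation_rate) {
    plan[[length(plan) + 1L]] <- list(family = families$negated,
                                      tpl = pick(tpls[[families$negated]]))
    if (stats::runif(1) < config$multi_instance_rate) {
      plan[[length(plan) + 1L]] <- list(family = families$negated,
                                        tpl = pick(tpls[[families$negated]]))
    }
  }
  plan
}

#' Generate a synthetic corpus with instance-level ground truth
#'
#' Draws patient-level history states at the configured prevalences, plants
#' template mentions accordingly, derives every note's gold labels from the
#' planted instances through the same majority/last-mention rule the
#' document classifier uses, and emits an intentionally under-coded ICD
#' table (each truly positive patient is coded with probability
#' `icd_coding_rate`, dated before the earliest note).
#'
#' @param config A [synthetic_config()].
#' @return Object of class `stb_corpus`: list with `notes` (note_id,
#'   patient_id, date, note_type, text, psh_label, fsh_label), `instances`
#'   (planted gold mentions with offsets and template family), `patients`
#'   (patient-level labels), `icd` (patient_id, code, date), `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "stb_synth_config"))
  with_seed(config$seed, {
    note_types <- c("progress note", "psychiatric note", "ED note",
                    "telephone encounter")
    notes <- list(); instances <- list()
    psh_true <- stats::runif(config$n_patients) < config$psh_prevalence
    fsh_true <- stats::runif(config$n_patients) < config$fsh_prevalence
    note_counter <- 0L
    for (pi in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", pi)
      n_notes <- if (length(config$notes_per_patient) > 1L) {
        sample(config$notes_per_patient, 1L)
      } else {
        config$notes_per_patient
      }
      for (ni in seq_len(n_notes)) {
        note_counter <- note_counter + 1L
        nid <- sprintf("N%06d", note_counter)
        carries_p <- ni == 1L || stats::runif(1) < config$mention_note_rate
        carries_f <- ni == 1L || stats::runif(1) < config$mention_note_rate
        plan <- c(
          plan_scope(psh_true[pi], carries_p, config,
                     list(scope = "PERSONAL", affirmed = "affirmed_history",
                          negated = "negated_history")),
          plan_scope(fsh_true[pi], carries_f, config,
                     list(scope = "FAMILY", affirmed = "family_affirmed",
                          negated = "family_negated"))
        )
        distract <- stats::runif(1) < config$distractor_rate
        built <- assemble_note(nid, pid, plan, distract)
        notes[[note_counter]] <- data.frame(
          note_id = nid, patient_id = pid,
          date = as.character(as.Date("2018-01-01") + sample.int(364L, 1L)),
          note_type = sample(note_types, 1L),
          text = built$text, stringsAsFactors = FALSE
        )
        if (!is.null(built$planted)) {
          instances[[length(instances) + 1L]] <- built$planted
        }
      }
    }
    notes <- do.call(rbind, notes)
    instances <- if (length(instances)) do.call(rbind, instances) else
      data.frame(note_id = character(), patient_id = character(),
                 template_family = character(), category = character(),
                 polarity = character(), scope = character(),
                 start = integer(), end = integer(), surface = character(),
                 stringsAsFactors = FALSE)
    rownames(notes) <- rownames(instances) <- NULL

    # derive note labels from planted instances via the document rule
    derive <- function(nid, scope) {
      sub <- instances[instances$note_id == nid & instances$scope == scope, ,
                       drop = FALSE]
      if (!nrow(sub)) return("NEGATIVE")
      classify_instances(data.frame(polarity = sub$polarity,
                                    concept_start = sub$start))
    }
    notes$psh_label <- vapply(notes$note_id, derive, character(1), "PERSONAL")
    notes$fsh_label <- vapply(notes$note_id, derive, character(1), "FAMILY")

    patients <- data.frame(
      patient_id = sprintf("P%05d", seq_len(config$n_patients)),
      psh_label = ifelse(psh_true, "POSITIVE", "NEGATIVE"),
      fsh_label = ifelse(fsh_true, "POSITIVE", "NEGATIVE"),
      stringsAsFactors = FALSE
    )

    # under-coded ICD table: qualifying code before the earliest note with
    # probability icd_coding_rate; background non-STB codes for realism;
    # occasional post-index qualifying code that must NOT count.
    icd <- list()
    stb_codes <- c("R45.851", "T14.91", "X71.0", "Z91.5", "V62.84", "E950.0")
    other_codes <- c("I10", "E11.9", "J45.909", "M54.5")
    for (pi in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", pi)
      first_note <- min(as.Date(notes$date[notes$patient_id == pid]))
      if (psh_true[pi] && stats::runif(1) < config$icd_coding_rate) {
        icd[[length(icd) + 1L]] <- data.frame(
          patient_id = pid, code = sample(stb_codes, 1L),
          date = as.character(first_note - sample.int(720L, 1L)),
          stringsAsFactors = FALSE)
      }
      if (psh_true[pi] && stats::runif(1) < 0.05) {
        icd[[length(icd) + 1L]] <- data.frame(
          patient_id = pid, code = sample(stb_codes, 1L),
          date = as.character(first_note + sample.int(360L, 1L)),
          stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < 0.3) {
        icd[[length(icd) + 1L]] <- data.frame(
          patient_id = pid, code = sample(other_codes, 1L),
          date = as.character(first_note - sample.int(720L, 1L)),
          stringsAsFactors = FALSE)
      }
    }
    icd <- if (length(icd)) do.call(rbind, icd) else
      data.frame(patient_id = character(), code = character(),
                 date = character(), stringsAsFactors = FALSE)
    rownames(icd) <- NULL

    structure(list(notes = notes, instances = instances, patients = patients,
                   icd = icd, config = config),
              class = "stb_corpus")
  })
}

#' @export
print.stb_corpus <- function(x, ...) {
  cat(sprintf("<stb_corpus> %d notes / %d patients (seed %d)\n",
              nrow(x$notes), nrow(x$patients), x$config$seed))
  cat(sprintf("  PSH-positive patients: %d; FSH-positive: %d\n",
              sum(x$patients$psh_label == "POSITIVE"),
              sum(x$patients$fsh_label == "POSITIVE")))
  cat(sprintf("  planted instances: %d; ICD records: %d\n",
              nrow(x$instances), nrow(x$icd)))
  invisible(x)
}
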