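---
title: "Detecting personal and family suicidal history in clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting personal and family suicidal history in clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stbhistory)
```

## The problem

A personal history of suicidal thoughts and behaviors (PSH) and a family
history of the same (FSH) are among the strongest known risk factors for
future suicide events, yet they are rarely captured in structured data.
ICD-9 had no code for the *historical* aspect of suicidality at all, and
even under ICD-10 most patients whose notes document a past attempt carry
no corresponding diagnosis code.  The information lives almost entirely in
free-text clinical narrative: "h/o suicide attempt in 2014", "mother died
by suicide", "denies any history of SI".

`stbhistory` detects these two note-level outcomes with two complementary
methods and ships the evaluation and benchmarking machinery around them:

1. a **rule-based extractor**: lexicon-driven concept matching, historical
   modifier pairing, ConText-style negation, and kinship-proximity family
   attribution, aggregated to note labels;
2. a **context-window span pipeline** feeding a trainable classifier,
   evaluated by repeated cross-validation with weighted metrics.

Because real clinical corpora for this task are protected health data, the
package also ships a seeded **synthetic note generator** with
instance-level ground truth.  Everything below runs on synthetic data.

## The rule-based model

Suicidal thoughts and behaviors (STB) are modelled as three concept
categories: suicidal ideation (SI), suicidal behavior (SB), and suicide
attempt (SA).  The extractor works sentence-by-sentence:

1. **Concept matching.** Every target-concept pattern in the lexicon is
   matched case-insensitively.  Matches overlapping an *exclusion* phrase
   are suppressed (non-life-threatening self-harm such as "cutting" or
   "burning", and boilerplate such as "suicide precautions").  Overlaps
   resolve longest-match-wins, ties to the leftmost start.
2. **Modifier pairing.** A mention only becomes a *history* instance when
   paired with a historical modifier ("history of", "h/o", "prior", ...)
   in the same sentence within `max_pair_distance` tokens (default 10).
   A bare current-tense "suicidal ideation" is deliberately not history.
3. **Polarity.** ConText-style negation: a cue ("denies", "no", ...)
   within `negation_scope` tokens (default 6) negates the concept unless a
   termination cue ("but", "however", ";") intervenes or the cue is part
   of a pseudo-negation ("no change in").  Post-scope cues ("... was
   ruled out") mirror this forward.
4. **Scope.** FAMILY iff a kinship term falls within `family_proximity`
   tokens (default 5) of the concept-modifier span in the same sentence;
   otherwise PERSONAL.

The three distances are the tunable parameters that matter.  Their
defaults follow common practice for bounded-scope context rules: negation
cues rarely govern past six tokens, and kinship attribution beyond five
tokens is mostly wrong ("mother was present ... discussed prior SA" is the
patient's attempt, not the mother's).  All are surfaced in
`extractor_config()` rather than hard-coded.

Two relaxations are exposed as flags because annotation practice genuinely
varies:

* `family_verb_concepts` (default on): "her father died by suicide"
  carries intrinsic pastness, so a kinship term next to a
  completed-suicide phrasing forms a family instance without an explicit
  modifier.  Family events are very often documented this way.
* `treat_negated_unmodified_as_history` (default off): whether "denies
  SI" — negated, but not explicitly historical — counts as a (negated)
  history instance.  Off by default because the pairing step defines
  history; some annotation schemes count it, so it is a switch.

A third flag, `use_temporal_modifiers` (default on), controls whether
date-only phrasings ("suicide attempt 2014", "SI 03/12/2019") count as
historical modifiers.  Timestamp-style documentation is the dominant
cause of rule-based false negatives in external-site error analyses, so
the default lexicon includes year/date patterns as a remediation, and
turning them off reproduces the failure mode for study.

### Document and patient labels

Note-level labels follow the annotation guideline exactly
(`classify_instances()`): no instance of a scope means NEGATIVE; a single
instance decides by its own polarity; several instances vote by majority;
an exact tie is decided by the polarity of the *last-mentioned* instance,
operationalised as the greatest concept start offset.  NEGATIVE conflates
"explicitly negated" and "never mentioned" — that is the canonical binary
form of the four-label scheme (PSH/FSH × present/absent); the instance
lists are retained on the classification object for error analysis.
Patients are POSITIVE iff any contributing note is POSITIVE.

```{r doc-rule}
extract_instances("Pt denies SI. Mother has a history of suicide attempt.")
```

## The span pipeline and classifier

The trainable route reuses the rule engine's dictionary as *anchor* rules
(concept optionally preceded by a modifier, so "history of suicide
attempt" is one anchor).  Around each anchor an `n`-word context window is
cut (`n` ∈ {8, 16, 24, 32} in the sweep; counted in word tokens,
punctuation rendered but not counted, windows cross sentence boundaries
and truncate at document bounds).  Overlapping or adjacent windows merge;
the merged spans joined by a reserved `[SEP]` token form the document's
text representation, labelled with the document's gold label.  Anchor-free
documents are kept with a reserved `[EMPTY]` placeholder so that every
labelled note enters training and evaluation; dropping them instead is a
flag (`drop_anchor_free`).  This keeps label multisets conserved between
corpus and span dataset, which the tests assert.

The classifier sits behind a two-generic backend contract
(`backend_fit()` / `backend_predict()`).  The shipped **reference
backend** is a ridge-penalised logistic regression over lower-cased token
counts (glmnet, `alpha = 0`, fixed `lambda = 0.01`, no standardisation) —
deterministic given a seed, dependency-light, and strong on
window-local lexical evidence, which is exactly the signal the span
representation concentrates.  Transformer encoders (clinical BERT-style
models with frozen early layers, batch size 16, learning rate 1e-5,
dropout 0.3, 5 epochs, AdamW) conform to the same contract; the
`train_config()` object carries those hyperparameters through unchanged.
How many layers to freeze is left to the backend (`freeze_early_layers`
is a boolean intent, not a count), since no principled default exists.

Cross-validation deliberately mirrors a quirk of the protocol it
implements: "10-fold cross-validation using 80% for training and 20% for
testing" describes *repeated random sub-sampling*, not standard 10-fold
(which would hold out 10%).  `make_cv_splits()` therefore defaults to ten
independent seeded 80/20 partitions, with conventional disjoint k-fold
behind `method = "disjoint"`.  Fold metrics are summarised as mean ±
sample (n−1) standard deviation; weighted averaging is the default
because both outcomes are heavily imbalanced.  Folds whose training half
degenerates to a single class are skipped and recorded, not silently
scored.

## The synthetic generator

`generate_corpus()` emulates the documentation phenomena the methods must
confront, not clinical language in general:

* template families **affirmed-history**, **negated-history**,
  **family-affirmed**, **family-negated**, **timestamp-style**, and
  **distractor** (safety-planning/risk-screening boilerplate that contains
  the string "suicide" but no history), embedded in innocuous filler
  sentences, one sentence per line;
* patient-level PSH/FSH states drawn at configured prevalences (defaults
  0.3 and 0.1, matching a screening-enriched annotation corpus); the
  first note of a positive patient always documents the history, later
  notes with probability `mention_note_rate` (0.8);
* note gold labels are *derived* from the planted instances through the
  same majority/last-mention rule the classifier uses, so gold is
  self-consistent by construction and the planted offsets point at the
  planted surfaces (both are asserted in tests);
* an intentionally under-coded ICD table: truly positive patients carry a
  qualifying code dated before their earliest note with probability
  `icd_coding_rate` (default 0.05, mid-range of the 2–9% coded fractions
  reported for real gold corpora), plus background non-STB codes and the
  occasional post-index code that must not count.

Default rates (`negation_rate` 0.3, `multi_instance_rate` 0.2,
`timestamp_style_rate` 0.1, `distractor_rate` 0.3) were chosen once as
plausible documentation frequencies and are not calibrated to any
evaluation outcome.  In multi-instance positive notes the extra mention is
planted *before* the forced affirmed one, so derived note labels provably
match the intended patient states at any rate setting.

What passing on this corpus does **not** show: robustness to real
documentation diversity.  Template surfaces are finite and authored to be
recoverable by the default lexicon (except the distractors and, for the
timestamp family, recoverable only via temporal modifiers); real notes
contain misspellings, site-specific abbreviations, copy-forward noise and
EHR templating structure, none of which the generator emulates and the
first of which historically halves external-site recall.  Perfect
noise-free recovery is a correctness check on the machinery, not a
performance claim.

```{r demo}
corp <- generate_corpus(synthetic_config(n_patients = 60, seed = 42,
                                         timestamp_style_rate = 0))
rep <- extraction_report(corp)
rep$family_recall
positive_f1(rep$psh)
```

Raising `timestamp_style_rate` with temporal modifiers disabled lowers
recall while precision holds — the per-family recall table isolates the
failure mode:

```{r timestamp}
corp_ts <- generate_corpus(synthetic_config(n_patients = 60, seed = 42,
                                            timestamp_style_rate = 1))
rep_ts <- extraction_report(
  corp_ts, config = extractor_config(use_temporal_modifiers = FALSE))
rep_ts$family_recall
```

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open everywhere (the BRAT
  convention); token indices are 1-based (the R convention).  The two
  never mix: offsets index characters, indices index token rows.
* Metric zero-divisions (a class never predicted, or absent from gold)
  score 0 with a flag, keeping macro averages defined.
* Cohen's kappa returns 1 when both annotators agree perfectly on a
  single label (observed and expected agreement both 1) and `NaN` in the
  degenerate case of unit expected agreement without unit observed
  agreement (unreachable from real annotation tables, but defined).
* Overlap ties in matching break longest-first, then leftmost, then
  pattern order; modifier-pairing ties break to the earlier modifier —
  every tie-break is deterministic, and byte-identical reruns are tested.
* Empty notes, anchor-free documents, empty instance lists, and empty ICD
  tables all flow through as empty-but-valid values, never errors.
* ICD matching normalises codes (upper-case, dots stripped) and matches
  by prefix, so "X71" covers "X71.0"; "on or before the index date" is
  date-inclusive; the shipped code set is an editable reconstruction.

## Problem sizes

The test suite and the acceptance script size their corpora at 120–500
synthetic patients (about 240–1000 notes): large enough that binomial
checks on prevalences and coded fractions are meaningful at 3σ, small
enough that the full suite runs in under a minute on one core.

## Known limitations

* The default lexicon is a curated reconstruction, not a validated
  site dictionary; external deployments should expect to localise it
  (every category loads from YAML/JSON).
* Semi-structured/templated note content is processed as plain text; no
  template stripping is attempted in this version.
* The "disambiguation" step of concept mapping is realised only as the
  exclusion and pseudo-negation lists.
* Temporal *resolution* (when the event happened) is out of scope; dates
  only serve as pastness evidence.
* No transformer backend ships with the package; the contract is the
  extension point.
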