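# stbhistory

Detecting a **personal history** (PSH) and a **family history** (FSH) of
suicidal thoughts and behaviors (STB — suicidal ideation, suicidal
behavior, suicide attempts) in free-text clinical notes.

Both histories are strong risk factors for future suicide events, and both
are notoriously absent from structured data: most patients whose notes
document a past attempt carry no corresponding ICD-9/10 code (ICD-9 had no
code for the historical aspect at all), and no ICD code for family
suicidal history exists.  The signal lives in narrative text — "h/o
suicide attempt in 2014", "mother died by suicide", "denies any history of
SI" — which is what this package mines.

It is aimed at clinical-NLP researchers and EHR phenotyping teams who need
(a) a transparent rule-based extractor, (b) a span-classification pipeline
for trainable models, (c) the evaluation apparatus to compare both against
gold annotations and against code-based phenotyping, and (d) a synthetic
benchmark so all of it runs without protected health data.

## What is inside

**Rule-based extractor.**  A dual-lexicon engine: target STB concepts and
historical modifiers, matched by regular expressions with
longest-match-wins overlap resolution and an exclusion list
(non-life-threatening behaviors such as *cutting*/*burning* are never
concepts).  Each concept pairs with its nearest same-sentence modifier
within a token budget; polarity is assigned ConText-style — a negation cue
within a bounded scope negates unless a termination cue ("but", ";")
intervenes or the cue is a pseudo-negation ("no change in"); scope is
FAMILY iff a kinship term falls near the concept-modifier span.

**Document rule.**  Per scope: no instance → NEGATIVE; one instance →
its polarity decides; several → majority polls; an exact tie is broken by
the last-mentioned instance.  Patients are positive if any note is.

**Span pipeline + classifier.**  Anchor phrases (concept, optionally
modifier-prefixed) are matched with the same dictionary; an *n*-word
context window around each anchor (n ∈ {8, 16, 24, 32}) is extracted,
merged and joined into one text representation per document, labelled with
the document's gold label.  A backend contract (`backend_fit` /
`backend_predict`) runs inside repeated random 80/20 cross-validation with
weighted precision/recall/F1 summarised as mean ± sd.  The shipped
reference backend is a seeded ridge logistic regression over token counts;
transformer encoders plug into the same contract.

**Evaluation & baseline.**  Confusion counts, per-class/macro/weighted
P/R/F1, Cohen's kappa, and an ICD-code baseline: among gold-positive
patients, the fraction carrying a qualifying STB diagnosis code on or
before their index date versus the fraction detected from notes.

**Synthetic corpus.**  A seeded generator planting affirmed/negated
personal and family mentions, timestamp-style mentions ("Suicide attempt
2014.") and distractor boilerplate into filler text, with exact
instance-level gold (BRAT + CSV + JSONL bundle) and an under-coded ICD
table.

## Worked example

```r
library(stbhistory)

extract_instances("Pt denies SI. Mother has a history of suicide attempt in 2009.")
#>   category polarity  scope    concept_text modifier_text
#> 1       SA AFFIRMED FAMILY suicide attempt    history of
```

One instance: *suicide attempt*, affirmed, attributed to the family
("Mother" within the proximity window).  The bare negated "SI" is not a
*history* instance under the default configuration (no historical
modifier), so this note classifies PSH-negative, FSH-positive.

```r
corp <- generate_corpus(synthetic_config(n_patients = 100, seed = 42))
corp
#> <stb_corpus> 204 notes / 100 patients (seed 42)
#>   PSH-positive patients: 28; FSH-positive: 6
#>   planted instances: 210; ICD records: 35

extraction_report(corp)
#> <stb_extraction_report>
#>   PSH: accuracy 1.000, macro F1 1.000
#>   FSH: accuracy 1.000, macro F1 1.000
#>   instance precision: 1.000
#>   per-template-family recall:
#>   template_family  n recovered recall
#>  affirmed_history 56        56      1
#>   family_affirmed 13        13      1
#>    family_negated 88        88      1
#>   negated_history 49        49      1
#>   timestamp_style  4         4      1
```

The report scores rule-extracted note labels against the generated gold:
document-level accuracy/F1 for both outcomes, instance-level precision,
and recall broken down by planted template family — the per-failure-mode
view (disable temporal modifiers via
`extractor_config(use_temporal_modifiers = FALSE)` and the
`timestamp_style` row drops to 0 while precision holds).

A command-line wrapper over the same functions ships in
`inst/cli/stbhistory.R` (`simulate`, `extract`, `classify`, `spans`,
`train`, `evaluate`, `icd-baseline`).

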