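---
title: "Extracting heart-disease risk factors from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting heart-disease risk factors from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardionlp)
```

## The task

Longitudinal notes of diabetic patients record heart-disease risk factors as
free text: disease mentions ("type 1 diabetes", "HTN"), lab values
("BP: 158/72", "A1c 8.2"), medication lists, smoking statements, and family
history. `cardionlp` turns each note into a set of tags of the form

> (risk factor, indicator attribute, time attributes),

where the risk factor is one of CAD, DIABETES, HYPERLIPIDEMIA, HYPERTENSION,
OBESITY, MEDICATION, SMOKER, FAMILY_HIST; the indicator attribute names the
kind of evidence (a *mention*, *high A1c*, a medication category such as
*ACE inhibitors*, ...); and the time attributes locate the evidence relative
to the document creation time (DCT) parsed from the note's
"Record date: YYYY-MM-DD" header. Smoking and family history are
document-level classifications and carry no time attribute. The legal
(risk factor, indicator) pairs live in a machine-readable schema
(`legal_indicator_table()`), and indicator assignment itself is a
declarative, auditable rule ledger (`indicator_rules()`).

## Pipeline and modeling assumptions

**Sentences and tokens.** Clinical notes are line-oriented; every line break
ends a sentence so that heading lines ("MEDICATIONS:") are isolated, and
sentence-final punctuation followed by whitespace splits within lines. All
spans are 0-based half-open character intervals into the raw text, chosen so
that any annotation round-trips exactly (`text_slice(text, start, end)`
equals the stored sentence or token text). Slash compounds such as "158/72"
tokenize into three tokens; the lab-value rules operate on raw sentence text,
so tokenization conventions do not affect extraction. The POS tagger is a
deterministic lexicon-and-suffix tagger emitting Penn-style tags. It is built
for the coarse noun/verb distinctions the downstream feature templates
consume, not for general parsing — an intentional trade of coverage for
reproducibility.

**Concept recognition.** Disease, CAD-phrase, and medication mentions come
from longest-match n-gram dictionary lookup (n ≤ 4) over sentence tokens with
three normalization attempts per n-gram: raw, misspelling-corrected, and
abbreviation-expanded. Expansion precedes nothing exotic: abbreviations are
exact-match, the misspelling map is an explicit list, and there is no
edit-distance matching. Overlapping candidate matches collapse to the longest
span. Negated mentions ("no CAD") are *not* suppressed; context handling is a
known limitation, acceptable because negated risk-factor mentions are rare in
this genre.

**Lab values and thresholds.** Extraction patterns cover the dialects
"BP: S/D", "blood pressure S/D", "blood pressure *words* at S/D", and the
range form "S1–S2/D1–D2"; keyword-then-number patterns cover lipids, A1c,
glucose, BUN, creatinine, and BMI. Ranges are resolved to the per-component
maximum, so "120–130/88–92" is read as 130/92 and the high diastolic at the
top of the range still reaches the filter — a deliberate repair of the
classic failure mode where ranges are truncated to "130/88" and missed.
Plausibility gates (systolic 50–300, diastolic 30–200 mmHg) drop garbage
matches. Thresholds are strict inequalities:

| parameter | default | units | rationale |
|---|---|---|---|
| systolic_high | 140 | mmHg | extraction rule ledger |
| diastolic_high | 90 | mmHg | extraction rule ledger |
| a1c_high | 6.5 | % | standard diagnostic cutoff |
| glucose_high | 126 | mg/dL | fasting-glucose diagnostic cutoff |
| total_chol_high | 240 | mg/dL | "high" total cholesterol |
| ldl_high | 100 | mg/dL | optimal-LDL upper bound |
| bmi_obese | 30 | kg/m² | obesity definition |

Only the blood-pressure cutoffs are fixed by the rule ledger; the others are
standard clinical guideline values supplied as explicit, overridable defaults
(`lab_thresholds()`). BUN, creatinine, and triglycerides are extracted but
never promoted to risk-factor evidence.

**Sectionizer.** A linear-chain conditional random field over each document's
sentence sequence assigns *section heading*, *section heading with text*, or
*text*. The chain structure follows from the feature template, which includes
the neighbors' features. Local features: first word uppercased, all words
uppercased/lowercased, heading-dictionary match (case-insensitive
containment), first and second word, final full stop, colon presence;
neighbor features are the neighbor's own local features, non-recursively.
Training is penalized maximum likelihood (L2, λ = 0.1) via forward–backward
gradients and L-BFGS from a zero start, hence deterministic for fixed data. A
post-classifier override relabels TEXT sentences containing heading-lexicon
terms as SECTION_HEADING; it is idempotent. Section names are the lower-cased
text before the first colon and propagate forward from the most recent
heading.

**Smoking status.** Sentences containing smoking-lexicon terms are classified
current/past/never by a multinomial Naive Bayes over bag-of-words plus POS
tags (additive smoothing, α = 1). The rare "ever" class is excluded from the
problem. Documents with no smoking sentence are *unknown*; with several
sentences, the priority current > past > never resolves the document — a
clinical-recency choice, since a current-smoker statement dominates the risk
picture. Prediction ties break in that same fixed class order.

**Family history of premature CAD.** Purely rule-based: *present* iff some
sentence contains a CAD term, a first-degree-relation term, and a parseable
age below the premature-age threshold; otherwise *not present* (the
no-evidence outcome maps to *not present*, the only other legal value). The
default cutoff is **55 years**; 45 is the other convention in circulation,
so the parameter is exposed (`fh_age_threshold`). Age patterns: "at age N",
"aged N", "at N", "died … N"; a CAD+relation sentence without a parseable
age is treated as not premature.

**Time attributes.** Each recognized phrase is classified into before DCT /
during DCT / after DCT / *continuing* by a multinomial Naive Bayes over the
phrase tokens, the one-token neighborhood with POS tags, the section name,
and the indicator attribute; *continuing* expands to all three attributes
(never 0 or 2). One deterministic rule overrides the classifier: medications
under a medication section heading are always *continuing*. Tie-breaks use
the fixed class order (before, during, after, continuing).

## The synthetic-data generator

No public corpus with this tag schema exists, so the package generates one.
`generate_corpus(gen_config(seed))` produces notes with a record-date header
and sections drawn from heading templates; each construct family (disease
mentions, CAD phrases, medication lists, the four blood-pressure dialects
including ranges, lipid panels, blood tests, smoking statements,
family-history statements) has at least four surface templates, plus
configurable abbreviation (default 0.3) and misspelling (default 0.1) rates.
Default corpus shape (10 patients × 3 notes, construct inclusion
probabilities 0.2–0.8, systolic ~ U[100, 200], diastolic ~ U[50, 110])
emulates the structure of longitudinal diabetic-patient records at desk
scale. Gold tags derive from the planting decisions through the generator's
own inline logic — a planted 158/72 yields a hypertension tag iff it exceeds
the configured cutoffs — deliberately *not* the extractor's code path, so
end-to-end agreement is a genuine cross-check. `generate_training_sets()`
yields labeled material for the three learned components; sectionizer
training also includes interior subsequences of notes so the chain start is
not biased toward the date-header class.

What the generator does **not** emulate: free narrative style, negation and
hedging, cross-note coreference, OCR noise, unit variation (mmol/L), or
abbreviations outside the shipped dictionary. Passing the end-to-end tests
therefore demonstrates that the mechanism is correct and self-consistent on
template-generated language, not that field performance on real EHRs would
match.

## Numerical and design choices

- All randomness flows from explicit integer seeds; generation, training
  (zero-initialized L-BFGS, count-based Naive Bayes), and decoding are
  bit-for-bit reproducible, verified by serialization hashes.
- Evaluation is tag-level, not span-level, because indicator and time
  attributes are document-scoped claims; per-document duplicates are merged
  before scoring. Macro-averaging is the unweighted mean of per-document
  scores; a document with neither gold nor predicted tags for a key is
  skipped for that key by default (`macro_empty = "skip"`), with a "zero"
  convention available since both exist in practice.
- Degenerate inputs: empty text yields no sentences; whitespace-only
  sentences tokenize to nothing; empty lexicon files are valid and degrade
  to no matches; training aborts with a named-class error when a class is
  absent.
- Test problem sizes: unit properties run on 3–40-note corpora; the
  end-to-end recovery check uses a 200-note corpus (seeded), where tag
  recovery against generator gold reaches micro-F ≈ 0.99 and the learned
  components exceed 0.90 held-out accuracy. These sizes were chosen as the
  smallest at which every construct family and class appears many times.

## Known limitations

- No negation or context awareness: "denies hypertension" still yields a
  mention tag.
- The CAD event/test-result/symptom lexicon is a small starter list and is
  the weakest recognizer by construction.
- One note per file; multi-record files are out of scope.
- No unit conversion and no waist-circumference extraction.
- The medication dictionary is a curated starter (114 generics across the 22
  categories), override-able via `--lexicon-dir`/`load_lexicons(dir)`; it is
  the mechanism, not an exhaustive formulary.
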