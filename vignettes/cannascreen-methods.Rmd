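---
title: "Methods: screening clinical notes for cannabis-use documentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening clinical notes for cannabis-use documentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannascreen)
```

## The problem

Cannabis use in pediatric and young-adult patients is documented, when it is
documented at all, inside unstructured clinical notes: social-history blurbs,
toxicology reports, medication lists, counseling summaries. The terms are
heterogeneous (marijuana, cannabis, THC, CBD, weed, MJ, prescription
cannabinoids such as dronabinol), frequently misspelled, and two of them are
systematically ambiguous — *CBD* is also the common bile duct and *weed* is
also a plant allergen. Notes for very young children mention cannabis almost
exclusively as household or prenatal exposure rather than patient use.
`cannascreen` implements a staged pipeline that turns a raw note corpus into
patient-level cannabis-use status, yearly trend tables, a diagnostic-code
cross-check, and adjusted-odds-ratio disparity estimates.

## Lexicon and misspelling expansion

The dictionary starts from seed keywords (marijuana, cannabis, cbd, weed,
thc, mj) and medically prescribed cannabinoid terms (tetrahydrocannabinol,
epidiolex, cannabidiol, marinol, dronabinol, syndros, cesamet), all
overridable through a YAML/JSON config. Misspellings observed in the corpus
are attached automatically: every distinct word token is profiled as a
*combined* character n-gram count vector over gram lengths 1–3, and the
cosine similarity

$$\mathrm{sim}(A, B) = \frac{A \cdot B}{|A|\,|B|}$$

against each seed's profile is compared with a per-seed threshold
(default 0.70). The combined vector — all gram lengths concatenated into one
space, raw counts rather than binary presence, lowercase before profiling —
is load-bearing: it is the construction under which the canonical example
pair (*marijuana*, *marijuahana*) scores 0.90; averaging per-length cosines
does not reproduce that value and was rejected.

```{r}
round(ngram_cosine(char_ngram_profile("Marijuana"),
                   char_ngram_profile("Marijuahana")), 2)
```

Three choices here were genuinely open and are worth recording:

* **Short seeds are not expanded.** n-gram cosine on 2–3 letter tokens (mj,
  thc, cbd) is promiscuous — nearly any token sharing two letters clears a
  0.70 threshold — so seeds shorter than 4 characters are excluded from
  expansion by default (`min_seed_nchar`).
* **Collisions go to the most similar seed**, ties broken by lexicographic
  order, so the expansion map is a function (each variant has exactly one
  canonical seed) and deterministic.
* **Thresholds are per-seed** with a single default of 0.70, the only value
  with external support; nothing in the method requires them to be equal.

## Screening, context exclusion, age filter

Terms are matched case-insensitively at token boundaries (so *seaweed* never
hits *weed*), longest term first when matches overlap. *MJ* is special-cased:
it only counts when uppercase in the source or followed by a colon (a
template field like `MJ: +`), which suppresses initials.

Exclusions operate at note level, in a fixed order: keyword match → context
exclusion → age filter → sentence extraction, and a note that fails an early
stage never reaches a later one.

* A note whose **only** matched seed is *cbd* and which contains bile-duct
  vocabulary (gallbladder, pancreas, abdominal, ...) is excluded; likewise
  *weed*-only notes with allergy vocabulary (pollen, allergy, allergens,
  ...). Any unambiguous seed rescues the note: context exclusion never
  discards a note that also says *marijuana*.
* Patients younger than 7 years at the note date are excluded
  (`excluded_underage`); the boundary is inclusive at exactly 7.0 years with
  age computed as days/365.25. This reflects the observation that
  cannabis mentions for very young children almost always describe household
  or in-utero exposure, not patient use. Whether the rule should drop the
  note or the whole patient is ambiguous in principle; it is implemented at
  note-date level, which is the weaker and safer reading.

Sentence extraction keeps exactly the keyword-bearing sentences, which
become the classifier's input. The splitter is deliberately rule-based and
deterministic (no model download): boundaries are sentence-final punctuation
followed by whitespace, vetoed after clinical abbreviations (Dr., prn, Hx,
...) and inside dosage strings such as `MARINOL(2.5MG/TAB`, which contain
periods but no post-period whitespace.

## Sentence classification

The unit of classification is one sentence; a note is positive if any of its
sentences is positive, and a patient is positive if any note is. (A config
switch to concatenate a note's hit sentences into one input exists, but
per-sentence is the default because it is directly testable against
sentence-level fixtures.)

Two backends satisfy the same contract:

* **Rule baseline** (`rule_based_label`): deterministic, negation-aware cue
  scoping in the NegEx tradition. Priority order: toxicology-positive
  patterns (scoped to the end of the clause) beat everything, including an
  earlier denial in the same sentence; counseling/discussion cues and
  third-party attribution (mother, brother, household, in utero) are
  negative unless a patient-anchored affirmation is present; otherwise a
  negation cue earlier in the clause scopes forward over the whole clause —
  "denied smoking marijuana" is negative even though *smoking* sits between
  the denial and the term — and an un-negated preceding affirmation is
  positive. A bare mention with no cue is negative: a mention is
  documentation, not endorsement.
* **Trained baseline** (`train_classifier`): ridge-penalized logistic
  regression (glmnet, fixed penalty, deterministic) on word unigram+bigram
  counts. This is a desk-scale stand-in for heavier contextual encoders; any
  model exposing the same train/predict contract can be plugged in. No class
  re-weighting is applied although the documented class balance is ~73%
  positive — the imbalance is informative, not an artifact.

Splits are assigned by note, not by sentence, so sentences from one note
never straddle train/test. Metrics are confusion-matrix based with AUROC by
the Mann–Whitney rank statistic with midrank tie correction; the decision
threshold defaults to 0.5.

## Cohort aggregation and trends

Patient status is a three-way partition: *positive* (any positive sentence),
*negative_documented* (screened-in note but no positive sentence),
*undocumented*. First-positive date is the earliest note date with a
positive sentence, and age at first positive uses days/365.25. Trend tables
report per-year documentation and positivity percentages over all notes and
over OSM (orthopedic/sports-medicine) notes with OSM-only denominators; new
positive patients count once, in the year of first positivity; the mean age
of new positives carries a t-interval (the 95% CI method is otherwise
unspecified upstream, and the t-interval is the standard choice).

Diagnostic-code cross-checking matches ICD codes by prefix through the dot
hierarchy (F12.20 extends F12; dots are stripped before comparison) and
SNOMED CT codes exactly — the code lists are flat, so no ontology traversal
is attempted. The headline statistic is the share of NLP-positive patients
who also carry a cannabis diagnosis code, rounded to one decimal.

## Disparity models

Two settings mirror the two cohort contrasts: documentation (any
documentation vs. none) and positive use (positive vs. a comparator). The
positive-use comparator defaults to *all* non-positive patients, with a flag
for documented-negatives only; both conventions are defensible and the
package reports whichever is requested, labeled.

The default fit is a fixed-effects logistic GLM: at one row per patient
there are no repeated measures, so a random effect has nothing to group by
and the fixed-effects model is the identifiable choice. A
`glmm_random_intercept` method (lme4) is available when a genuine clustering
column (e.g. clinic site) is supplied. Results are exponentiated
coefficients with Wald 95% CIs and p-values; references are male (sex) and
white (race); SVI is rescaled ×100 so the reported aOR is per 0.01 index
units; rows with missing SVI are dropped and counted. No multiple-testing
correction is applied — raw p-values are reported, documented as such.
Separation is flagged (not repaired) when a Wald SE explodes.

A sensitivity filter (`exclude_medical_cannabis`) reassigns patients whose
only positive evidence is a prescription-cannabinoid sentence in an RX
context, approximating a "medical cannabis excluded" reanalysis; the exact
upstream exclusion rule is not public, so this approximation is documented
as the package's own.

## The synthetic generator: what it emulates and what it does not

`generate_cohort()` plants everything the pipeline is supposed to recover:

* demographics (52.6% female; race mix with 55.9% white; SVI ~
  Beta(0.63, 1.69) matching mean 0.27, SD 0.24),
* per-note documentation from a logistic model (baseline 2% at reference
  covariates; planted odds ratios per covariate; step increases in
  documentation odds at the 2012 and 2016 cutover years emulating
  legalization effects; yearly note volumes growing 5%/year),
* conditional positivity at 73% baseline among documented notes,
* template-rendered sentences for nine note classes (affirmation, denial,
  toxicology positive/negative, prescription cannabinoid, counseling,
  family/household use, bile-duct confounder, allergy confounder) embedded
  in orthopedic-flavored filler text,
* a 5% misspelling-injection rate (one random duplication, transposition, or
  vowel insertion; short tokens only get duplications so that every injected
  variant remains recognizably similar to its source),
* cannabis diagnosis codes for 14.5% of positive patients.

Template choice is parameterized as two normalized weight maps (one over
positive templates, one over negative templates) plus confounder rates over
undocumented notes, rather than a single joint map over all nine classes:
documentation and positivity are drawn from the planted logistic models
*first*, and a joint template map would conflate template style with the
planted class balance, making the odds ratios unrecoverable by
construction.

Gold records per note carry the true status, the injected terms and
misspellings, and the planted probabilities, which is what lets tests assert
recall and filter soundness exactly and trend recovery within binomial
bounds. Generation is byte-identical under a fixed seed.

What the generator does **not** emulate: discourse-level context (sarcasm,
history-of sections, copy-forward), section structure, OCR noise,
patient-identifying text, or realistic vocabulary breadth. Passing tests on
synthetic corpora therefore demonstrate that the pipeline's logic is
internally correct under its stated assumptions — not that the rule
classifier would reach any particular accuracy on real hospital notes,
where template diversity is far larger.

## Numerical and testing choices

* Test problem sizes: the corpus-level property tests use a 5,000-patient
  corpus (~30k notes), parameter recovery uses 20,000 patients, and the null
  type-I simulation uses 200 replicates at n = 2,000 — sizes at which the
  binomial/Wald tolerances being asserted are decisive rather than vacuous.
* Trend recovery is asserted per year against planted rates with 95%
  binomial bounds; since 22 years × 2 curves are 44 simultaneous intervals,
  up to 2 excursions per curve are tolerated a priori (the nominal miss rate
  of a 95% interval), rather than widening the bounds.
* The screening recall property is asserted over *detectable* notes: an
  injected misspelling the lexicon declined to accept (similarity below
  threshold) is unfindable by construction and is reported separately
  rather than counted against recall.
* Degenerate inputs: empty vocabularies expand to nothing; single-class
  training sets and all-one-outcome designs are errors; zero-variance
  covariates are dropped with a warning; a one-class gold set yields NA
  AUROC with a warning while the other metrics are returned.

## Known limitations

The rule classifier's cue lists are English, template-oriented, and tuned to
the fixture phrasings of this problem domain; the trained baseline is a
linear n-gram model, not a contextual encoder; exclusion vocabularies ship
with conservative defaults and real deployments should extend them from
local data. The diagnosis codebook covers the cannabis families only
(F12, T40.7, 305.2, 304.3, four SNOMED concepts) and makes no attempt at
general ontology mapping.
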