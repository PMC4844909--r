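---
title: "Methods: annotation, preannotation, and agreement analysis for pharmacokinetic DDI corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, preannotation, and agreement analysis for pharmacokinetic DDI corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddikit)
```

## The problem

Structured product labels (SPLs) describe potential pharmacokinetic
drug–drug interactions (PDDIs) in free text. Building computable PDDI
resources therefore requires annotated corpora: typed drug mentions and
claim-level PDDI annotations over label sections, produced by human
curators, possibly assisted by NLP preannotation, and scored against an
expert reference standard. `pddikit` implements the full computational
scaffolding of such an annotation study: the data model and its JSON
interchange, a transparent rule-based preannotation pipeline, the
span-overlap matching rule with per-label precision/recall/F1, the
three-way user/NLP/reference agreement cross-tabulation, length-balanced
scenario assignment, and a synthetic corpus plus annotator simulator so
that every downstream computation can be exercised and audited without
human participants or proprietary label text.

## The annotation model

A corpus is a set of label sections (`label_section`), each with a
canonical sentence segmentation computed once at load time. Annotations
come in two types:

* **Drug mentions** — a character span typed as *active ingredient*,
  *metabolite*, or *drug product*, carrying a lexicon concept id and a
  normalized ingredient id. A drug product with a known sole active
  ingredient is normalized to that ingredient, mirroring
  terminology-driven postprocessing; unmappable products keep their own
  id and are flagged.
* **PDDI mentions** — a claim anchored to one or more sentences (not
  necessarily contiguous, since annotators may select several
  sentences), linking a *precipitant* (the drug that causes the
  pharmacokinetic change) and an *object* drug, with a *statement* type
  (quantitative: a magnitude is given; qualitative: direction only) and
  a *modality* (positive: the interaction is asserted; negative: it is
  explicitly denied).

Character offsets are 0-based and half-open throughout; sentence
identity is by index into the section's canonical segmentation, so sets
from different sources are comparable exactly when they annotate the
same loaded corpus — which the pipeline guarantees by segmenting once at
corpus load. Serialization is Open-Annotation-inspired JSON (a target
with a position selector and exact quote, plus a typed body; see
`pddikit_extdata("annotation-schema.json")`), deliberately not full
JSON-LD: the interchange needs to be auditable and round-trippable, not
context-resolvable. Unknown body keys survive round trips in a
pass-through slot.

## Sentence segmentation

Segmentation is deterministic and rule-based: a sentence ends at `.`,
`!`, or `?` followed by whitespace or end of text, unless the period
closes a token on a packaged abbreviation list (`e.g.`, `i.v.`, …).
Periods inside tokens (decimal numbers, "2.5-fold") are never
boundaries. This is intentionally simple: label-section prose is
terse, and a deterministic segmenter makes sentence indices a stable
anchor for PDDI mentions across annotation sources.

## The preannotation pipeline

The pipeline (`run_pipeline()`) is a deterministic, auditable stand-in
for an NLP preannotation service, built from three steps:

1. **Dictionary NER** (`annotate_drug_mentions()`): case-insensitive,
   token-boundary-anchored, longest-leftmost matching of lexicon names
   and synonyms. Token boundaries treat hyphens and digits as word
   characters because drug names contain both. Entries typed
   `non_drug` are matched (so they can shadow shorter drug names) and
   then filtered out — the dictionary-then-filter design of broad
   terminology annotators. Products are normalized to sole active
   ingredients by exact case-insensitive name identity.
2. **Sentence-level PDDI classification**
   (`extract_pddi_mentions()`): a sentence window (size 1 by default,
   configurable to 2) is a PDDI candidate iff at least two distinct
   normalized ingredients co-occur with at least one pharmacokinetic
   cue term from a packaged, editable cue lexicon (`AUC`, `clearance`,
   `inhibit…`, …). Modality is negative iff a negation phrase from a
   packaged list scopes the window ("no effect", "did not", …);
   statement is quantitative iff a numeric magnitude (percent, fold,
   ratio) occurs.
3. **Role assignment**: for each drug pair (ordered by first
   occurrence), a passive frame between the drugs ("… was increased
   by X") makes the *second* drug the precipitant; otherwise a
   causative verb between them ("X increased … Y") makes the *first*
   the precipitant; otherwise the first drug is the precipitant. The
   fallback is explicit policy, flagged per mention in its
   pass-through slot, because role assignment is undecidable for
   cue-only sentences.

These frames are this package's own formalization — the rule system is
a transparent surrogate for machine-learned classifiers whose internals
are not reproducible here, and its published operating points appear in
this package only as *simulation parameters* for the synthetic NLP
(below), never as claims about the rule system itself.

## Matching and metrics

A candidate PDDI mention is a true positive against a reference mention
iff precipitant, object (both after ingredient normalization), and
modality all agree, and the sentence sets partially or exactly overlap.
The statement type is deliberately not part of the criterion. Matching
is one-to-one per section: candidates and references are processed in
(first sentence index, precipitant id) order and paired by augmenting
paths. This yields the deterministic first-come pairing whenever that
pairing is maximal, and a maximum one-to-one matching always — the
greedy order alone can strand a pairable candidate when non-contiguous
sentence selections interleave, and a matcher that loses attainable
true positives to processing order would understate annotator
performance. The matcher is validated in the test suite against an
exhaustive bitmask-DP maximum-matching oracle.

Metrics are computed **by label** (per product-label section — the
annotation unit) and then macro-averaged per scenario, unweighted.
Undefined metrics are excluded rather than coerced: a label with no
reference and no candidate mentions is dropped entirely; a label with
reference mentions but no candidates contributes recall 0 but no
precision; F1 exists only where both precision and recall do and
P + R > 0. This avoids arbitrary 0/0 conventions while keeping every
defined quantity in the averages.

All printed rounding is half-up (`round_half_up()`): half-up to two
decimals for means, one decimal for percentages, with integral
percentages printed without a trailing ".0" — matching the number
formatting conventions of published agreement tables (59/151 prints as
39.1, 93/93 as 100).

## The agreement cross-tabulation

`build_agreement()` classifies every reference mention by whether the
NLP and the user each found it (four cells summing to the number of
reference mentions), then splits the NLP false-positive pool by whether
the user's set contains a mention matching the NLP mention (accepted vs
rejected), reusing the single matching rule everywhere. User mentions
matching neither reference nor NLP pool are user-invented false
positives; that cell has no natural denominator and is reported as a
bare count. The analysis is typically restricted to the scenario in
which users actually saw PDDI preannotations.

## Study design utilities

`assign_scenarios()` distributes sections across scenarios (including a
training holdout) balanced by a two-class length stratification
(short/long at the median section length): each stratum is allocated
across scenarios by largest-remainder apportionment and dealt
round-robin in length order with a seeded tie-break shuffle. Sizes are
exact; each scenario's long/short composition is within one section of
perfect balance. The default sizes are 3 training plus 52/52/53/48 for
a 208-section corpus, scaled proportionally otherwise. The
second unassisted scenario exists only as a labelled split (a
learning-effect check); no longitudinal statistic is computed for it.
`summarize_usability()` and `tally_time_categories()` compute the
margin means of a participants-by-scenario ratings grid and the
task-time contingency table; the package ships the published ratings
and time reports as plain-TSV encodings so this arithmetic is
reproducible to the printed digit.

## The synthetic study generator

`generate_corpus()` emulates everything the evaluation design assumes,
from templated prose up to simulated annotators:

* **Corpus composition.** Defaults are calibrated once to the
  composition of the reference-standard corpus this design targets:
  2–4 PDDI statements per section (so a 205-section corpus carries
  about 607), and per-section Poisson rates for extra
  active-ingredient, drug-product, and metabolite mentions derived
  from the reference totals 3351/234/201 over 205 sections. Negative
  modality and quantitative statements are planted at configurable
  probabilities (defaults 0.15 and 0.5 — labels deny interactions far
  less often than they assert them, and magnitudes accompany roughly
  half of the assertions; neither proportion is published, so these
  are the package's own choices, fixed here).
* **Rule-grammar text.** PDDI sentences are drawn from templates that
  exactly instantiate the extractor's cue, frame, negation, and
  magnitude rules, so with noise rates at their defaults of zero the
  pipeline provably attains precision = recall = 1 against the
  planted truth — the corpus is a *verification instrument*, not a
  simulation of real prose. Two noise channels degrade it
  controllably: paraphrased PDDI sentences outside the rule grammar
  (recall noise) and cue-bearing two-drug distractors (precision
  noise).
* **Simulated NLP.** Each reference mention is emitted with
  probability equal to the planted sentence-level recall (default
  0.81); false positives are drawn from planted two-drug non-PDDI
  sentences so that expected precision equals the planted value
  (default 0.86). The sentence-level pair is used rather than the
  document-level one because the simulated errors are sentence
  events; both are configurable.
* **Simulated annotators.** Four rates — fix an NLP miss, drop an NLP
  hit, accept an NLP false positive, invent a mention — chosen as the
  minimal behavioural model whose cell expectations are exactly the
  agreement table's proportions. Defaults are calibrated to the
  published behaviour of the strongest nonexpert annotator (63/109,
  11/42, 5/93, ~0.3 per section). Unassisted mode reuses the fix rate
  as base sensitivity rather than adding a fifth parameter
  (overridable). Every mention's fate is recorded in a ground-truth
  ledger, and `build_agreement()` must reproduce the ledger
  aggregation *exactly* — an end-to-end identity, not a statistical
  check.

What the generator does **not** emulate: real SPL prose style (tables,
enumerations, cross-references), ambiguous or discontinuous drug
mentions, disagreements about sentence boundaries, and annotator
behaviour that depends on section difficulty or fatigue. Passing tests
on synthetic corpora therefore demonstrate the correctness of the
bookkeeping, matching, and metric machinery and the recoverability of
planted parameters — not the real-world accuracy of the rule-based
extractor.

## Numerical and implementation choices

* Rounding is half-up with a `1e-9` guard absorbing binary
  representation error at decimal halves.
* `is_match()` over differing sections returns `FALSE` by contract
  (not an error), so cross-section comparisons are simply never pairs.
* Duplicate PDDI mentions (same section, drugs, modality, statement,
  and sentence set) are invalid within one annotation set; near
  duplicates are legal and consume distinct reference mentions under
  one-to-one matching.
* Random draws are scoped with `withr::with_seed()`, so identical
  configurations give byte-identical outputs and library calls never
  perturb the caller's RNG state.
* Test problem sizes: matching is verified exhaustively on enumerated
  families and on random instances up to 8×8 mentions per section
  against the DP oracle; parameter recovery uses a 1700-section corpus
  (≈5100 planted mentions), where three binomial standard errors bound
  the planted-vs-recovered gap at about ±1.7 percentage points for
  recall; ledger identity and pipeline perfection are checked at the
  canonical 208-section size.

## Limitations

The rule-based extractor is a transparent surrogate, not a
reimplementation of any published classifier; its real-text behaviour
is untested here and its published-looking operating points come from
simulation parameters. The lexicon emulates terminology relations with
flat TSV files and handles only sole-active-ingredient products.
Agreement is reported as raw cross-tabulations; chance-corrected
coefficients are out of scope. The "overall" row printed in some
published summaries of this study design is not the unweighted mean of
the scenario values and its weighting is unstated, so this package
computes overall metrics only as the unweighted mean over labels and
makes no claim of matching such rows.
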