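---
title: "Methods: annotation–survey concordance for forum-derived quality-of-life data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation–survey concordance for forum-derived quality-of-life data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolforum)
```

## The problem and the data model

qolforum quantifies how much of a patient's questionnaire-measured quality
of life (QoL) can be recovered from what they write in an online health
forum. The setting pairs two data sources per user: one EORTC QLQ-C30 +
QLQ-BR23 response set (53 ordinal items — items 1–28 and 31–53 on 4-level
scales, the global items 29–30 on 7-level scales) taken on a known survey
date, and a history of forum posts and comments. Trained coders mark text
spans with the questionnaire item they answer, a polarity ("positive" = the
issue is reported present, "negative" = reported absent), and an
exact-match flag; whole documents additionally carry a past-reference flag
and a flag for posts about someone other than the author.

Four tibbles (documents, annotations, flags, surveys) form a validated
`qol_corpus`. Span offsets are 0-based, half-open, counted in Unicode code
points — the usual standoff-annotation convention, chosen so that offsets
are language- and encoding-stable and a round trip through the JSONL files
is byte-exact. Timestamps are dates: all temporal logic operates in months
relative to a user's survey date, so sub-day resolution adds nothing.
An optional coverage table records which annotator read which document;
without it, full coverage is assumed.

## Inter-annotator agreement

Agreement is computed per question with Fleiss' κ, which assumes a fixed
number of raters assigning items to categories. Two unitizations are
supported:

* **word units**: every whitespace-delimited token of every in-scope
  document is an item; a rater labels the token iff one of their spans for
  the question overlaps it by at least one code point;
* **document units**: each document is one item, labeled iff the rater
  placed any span for the question in it.

Polarity and exact-match are deliberately ignored here: agreement is about
*where the label applies*. Three numerical choices deserve note.
Tokenization splits on Unicode whitespace with punctuation left attached —
reproducible and dialect-free, at the cost of counting "pain!" and "pain"
as different surface tokens (irrelevant for agreement, which never compares
token strings). The overlap rule gives credit for partial span overlap,
consistent with span-based annotation where boundary placement is itself
noisy; exact-boundary agreement would conflate boundary jitter with label
disagreement. Finally, when every rating falls into a single category
(e.g. a question nobody ever labeled), 1 − P̄ₑ = 0 and κ is formally
undefined although observed agreement is perfect; we return 1 with a
`degenerate` flag rather than NaN, and summaries report means both over all
questions and restricted to questions with at least one labeled document.
Negative κ values are reported as computed, never clamped.

Because Fleiss' formula requires a constant rater count per item, κ is
computed per homogeneous stratum: the API takes an explicit panel and
excludes (with a warning count) documents not covered by the full panel.
This mirrors a design where the recent months are triple-annotated and
older material double-annotated. `agreement_table()` uses a vectorized
one-pass implementation; the test suite checks it to 1e-12 against the
explicit `unitize()` + `fleiss_kappa()` route, and checks `fleiss_kappa()`
itself to 1e-10 against an independently coded brute-force transcription of
the 1971 formulas.

## Concordance between annotations and survey answers

Both sides are reduced to a binary "issue present / absent" scheme. For
4-level items, "not at all" maps to negative and the other three categories
to positive. The 7-level global items have no published binarization; we
take answers at or below the scale midpoint (4) as positive/impaired. The
threshold is configurable (`seven_level_threshold`), and any monotone
choice is defensible given how rarely global-health text is annotated; the
midpoint is simply the symmetric default.

A *comparison* pairs a predicted label (from annotations) with the actual
label (binarized survey answer of the same user and question). Two levels
are first-class because both readings of "how often is the post right?"
are legitimate: at **annotation level** every span is one comparison, so
frequently-mentioned issues weigh more; at **user level** each (user,
question) pair contributes once, the prediction being the majority polarity
with ties broken toward positive (the annotation schema is presence-biased:
the unmarked base label asserts presence). A user with no labeled data for
a question contributes nothing for that question.

Counts pool into TP/FP/TN/FN per question, per fine group (the 23
scoring-manual scales), per coarse group (functional / symptomatic /
global) or overall. Grouping is micro-pooling of raw counts — totals are
conserved under every partition, which the tests assert — rather than
re-binarizing at group level, so a group's F1 is the F1 of its pooled
mentions. Precision and recall are undefined (NA, excluded from averages
and reported as blanks) when their denominators vanish; F1 is computed as
2TP/(2TP+FP+FN), which equals the harmonic mean whenever both components
are defined and is 0 when there are errors but no true positives.
Mean/SD summaries across questions or users are unweighted arithmetic means
and sample (n−1) standard deviations.

Temporal filtering keeps documents within `months` of the posting user's
own survey date (calendar-month arithmetic with day clamping) and can
additionally drop past-referenced documents, aligning forum content with
the questionnaire's one-week recall window. The window is anchored on the
survey date — the one date the data model guarantees per user.

## EORTC scale scoring

Scales coincide with the fine groups. With RS the mean of answered items
and `range = n_levels − 1`, reversed scales score `(1 − (RS−1)/range)·100`
and unreversed ones `((RS−1)/range)·100`. All functional scales are
reversed except sexual functioning and sexual enjoyment, whose items are
worded so a higher answer already means better functioning — the scoring
manual's convention, encoded per scale in `eortc_scales()$reversed`. A
scale is missing unless at least half its items (rounded up) are answered;
with fully-complete surveys the rule is only exercised by partial synthetic
input, but it is implemented and tested exhaustively over answered-item
counts.

## What the synthetic cohort emulates

Study data of this kind are private, so the generator is a first-class
module rather than a fixture. It encodes the statistical structure the
analysis assumes — a static latent binary state per user and question
driving both sides:

* **Cohort shape**: 123 posting users plus 11 survey-only users; per-user
  document counts drawn log-uniformly within long-tail activity bins
  (weights 6 : 28 : 63 : 22 : 4 from a single user up to a few hundred
  documents over the 24-month period); ~5% initial posts vs comments;
  timestamps uniform over the period. At these defaults a cohort has
  roughly 2,500–3,100 documents.
* **Mention process**: only present issues are mentioned; the per-document
  mention probability profile is dominated by a general "ill or unwell"
  fallback label (0.16) followed by worry, pain, tension and a thin 0.005
  tail, with three intimate-topic questions never mentioned. With 0.5
  prevalence this yields a labeled-document fraction around one quarter to
  one third, and a top-label share several times the median — the regime
  the analysis is designed for.
* **Noise**: a mention's polarity matches the latent state with
  consistency *c* (default 0.85); survey answers contradict the state with
  probability *s* (default 0.05), drawn uniformly within the positive
  (2–4) or negative (1) answer range, and symmetrically around the
  midpoint for the 7-level items. Three annotators (span recall 0.90 /
  0.85 / 0.80, 3% polarity flips, ±1 token boundary jitter, 0.01 false
  spans per document) cover the most recent 6 months; the first two cover
  the older stratum. 10% of documents are past-referenced, 0.5% are about
  another subject.

Because mentions arise only from present issues, true "I have no pain"
statements occur only via consistency failures; real forums contain
genuine negated reports, so simulated true-negative cells are sparser than
real ones. Text is assembled from per-question template sentences plus
fillers — span offsets are exact and word unitization meaningful, but
nothing about real language (ambiguity, the vagueness that drives real
annotator disagreement) is modeled. Latent states are static over the
period, so the generator cannot express the drift that temporal filtering
addresses in real data; passing tests therefore demonstrate correctness of
the *pipeline arithmetic* under the assumed model, not robustness to real
linguistic or temporal variation.

With no annotator polarity noise, annotation-level accuracy has the closed
form `c(1−s) + (1−c)s` (`expected_accuracy()`), independent of prevalence
and mention rates — both polarity and binarized answer are independent
coin-flips around the same latent bit. The test suite recovers *c* ∈
{0.6, 0.75, 0.9} to within ±0.03 from cohorts of 150 users (≥5,000
annotation-level comparisons) and checks the noisy closed form the same
way; the noiseless limit (c = 1, s = 0, no annotator noise) must give
F1 = 1 for every defined key at every granularity.

## Problem sizes and reproducibility

All randomness flows through one seeded generator with the caller's RNG
state restored afterwards; identical configurations reproduce corpora and
report bundles byte for byte (the manifest deliberately contains no
timestamps). Unit tests run on corpora of 10–60 users; recovery tests use
150 users; the end-to-end report runs at the default 123-user scale. The
full suite completes in well under a minute on a single CPU, and
`scripts/acceptance.R` in about fifteen seconds.

## Known limitations

* The generator's conditional answer distributions (uniform within the
  positive range) are a modeling choice, not an estimate of any patient
  population.
* Per-document flags treat past-reference and other-subject as document
  properties; a document mixing current and past statements cannot be
  split.
* Fleiss κ per homogeneous panel cannot combine the 2- and 3-annotator
  strata into one statistic; the package reports them separately by design.
* Group-level concordance is micro-pooled; an alternative (re-binarizing a
  user's group state before comparison) is out of scope.
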