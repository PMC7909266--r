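---
title: "Scoring the informativeness of picture-description speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the informativeness of picture-description speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuscore)
```

## The measurement model

`cuscore` quantifies how much picture-relevant content a speaker conveys
per unit of speech. The unit of analysis is the *utterance*, defined at the
token level: every verbalization attempt — a real word, a filler, a false
start, an unrecognizable word — counts exactly once. This definition is
deliberate: healthy adults describing a picnic scene produce on the order
of 150 such attempts in under a minute, so token-level counting is the only
reading consistent with the group means the measure was designed around,
and the atypical-speech proportions are defined over words as well.

Content is measured against a *content-unit (CU) lexicon*: 64 concepts,
each defined by the variant phrases controls used for it, each produced by
at least three of 31 controls. Two counting schemes are implemented:

* **original** — each CU scores at most once per sample, regardless of how
  many times or with which description it is mentioned, and absent CUs are
  not penalized;
* **unique-referent** — the 12 CUs whose surface forms are ambiguous
  between picture entities (e.g. "fellow": the reading man, the running
  boy, or the fisherman) are subdivided by referent, so re-using a word for
  a *different* entity scores a new identity. Referent resolution requires
  the coder's context judgment, so it is read from explicit `[CU45:a]`
  annotation tags; all untagged mentions of one ambiguous CU collapse into
  a single "referent unknown" identity rather than being guessed. A
  consequence worth stating: the unique-referent count can never be smaller
  than the original count.

The headline statistic is **informativeness** — raw CU count divided by
total utterances — a content-efficiency measure robust to sample length.

## Matching: deterministic surface lexicon, not semantics

Human coders recognize concepts; the package approximates them with an
exact variant list plus a deterministic inflection table (plural `-s/-es`,
`-ing`, `-ed`, with e-drop and consonant doubling). Matching is greedy
longest-match left-to-right over normalized tokens (lowercased,
punctuation-stripped except apostrophes), capped at 4-token phrases.
Stored variants always beat inflected expansions; an inflected form two CUs
would both generate is dropped as ambiguous. False-start fragments and
unrecognizable tokens never participate in matches. Printed variants with
disambiguating parentheticals ("caught (a fish)") match on the head phrase;
two editorial corrections to the packaged table ("Nasket" → "basket";
"(Man's) glasses" stored as the full phrase because the bare head would
collide with the drinking-glass CU) are recorded in
`inst/extdata/lexicon_provenance.txt`.

Matches inside tangential or self-referential spans still count (nothing in
the coding scheme excludes content produced inside a tangent), and
corrected phonemic errors (`{splanket→blanket}`) are matchable as the
intended word: the approach deliberately ignores form errors.

## Atypical speech

Five categories of task-irrelevant output are scored as word-level
proportions of total utterances: self-referential statements, statements
about inability to do the task, tangential statements, empty speech
(fillers, unrecognizable words, stock phrases) and false starts. Annotation
spans are authoritative. In the default `rules+annotation` mode,
unannotated tokens are labeled by rule with fixed precedence
annotation > false start > empty > inability cue; the precedence for tokens
that qualify twice (a filler inside a self-referential span) is the
package's own convention, documented here because no published rule exists.
Self-referential and tangential speech get *no* rule: the published
examples ("Maybe an investor in a sailboat company") require pragmatic
judgment, so rules would be unverifiable. A first-person-pronoun heuristic
is available (`first_person_heuristic()`) but reported separately.
Inter-rater reliability is simple percent agreement over tokens (identical
presence and category); Cohen's kappa is offered as an extra, clearly
labeled statistic.

## Group statistics

The analysis plan for a four-group design (svPPA, lvPPA, nfvPPA, HC):

* one-way ANOVA on raw CU counts and informativeness — from raw scores
  (`anova_oneway()`, delegating to `stats::aov`) or from per-group
  summary statistics (`anova_from_summary()`), the latter so printed
  tables can be re-analyzed; the two agree to numerical precision on raw
  data, which the test suite asserts at 1e-10;
* pooled-variance pairwise t-tests at Bonferroni-adjusted alpha
  (0.05/6 ≈ 0.0083, displayed 0.008; compared unrounded). The pooled
  (Student) test matches the pooled-SD convention of the effect size;
  Welch is available behind a flag;
* Hedges' g with the small-sample correction J = 1 − 3/(4N − 9), reference
  group (HC) first, so deficits on higher-is-better measures are positive;
* impairment flags: a participant is impaired when informativeness falls
  strictly below the control mean − 1.96 control SDs. This is a
  normal-range interval over the HC *distribution*, one-sided because only
  deficits are abnormal here. A confidence interval of the mean would be
  ~5 times narrower and would flag nearly every patient, which contradicts
  the observed handful of impaired cases per group; a value exactly at the
  bound is not impaired.

With the published original-method group summaries as input, the package
reproduces the printed effect sizes to within input rounding (HC vs nfvPPA
g = 1.286 vs printed 1.28; HC vs svPPA 2.470 vs 2.47; HC vs lvPPA 2.237 vs
2.25; informativeness HC vs nfvPPA −0.286 vs −0.29) and the group effect on
raw CUs, F(3, 97) = 35.97 from 3-significant-figure inputs against the
printed 36.2 computed from unrounded data. Two printed informativeness
effect sizes (lvPPA 1.75, svPPA 1.69) are *not* reproducible from the
printed summaries by the standard formula (which yields ≈1.67 and ≈1.60);
the package reports what the formula gives and does not treat those cells
as reference values.

## The synthetic cohort generator

The clinical transcripts are not publicly available, so the package
validates itself on synthetic cohorts with known ground truth. Defaults
encode the study conditions: group sizes 19/26/25/31; utterance counts
drawn from truncated normals (≥ 10 tokens) with means 135, 135, 97.1, 150
and SDs 53.6, 60.3, 34.1, 65.9 for svPPA, lvPPA, nfvPPA, HC; per-participant
informativeness drawn from truncated normals (clamped to [0, 1]) with the
original-scheme group means 11.1%, 11.7%, 23.1%, 20.9% and SDs 6.46, 5.18,
9.45, 5.67 percentage points. Each participant plants
`C = round(p · U)` distinct CUs (random variant phrases), fills the
remaining budget with tagged atypical spans and distractor words, and
records the ground truth.

Design notes:

* Utterance count and informativeness are drawn independently; the CU count
  is derived. The generator therefore targets the utterance and
  informativeness moments, not the raw-CU moments (a ratio of means is not
  a mean of ratios). Informativeness is the headline measure, so it gets
  the calibration.
* The distractor vocabulary is screened at load time against every lexicon
  variant and inflected form and against the filler/cue phrase lists; a
  collision is an error. Combined with the lexicon's token-level
  prefix-freeness, this guarantees the pipeline recovers the planted CU
  count *exactly* for every synthetic participant — the strongest available
  end-to-end oracle — and the test suite asserts 100% recovery on a full
  cohort.
* Atypical rates per group are *qualitative* settings (no printed values
  exist): svPPA leads on self-referential (0.08) and inability (0.06)
  content, lvPPA on empty speech (0.15) and false starts (0.07), nfvPPA
  tracks controls. They encode the published ordering and are free
  parameters of the generator, stated in `default_cohort_config()`.
* A fixed seed yields a byte-identical corpus; infeasible draws (more
  planted tokens than the utterance budget) shrink the atypical targets,
  then the variant lengths, then C, and the *realized* values are what the
  truth table records.

What passing synthetic tests do **not** show: real aphasic speech has
syntax, disfluency structure, coreference and semantic errors the generator
does not model; exact recovery demonstrates the scoring machinery is
correct, not that lexicon coverage of real transcripts is complete.
Recovered group means match configured means within sampling error
(2 standard errors at the study's group sizes), not exactly.

## Numerical and convention choices

* Token spans and annotation spans are 0-based, half-open, everywhere.
* A zero-utterance transcript has *undefined* informativeness and atypical
  proportions — scoring raises an error rather than emitting 0.
* The impairment bound uses a strict inequality; ties are unimpaired.
* Matching ties (same start, different lengths) resolve to the longest
  phrase; the brute-force oracle in the test suite enumerates every
  candidate window and resolves leftmost-then-longest, and must agree
  exactly with the greedy scanner.
* Every token counts once toward the denominator, including fillers inside
  false starts (the conventions do not state a double-count rule).
* The unique-referent expansion of the packaged lexicon yields 46
  sub-identities over 12 subdivided CUs, a net gain of 34 scoreable
  concepts over the original 64 (reported by `expand_uniqueref()`); the
  companion "referent unknown" fallback per subdivided CU is a scoring
  convenience, not a new concept. Published prose cites a nearby figure
  (35 additional); the package encodes the table as printed and reports
  its own arithmetic.
* Problem sizes in the test suite: full 101-participant cohorts for the
  end-to-end checks, 200 random ≤30-token transcripts for the matcher
  oracle, 100 random datasets for the ANOVA equivalence, 20 seeds at
  n ∈ {10, 31, 100} for the generator-consistency check.

## Limitations

The lexicon is stimulus-specific: user lexicons for other pictures load
through the same TSV/JSON dialect, but none is packaged. Matching is
surface-based and will miss circumlocutions a human coder would credit.
Referent disambiguation relies on annotation; the optional context
heuristics stay off by default. Cohesion and pragmatics of discourse are
out of scope.
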