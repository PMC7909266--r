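# cuscore

Content-unit scoring and informativeness analysis of naturalistic,
picture-elicited speech, for clinical speech-language research in primary
progressive aphasia (PPA) and related disorders.

## The problem

Connected-speech samples (e.g. descriptions of the WAB-R "Picnic Scene")
capture functional communication better than constrained naming or
repetition tasks, but scoring them by hand is slow and conventions vary.
`cuscore` implements a complete, deterministic pipeline for the
content-unit (CU) approach:

- **Content units.** A CU is a unique picture-relevant concept, defined by
  the set of verbal descriptions healthy controls used for it ("dog",
  "puppy" → one concept). The package ships a 64-CU lexicon for a
  picnic-scene stimulus, each CU produced by at least 3 of 31 controls, with
  referent sub-units for the 12 CUs whose surface forms are ambiguous
  between picture entities. Form-based errors (mispronunciations, unusual
  word choice, grammatical errors) are never penalized.
- **Two coding schemes.** The *original* scheme counts each CU at most once
  per sample. The *unique-referent* scheme additionally splits an ambiguous
  CU when the same word refers to a different entity (tagged
  `fellow[CU45:a] … fellow[CU45:d]` counts twice).
- **Informativeness.** The normalized content-efficiency measure
  `informativeness = raw CU count / total utterances`, where an *utterance*
  is any verbalization attempt at the token level: real words, fillers
  ("um", "uh"), false starts (`&spl-`) and unrecognizable words (`xxx`) all
  count once in the denominator.
- **Atypical speech.** Word-level classification of five task-irrelevant
  categories — self-referential, inability, tangential, empty speech, false
  starts — as proportions of total utterances, with annotation spans
  authoritative and mechanical rules for the convention-driven categories,
  plus word-level percent agreement between raters.
- **Group statistics.** Per-group summaries; one-way ANOVA from raw scores
  or **from printed summary statistics** (n, mean, SD per group):
  `F = [Σ nᵢ(mᵢ − m̄)² / (k−1)] / [Σ (nᵢ−1)sᵢ² / (N−k)]`;
  pooled-variance pairwise t-tests at a Bonferroni-adjusted alpha
  (0.05/6 ≈ 0.008 for four groups); Hedges' g with the small-sample
  correction `g = J (m_a − m_b)/s_p`, `J = 1 − 3/(4N − 9)`; and
  normal-range impairment flags (below the control mean − 1.96 SD).
- **Synthetic cohorts.** A seeded generator emulating the four study groups
  (19 svPPA, 26 lvPPA, 25 nfvPPA, 31 HC) with configurable utterance-count
  and informativeness distributions and known ground truth, so the whole
  pipeline is testable without patient data (the clinical transcripts are
  not public).

## Worked example

```r
library(cuscore)
lex <- load_lexicon(cu_lexicon_path())
#> <cu_lexicon> 64 parent CUs, 205 variant phrases, 46 referent sub-units

lines <- c("um the {spoy→boy} is run- running",
           "<in> i am not sure what that is </in>",
           "a fellow[CU45:d] fishing on the dock")
dir <- tempfile(); dir.create(dir)
writeLines(lines, file.path(dir, "p01.txt"))
manifest <- data.frame(participant_id = "p01", group = "lvPPA")

t <- parse_transcript(file.path(dir, "p01.txt"), manifest)
score_participant(t, lex)
#>   participant_id group total_utterances raw_cu_original raw_cu_uniqueref
#> 1            p01 lvPPA               19               5                5
#>   informativeness_original informativeness_uniqueref
#> 1                0.2631579                 0.2631579
```

The 19 utterances include the filler `um`, the false start `run-` and the
corrected phonemic error `{spoy→boy}` (scored as the intended word `boy`).
Five CUs are detected (`boy`, `running`, `fellow` tagged to the fisherman
referent, `fishing`, `dock`), giving informativeness 5/19 ≈ 0.26; the
`<in>…</in>` span contributes 7 tokens to the inability proportion.

Group statistics work directly from printed summary tables:

```r
rs <- reference_summaries("raw_cu", "original")
anova_from_summary(rs)
#> One-way ANOVA: F(3, 97) = 35.972, p = 1.024e-15
hedges_g(rs[rs$group == "HC", ], rs[rs$group == "svPPA", ])
#> [1] 2.470454
```

A full synthetic study, end to end:

```r
cohort <- run_simulate(tempdir(), seed = 1)            # 101 transcripts
scores <- run_score(cohort$dir, cohort$manifest_path, "out")
run_analyze(file.path("out", "scores.csv"), "reports", method = "both")
```

A thin command-line wrapper with the same subcommands (`score`, `analyze`,
`simulate`, `validate-lexicon`) is installed at `inst/cli/cuscore.R`.

## Scope

The package scores transcripts; it does not transcribe audio, align
speakers, or resolve coreference. Judgment-heavy atypical categories
(self-referential, tangential) are taken from annotations, not guessed by
rules. See the methods vignette (`vignettes/informativeness-scoring.Rmd`)
for the model, parameter choices and limitations.
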