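# a reduced configuration (same distributional parameters, fewer
# participants) keeps the unit tests fast; the full default cohort is
# exercised by the acceptance suite
small_config <- function(seed = 1L, n = 4L) {
  cfg <- default_cohort_config(seed)
  cfg$profiles <- lapply(cfg$profiles, function(p) { p$n <- n; p })
  cfg
}

test_that("the distractor vocabulary never collides with the lexicon", {
  lex <- pkg_lexicon()
  vocab <- distractor_vocabulary(lex)
  expect_gt(length(vocab), 50L)
  lex_tokens <- unique(unlist(strsplit(lex$match_table$phrase, " ")))
  expect_length(intersect(vocab, lex_tokens), 0L)
  for (w in vocab) expect_identical(lookup_variant(lex, w), NA_integer_)
})

test_that("a fixed seed yields a byte-identical corpus; seeds differ corpora", {
  d1 <- tempfile("c1_"); d2 <- tempfile("c2_"); d3 <- tempfile("c3_")
  c1 <- generate_cohort(small_config(seed = 7L, n = 2L), d1)
  c2 <- generate_cohort(small_config(seed = 7L, n = 2L), d2)
  c3 <- generate_cohort(small_config(seed = 8L, n = 2L), d3)
  f1 <- sort(list.files(d1, pattern = "\\.txt$"))
  expect_identical(f1, sort(list.files(d2, pattern = "\\.txt$")))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$truth, c3$truth))
})

test_that("the default configuration encodes the four-group study design", {
  cfg <- default_cohort_config()
  groups <- vapply(cfg$profiles, function(p) p$group, character(1))
  ns <- vapply(cfg$profiles, function(p) p$n, integer(1))
  expect_setequal(groups, c("svPPA", "lvPPA", "nfvPPA", "HC"))
  expect_identical(sum(ns), 101L)
  expect_identical(ns[match(c("svPPA", "lvPPA", "nfvPPA", "HC"), groups)],
                   c(19L, 26L, 25L, 31L))
})

test_that("zero atypical rates yield transcripts of CU phrases and distractors only", {
  lex <- pkg_lexicon()
  prof <- group_profile("HC", 5, 120, 30, 0.2, 0.05,
                        c(self_referential = 0, inability = 0,
                          tangential = 0, empty = 0, false_start = 0))
  set.seed(3)
  gp <- generate_participant(prof, lex, "clean1")
  t <- make_transcript(gp$lines, pid = "clean1")
  expect_true(all(t$tokens$kind == "word"))
  expect_identical(nrow(t$annotations[t$annotations$label != "referent_tag", ]),
                   0L)
  expect_true(all(classify_atypical(t)$counts == 0L))
})

test_that("the pipeline recovers the generated ground truth exactly", {
  cfg <- small_config(seed = 11L, n = 5L)
  cohort <- generate_cohort(cfg, tempfile("rc_"))
  rc <- recovery_check(cohort, cfg)
  expect_true(rc$checks[["exact_cu_recovery"]])
  expect_true(rc$checks[["utterance_identity"]])
  expect_true(rc$checks[["uniqueref_ordering"]])
  # per-participant: the scored original CU count equals the planted count
  merged <- merge(rc$scores, cohort$truth, by = "participant_id")
  expect_identical(merged$raw_cu_original, merged$cu_count)
  expect_identical(merged$total_utterances, merged$utterances)
  # atypical token counts are recovered too (annotation + rules)
  for (cat in c("self_referential", "inability", "tangential", "empty",
                "false_start")) {
    expect_equal(merged[[paste0("prop_", cat)]],
                 merged[[paste0("n_", cat)]] / merged$utterances)
  }
})

test_that("recovered group means concentrate around configured values as n grows", {
  lex <- pkg_lexicon()
  vocab <- distractor_vocabulary(lex)
  prof_of <- function(n) group_profile("HC", n, 150, 65.9, 0.209, 0.0567,
                                       c(empty = 0.05, false_start = 0.01))
  mad_at_n <- function(n, seeds) {
    devs <- vapply(seeds, function(s) {
      set.seed(s)
      p <- prof_of(n)
      inf <- vapply(seq_len(n), function(i) {
        generate_participant(p, lex, paste0("x", i), vocab)$truth$informativeness_true
      }, numeric(1))
      abs(mean(inf) - 0.209)
    }, numeric(1))
    mean(devs)
  }
  seeds <- 101:120
  mads <- c(mad_at_n(10, seeds), mad_at_n(31, seeds), mad_at_n(100, seeds))
  # consistency: the mean absolute deviation shrinks from n=10 to n=100
  expect_lt(mads[3], mads[1])
  expect_lt(mads[2], mads[1] * 1.5)
})
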