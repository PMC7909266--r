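test_that("matching finds content units by greedy longest match", {
  lex <- pkg_lexicon()
  t <- make_transcript("the man is fishing on the dock")
  m <- match_cus(t, lex)
  expect_setequal(m$cu_id, c(43L, 33L, 13L))

  # different descriptions of the same concept both match it
  t2 <- make_transcript(c("a dog chased the kite", "the puppy was happy"))
  m2 <- match_cus(t2, lex)
  expect_identical(sum(m2$cu_id == 4L), 2L)

  # excluded token kinds never participate
  t3 <- make_transcript("&fi- xxx")
  expect_identical(nrow(match_cus(t3, lex)), 0L)

  # multi-token variants beat their single-token sub-parts
  t4 <- make_transcript("he built a sandcastle today")
  m4 <- match_cus(t4, lex)
  expect_identical(m4$cu_id, 35L)
  expect_identical(m4$end - m4$start, 3L)
})

test_that("original scheme counts each CU once, with no absence penalty", {
  lex <- pkg_lexicon()
  t <- make_transcript("a dog and the puppy")
  m <- match_cus(t, lex)
  expect_identical(raw_cu_count_original(m), 1L)
  expect_identical(raw_cu_count_original(m[0, ]), 0L)
  # upper bound: one mention of every CU
  one_each <- vapply(split(lex$variants, lex$variants$cu_id),
                     function(v) v$phrase[which.min(v$n_tokens)], character(1))
  lines <- vapply(split(one_each, ceiling(seq_along(one_each) / 1L)),
                  paste, character(1), collapse = " ")
  t64 <- make_transcript(lines)
  expect_identical(raw_cu_count_original(match_cus(t64, lex)), 64L)
})

test_that("unique-referent scheme splits tagged mentions and collapses untagged ones", {
  lex <- pkg_lexicon()
  tagged <- make_transcript("the fellow[CU45:a] and another fellow[CU45:d]")
  m <- match_cus(tagged, lex)
  expect_identical(raw_cu_count_uniqueref(m, tagged, lex), 2L)
  expect_identical(raw_cu_count_original(m), 1L)

  untagged <- make_transcript("the fellow and another fellow")
  mu <- match_cus(untagged, lex)
  expect_identical(raw_cu_count_uniqueref(mu, untagged, lex), 1L)

  # unambiguous-only transcripts agree across schemes
  plain <- make_transcript("the dog chased the kite near the sailboat")
  mp <- match_cus(plain, lex)
  expect_identical(raw_cu_count_uniqueref(mp, plain, lex),
                   raw_cu_count_original(mp))

  # a tag naming a foreign sub-unit is a coding error
  bad <- make_transcript("the fellow[CU45:z]")
  mb <- match_cus(bad, lex)
  expect_error(raw_cu_count_uniqueref(mb, bad, lex), "coding error")
})

test_that("informativeness is raw CUs per utterance and undefined at zero", {
  expect_identical(informativeness(15L, 100L), 0.15)
  expect_identical(informativeness(0L, 50L), 0)
  expect_identical(informativeness(15L, 100L, as = "percent"), 15)
  expect_error(informativeness(3L, 0L), "undefined")
})

test_that("score_participant reproduces a hand-computed worked example", {
  lex <- pkg_lexicon()
  t <- make_transcript(c(
    "they are sitting on a {splanket→blanket}",
    "&sp- &spl- blanket",
    "xxx",
    "um the boy is run- running",
    "the man is fishing on the dock",
    "<sr> I hate fish I do not eat fish </sr>",
    "a fellow[CU45:a] and another fellow[CU45:d]"))
  s <- score_participant(t, lex)
  # hand application of the lexicon: sitting=52, blanket=25 (twice), boy=11,
  # running=51, man=43, fishing=33, dock=13, fish=20 (twice), fellow=45
  # (twice, tagged 45a and 45d) over 36 verbalization attempts
  expect_identical(s$total_utterances, 36L)
  expect_identical(s$raw_cu_original, 9L)
  expect_identical(s$raw_cu_uniqueref, 10L)
  expect_equal(s$informativeness_original, 9 / 36)
  expect_equal(s$informativeness_uniqueref, 10 / 36)
  expect_equal(s$prop_self_referential, 8 / 36)
  expect_equal(s$prop_false_start, 3 / 36)
  expect_equal(s$prop_empty, 2 / 36)

  expect_error(score_participant(make_transcript(character(0)), lex),
               "zero utterances")
  fill <- score_participant(make_transcript("um uh er"), lex)
  expect_identical(fill$raw_cu_original, 0L)
  expect_identical(fill$informativeness_original, 0)
})

test_that("scoring is deterministic, order-insensitive and scheme-ordered", {
  lex <- pkg_lexicon()
  set.seed(21)
  for (i in 1:25) {
    t <- random_transcript(lex, n_tokens = sample(10:60, 1))
    if (nrow(t$tokens) == 0L) next
    s1 <- score_participant(t, lex)
    s2 <- score_participant(t, lex)
    expect_identical(s1, s2)
    m <- match_cus(t, lex)
    expect_lte(raw_cu_count_original(m), max(nrow(m), 0L))
    expect_lte(raw_cu_count_original(m), 64L)
    expect_gte(s1$raw_cu_uniqueref, s1$raw_cu_original)
    # shuffling whole lines leaves the de-duplicated counts unchanged
    lines <- write_transcript(t)
    perm <- make_transcript(sample(lines))
    sp <- score_participant(perm, lex)
    expect_identical(sp$raw_cu_original, s1$raw_cu_original)
    expect_identical(sp$raw_cu_uniqueref, s1$raw_cu_uniqueref)
  }
})

test_that("greedy matcher agrees with the brute-force oracle on small inputs", {
  lex <- pkg_lexicon()
  set.seed(33)
  for (i in 1:50) {
    t <- random_transcript(lex, n_tokens = sample(3:30, 1))
    got <- match_cus(t, lex)[c("start", "end", "cu_id")]
    want <- brute_match(t, lex)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})
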