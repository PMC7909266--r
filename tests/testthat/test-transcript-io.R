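test_that("tokenize splits on whitespace, strips punctuation, flags fillers", {
  tk <- tokenize("Uh no, yeah I guess")
  expect_identical(nrow(tk), 5L)
  expect_identical(tk$kind[1], "filler")
  expect_identical(tk$normalized, c("uh", "no", "yeah", "i", "guess"))
  expect_identical(tk$index, 0:4)

  expect_identical(nrow(tokenize("")), 0L)

  tk2 <- tokenize("um, uh")
  expect_identical(tk2$kind, c("filler", "filler"))

  # apostrophes are kept, other punctuation is not
  tk3 <- tokenize("can't see; the T-shirt!")
  expect_identical(tk3$normalized, c("can't", "see", "the", "tshirt"))

  # the filler bigram marks both tokens
  tk4 <- tokenize("well you know really")
  expect_identical(tk4$kind, c("word", "filler", "filler", "word"))
})

test_that("phonemic-error corrections transcribe the intended word", {
  t <- make_transcript("they are sitting on a {splanket→blanket}")
  expect_identical(nrow(t$tokens), 6L)
  expect_identical(t$tokens$normalized[6], "blanket")
  expect_identical(t$tokens$surface[6], "{splanket→blanket}")
  # ASCII arrow accepted too
  t2 <- make_transcript("a {wog->dog}")
  expect_identical(t2$tokens$normalized[2], "dog")
})

test_that("false-start markers and unrecognizable words get their kinds", {
  t <- make_transcript("&sp- &spl- blanket")
  expect_identical(t$tokens$kind,
                   c("false_start_fragment", "false_start_fragment", "word"))
  t2 <- make_transcript("xxx")
  expect_identical(t2$tokens$kind, "unrecognizable")
  t3 <- make_transcript("run- running")
  expect_identical(t3$tokens$kind, c("false_start_fragment", "word"))
})

test_that("every token of any kind counts once toward total utterances", {
  t <- make_transcript("um the boy is run- running")
  expect_identical(count_total_utterances(t), 6L)
  empty <- make_transcript(character(0))
  expect_identical(count_total_utterances(empty), 0L)
  # definitional property over random transcripts
  set.seed(11)
  for (i in 1:20) {
    t <- random_transcript(pkg_lexicon(), n_tokens = sample(5:40, 1))
    expect_identical(count_total_utterances(t), nrow(t$tokens))
  }
})

test_that("annotation spans and referent tags parse with 0-based half-open coordinates", {
  t <- make_transcript(c("<sr> I hate fish </sr> but <em> um uh </em>",
                         "the boy[CU48:a] ran"))
  ann <- t$annotations
  expect_identical(ann$label,
                   c("self_referential", "empty", "referent_tag"))
  expect_identical(ann$start, c(0L, 4L, 7L))
  expect_identical(ann$end, c(3L, 6L, 8L))
  expect_identical(ann$payload[3], "48a")
})

test_that("malformed input raises named parse errors", {
  expect_error(make_transcript("<sr> never closed"), "unclosed")
  expect_error(make_transcript(c("fine line", "bad </tg> close")), "line 2")
  expect_error(make_transcript("<bogus> word </bogus>"), "unknown tag")
  # participant must be in the manifest
  dir <- tempfile(); dir.create(dir)
  p <- file.path(dir, "ghost.txt"); writeLines("hello", p)
  expect_error(
    parse_transcript(p, data.frame(participant_id = "p1", group = "HC")),
    "unknown participant")
  expect_error(
    read_manifest(data.frame(participant_id = "p1", group = "Martian")),
    "unknown group")
})

test_that("serialization round-trips transcripts through the file grammar", {
  lines <- c("they are sitting on a {splanket→blanket}",
             "<sr> I hate fish I don't eat fish </sr>",
             "um the fellow[CU45:a] is fishing",
             "&bl- &bla- xxx <em> uh </em>")
  t <- make_transcript(lines)
  t2 <- make_transcript(write_transcript(t))
  expect_identical(t2$tokens, t$tokens)
  expect_identical(t2$annotations, t$annotations)
  # idempotence of the canonical form
  expect_identical(write_transcript(t2), write_transcript(t))
  # random transcripts round-trip too
  set.seed(7)
  for (i in 1:10) {
    r <- random_transcript(pkg_lexicon(), n_tokens = 25)
    r2 <- make_transcript(write_transcript(r))
    expect_identical(r2$tokens, r$tokens)
    expect_identical(r2$annotations, r$annotations)
  }
})
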