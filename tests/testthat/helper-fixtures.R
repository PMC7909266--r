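# Shared fixtures: the packaged lexicon (loaded once per test run), a
# writer/parser shortcut for in-code transcripts, a random-transcript
# generator for property tests, and a brute-force CU matcher that serves as
# the independent oracle for match_cus().

pkg_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_lexicon(cu_lexicon_path())
    cache
  }
})

# write `lines` to a temp file and parse it as participant `pid` of `group`
make_transcript <- function(lines, pid = "p1", group = "HC") {
  dir <- tempfile("tr_")
  dir.create(dir)
  path <- file.path(dir, paste0(pid, ".txt"))
  writeLines(lines, path, useBytes = TRUE)
  parse_transcript(path, data.frame(participant_id = pid, group = group,
                                    stringsAsFactors = FALSE))
}

# a small mixed token pool for random transcripts: lexicon variants (single
# and multi token), out-of-lexicon words, fillers, markers
random_transcript <- function(lex, n_tokens = 30L, pid = "r1",
                              group = "HC") {
  singles <- lex$variants$phrase[lex$variants$n_tokens == 1L]
  multis <- lex$variants$phrase[lex$variants$n_tokens > 1L]
  pool <- list()
  n <- 0L
  while (n < n_tokens) {
    r <- runif(1)
    piece <- if (r < 0.35) {
      sample(singles, 1L)
    } else if (r < 0.45) {
      sample(multis, 1L)
    } else if (r < 0.75) {
      sample(c("the", "and", "there", "it", "they", "zebra", "walrus",
               "quux", "blorp"), 1L)
    } else if (r < 0.85) {
      sample(c("um", "uh", "er"), 1L)
    } else if (r < 0.95) {
      paste0("&", paste(sample(letters, 2L), collapse = ""), "-")
    } else {
      "xxx"
    }
    k <- length(strsplit(piece, " ", fixed = TRUE)[[1]])
    if (n + k > n_tokens) break
    pool[[length(pool) + 1L]] <- piece
    n <- n + k
  }
  words <- unlist(pool)
  nl <- max(1L, length(words) %/% 8L)
  lines <- vapply(split(words, ceiling(seq_along(words) / 8L)),
                  paste, character(1), collapse = " ")
  make_transcript(lines, pid = pid, group = group)
}

# Independent oracle: enumerate every contiguous window of <= max_len
# matchable tokens, test it with the plain total lookup, then resolve
# overlaps leftmost-start-then-longest. Shares no scanning logic with
# match_cus().
brute_match <- function(t, lex, max_len = 4L) {
  toks <- t$tokens
  n <- nrow(toks)
  ok <- toks$kind %in% c("word", "filler") & nzchar(toks$normalized)
  cand <- list()
  for (i in seq_len(n)) {
    for (len in seq_len(min(max_len, n - i + 1L))) {
      j <- i + len - 1L
      if (!all(ok[i:j])) next
      cu <- lookup_variant(lex, toks$normalized[i:j])
      if (!is.na(cu)) {
        cand[[length(cand) + 1L]] <-
          data.frame(start = i - 1L, end = j, cu_id = cu, len = len)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      cu_id = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -cand$len), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    span <- (cand$start[k] + 1L):cand$end[k]
    if (!any(taken[span])) {
      keep[k] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, c("start", "end", "cu_id")]
  rownames(out) <- NULL
  out
}
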