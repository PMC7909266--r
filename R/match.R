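# CU detection and scoring. Matching is surface-lexicon-based: greedy
# longest-match, left to right, over normalized tokens, with a hard cap of
# 4 tokens per phrase. False-start fragments and unrecognizable words never
# participate in matches; filler tokens may (no lexicon phrase contains one,
# so in practice they never match).

MATCHABLE_KINDS <- c("word", "filler")

#' Detect content-unit mentions in a transcript
#'
#' Scans the normalized token sequence left to right; at each position the
#' longest lexicon phrase (stored variant or inflected form, up to 4 tokens)
#' starting there is taken and its tokens are consumed, so overlapping
#' candidates resolve longest-then-leftmost. Tokens of kind
#' `false_start_fragment` or `unrecognizable` cannot start or occur inside a
#' match.
#'
#' @param t a `ppa_transcript`.
#' @param lex a `cu_lexicon`.
#' @param max_len maximum phrase length in tokens (default 4).
#' @return data.frame of matches: `start`, `end` (0-based half-open token
#'   span), `cu_id`, `phrase`.
#' @export
match_cus <- function(t, lex, max_len = 4L) {
  stopifnot(inherits(t, "ppa_transcript"), inherits(lex, "cu_lexicon"))
  toks <- t$tokens
  n <- nrow(toks)
  empty <- data.frame(start = integer(0), end = integer(0),
                      cu_id = integer(0), phrase = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ok <- toks$kind %in% MATCHABLE_KINDS & nzchar(toks$normalized)
  norm <- toks$normalized
  tab <- lex$match_table
  tab <- tab[order(!tab$exact), , drop = FALSE]  # exact phrases win lookups
  dict <- tab$cu_id
  names(dict) <- tab$phrase
  dict <- dict[!duplicated(names(dict))]
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      j <- i + len - 1L
      if (!all(ok[i:j])) next
      phrase <- paste(norm[i:j], collapse = " ")
      cu <- dict[phrase]
      if (!is.na(cu)) {
        out[[length(out) + 1L]] <- data.frame(
          start = toks$index[i], end = toks$index[j] + 1L,
          cu_id = unname(cu), phrase = phrase, stringsAsFactors = FALSE)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Raw CU count under the original coding scheme
#'
#' Each CU counts at most once per sample, no matter how many times or with
#' how many different verbal descriptions it is mentioned; absent CUs incur
#' no penalty.
#'
#' @param matches data.frame from [match_cus()].
#' @return integer count of distinct CUs.
#' @export
raw_cu_count_original <- function(matches) {
  length(unique(matches$cu_id))
}

#' Raw CU count under the unique-referent coding scheme
#'
#' For subdivided CUs the scoreable identity is `(cu_id, sub_id)`, where the
#' sub id comes from a `[CUnn:x]` referent tag covering the matched tokens;
#' untagged mentions of one subdivided CU all collapse into a single
#' `(cu_id, unknown)` identity (the coder's context judgment is not guessed).
#' Non-subdivided CUs count as in the original scheme, so the unique-referent
#' count is always greater than or equal to the original count.
#'
#' @param matches data.frame from [match_cus()].
#' @param t the `ppa_transcript` the matches came from (source of referent
#'   tags).
#' @param lex a `cu_lexicon`.
#' @return integer count of distinct scoreable identities.
#' @export
raw_cu_count_uniqueref <- function(matches, t, lex) {
  stopifnot(inherits(t, "ppa_transcript"), inherits(lex, "cu_lexicon"))
  if (nrow(matches) == 0L) return(0L)
  subdivided <- unique(lex$subunits$cu_id)
  refs <- t$annotations[t$annotations$label == "referent_tag", , drop = FALSE]
  identities <- character(nrow(matches))
  for (k in seq_len(nrow(matches))) {
    cu <- matches$cu_id[k]
    if (!cu %in% subdivided) {
      identities[k] <- as.character(cu)
      next
    }
    cover <- refs[refs$start >= matches$start[k] & refs$start < matches$end[k], ,
                  drop = FALSE]
    cover <- cover[grepl(paste0("^", cu, "[a-z]"), cover$payload), , drop = FALSE]
    if (nrow(cover) == 0L) {
      identities[k] <- paste0(cu, ":unknown")
    } else {
      sid <- cover$payload[1]
      valid <- lex$subunits$sub_id[lex$subunits$cu_id == cu]
      if (!sid %in% valid) {
        stop("coding error: referent tag '", sid, "' names a sub-unit that ",
             "does not belong to CU ", cu)
      }
      identities[k] <- sid
    }
  }
  length(unique(identities))
}

#' Informativeness: raw CU count per utterance
#'
#' @param raw_cu integer raw CU count.
#' @param total_utterances positive integer; a zero denominator is an error
#'   (the score is undefined, not zero).
#' @param as `"proportion"` (default) or `"percent"`.
#' @return numeric scalar.
#' @export
informativeness <- function(raw_cu, total_utterances,
                            as = c("proportion", "percent")) {
  as <- match.arg(as)
  if (length(total_utterances) != 1L || is.na(total_utterances) ||
      total_utterances <= 0L) {
    stop("informativeness is undefined for a transcript with zero utterances")
  }
  p <- raw_cu / total_utterances
  if (as == "percent") 100 * p else p
}

#' Score one participant end to end
#'
#' Composes tokenization, CU matching under both coding schemes,
#' informativeness and the atypical-speech proportions into a single score
#' record. Deterministic for fixed inputs.
#'
#' @param t a `ppa_transcript`.
#' @param lex a `cu_lexicon`.
#' @param atypical_mode see [classify_atypical()].
#' @return an object of class `ppa_score`: a one-row data.frame with columns
#'   `participant_id`, `group`, `total_utterances`, `raw_cu_original`,
#'   `raw_cu_uniqueref`, `informativeness_original`,
#'   `informativeness_uniqueref` and one `prop_*` column per atypical
#'   category; the match table is attached as attribute `matches`.
#' @export
score_participant <- function(t, lex,
                              atypical_mode = c("rules+annotation",
                                                "annotation")) {
  atypical_mode <- match.arg(atypical_mode)
  total <- count_total_utterances(t)
  if (total == 0L) {
    stop("cannot score participant '", t$participant_id,
         "': transcript has zero utterances")
  }
  matches <- match_cus(t, lex)
  raw_orig <- raw_cu_count_original(matches)
  raw_uref <- raw_cu_count_uniqueref(matches, t, lex)
  prof <- classify_atypical(t, mode = atypical_mode)
  row <- data.frame(
    participant_id = t$participant_id,
    group = t$group,
    total_utterances = total,
    raw_cu_original = raw_orig,
    raw_cu_uniqueref = raw_uref,
    informativeness_original = informativeness(raw_orig, total),
    informativeness_uniqueref = informativeness(raw_uref, total),
    stringsAsFactors = FALSE
  )
  for (cat in names(prof$proportions)) {
    row[[paste0("prop_", cat)]] <- prof$proportions[[cat]]
  }
  attr(row, "matches") <- matches
  class(row) <- c("ppa_score", class(row))
  row
}

#' Score a set of transcripts
#'
#' @param paths character vector of transcript files, or a directory (all
#'   `.txt` files are scored).
#' @param manifest cohort manifest (path or data.frame).
#' @param lex a `cu_lexicon` (default: the packaged picnic-scene lexicon).
#' @param atypical_mode see [classify_atypical()].
#' @param skip_bad when `TRUE`, transcripts that fail to parse or score are
#'   skipped with a warning instead of aborting.
#' @return data.frame with one row per participant (see
#'   [score_participant()]), with the concatenated match audit attached as
#'   attribute `matches`.
#' @export
score_transcripts <- function(paths, manifest, lex = NULL,
                              atypical_mode = "rules+annotation",
                              skip_bad = FALSE) {
  if (is.null(lex)) lex <- load_lexicon(cu_lexicon_path())
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.txt$", full.names = TRUE))
  }
  missing <- paths[!file.exists(paths)]
  if (length(paths) == 0L || length(missing) > 0L) {
    stop("no transcript file(s) to score",
         if (length(missing) > 0L) paste0(": ", missing[1], " not found"))
  }
  manifest <- read_manifest(manifest)
  rows <- list()
  audits <- list()
  for (p in paths) {
    res <- tryCatch({
      t <- parse_transcript(p, manifest)
      score_participant(t, lex, atypical_mode = atypical_mode)
    }, error = function(e) {
      if (skip_bad) {
        warning("skipping ", basename(p), ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      } else {
        stop("failed on ", p, ": ", conditionMessage(e), call. = FALSE)
      }
    })
    if (!is.null(res)) {
      m <- attr(res, "matches")
      if (nrow(m) > 0L) m$participant_id <- res$participant_id
      audits[[length(audits) + 1L]] <- m
      attr(res, "matches") <- NULL
      class(res) <- "data.frame"
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) stop("no transcript could be scored")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "matches") <- do.call(rbind, audits)
  out
}
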