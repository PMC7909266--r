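# Classification of the five task-irrelevant speech categories:
#   self_referential, inability, tangential, empty, false_start.
# Annotation spans are authoritative. Rules can supplement them only where
# the category is mechanical: false starts and unrecognizable words are fixed
# by transcription convention, fillers and packaged phrase patterns define
# empty speech, and a cue-phrase list flags statements about inability.
# Self-referential and tangential speech require pragmatic judgment and are
# annotation-only (an optional first-person heuristic is reported separately,
# never merged).

ATYPICAL_CATEGORIES <- c("self_referential", "inability", "tangential",
                         "empty", "false_start")

#' Packaged inability cue phrases
#' @return character vector of normalized cue phrases.
#' @export
default_inability_cues <- function() {
  normalize_phrase(read_word_list(
    system.file("extdata", "inability_cues.txt", package = "cuscore")))
}

#' Packaged empty-speech phrase patterns
#' @return character vector of normalized phrases.
#' @export
default_empty_phrases <- function() {
  normalize_phrase(read_word_list(
    system.file("extdata", "empty_phrases.txt", package = "cuscore")))
}

# assign `label` to every currently unlabeled token span matching one of the
# normalized phrases (contiguous word/filler tokens)
apply_phrase_rules <- function(labels, toks, phrases, label) {
  if (length(phrases) == 0L || nrow(toks) == 0L) return(labels)
  plists <- strsplit(phrases, " ", fixed = TRUE)
  plists <- plists[order(-lengths(plists))]  # longest cue first
  n <- nrow(toks)
  for (p in plists) {
    len <- length(p)
    if (len > n) next
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (all(labels[i:j] == "none") &&
          all(toks$kind[i:j] %in% c("word", "filler")) &&
          all(toks$normalized[i:j] == p)) {
        labels[i:j] <- label
      }
    }
  }
  labels
}

#' Classify atypical speech token by token
#'
#' Every token receives at most one of the five category labels (or
#' `"none"`). Annotation spans are authoritative; in `"rules+annotation"`
#' mode, unannotated tokens are then labeled by rule with the fixed
#' precedence annotation > false start > empty > inability cue.
#' Self-referential and tangential tokens can only come from annotations.
#'
#' @param t a `ppa_transcript`.
#' @param mode `"rules+annotation"` (default) or `"annotation"` (annotation
#'   spans only).
#' @param inability_cues,empty_phrases normalized phrase lists; defaults are
#'   the packaged files.
#' @return an object of class `ppa_atypical`: `labels` (one per token),
#'   `counts` and `proportions` (named by category) and `total_utterances`.
#' @export
classify_atypical <- function(t, mode = c("rules+annotation", "annotation"),
                              inability_cues = default_inability_cues(),
                              empty_phrases = default_empty_phrases()) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "ppa_transcript"))
  toks <- t$tokens
  n <- nrow(toks)
  labels <- rep("none", n)

  spans <- t$annotations[t$annotations$label %in% ATYPICAL_CATEGORIES, ,
                         drop = FALSE]
  for (k in seq_len(nrow(spans))) {
    idx <- seq.int(spans$start[k] + 1L, spans$end[k])  # 1-based rows
    clash <- labels[idx] != "none" & labels[idx] != spans$label[k]
    if (any(clash)) {
      stop("coding error: overlapping annotation spans with different ",
           "labels ('", labels[idx][clash][1], "' vs '", spans$label[k],
           "') at token ", idx[clash][1] - 1L)
    }
    labels[idx] <- spans$label[k]
  }

  if (mode == "rules+annotation" && n > 0L) {
    free <- labels == "none"
    labels[free & toks$kind == "false_start_fragment"] <- "false_start"
    free <- labels == "none"
    labels[free & toks$kind %in% c("filler", "unrecognizable")] <- "empty"
    labels <- apply_phrase_rules(labels, toks, empty_phrases, "empty")
    labels <- apply_phrase_rules(labels, toks, inability_cues, "inability")
  }

  counts <- vapply(ATYPICAL_CATEGORIES, function(cat) sum(labels == cat),
                   integer(1))
  proportions <- atypical_proportions(counts, n)
  structure(
    list(labels = labels, counts = counts, proportions = proportions,
         total_utterances = n),
    class = "ppa_atypical"
  )
}

#' Normalize atypical category counts by total utterances
#'
#' @param counts named integer vector (one entry per category).
#' @param total_utterances positive integer; zero is an error (the
#'   proportions are undefined).
#' @return named numeric vector of proportions in \[0, 1\].
#' @export
atypical_proportions <- function(counts, total_utterances) {
  if (length(total_utterances) != 1L || is.na(total_utterances) ||
      total_utterances <= 0L) {
    stop("atypical proportions are undefined for zero total utterances")
  }
  counts / total_utterances
}

#' Word-level percent agreement between two raters
#'
#' A token counts as a match only when both raters agree on the presence of
#' a rating and on the category (`"none"` must match `"none"`).
#'
#' @param ratings_a,ratings_b character vectors of per-token labels over the
#'   same tokens.
#' @return agreement percentage in \[0, 100\].
#' @export
percent_agreement <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating sequences differ in length (", length(ratings_a), " vs ",
         length(ratings_b), ")")
  }
  if (length(ratings_a) == 0L) stop("cannot compute agreement over 0 tokens")
  100 * mean(as.character(ratings_a) == as.character(ratings_b))
}

#' Cohen's kappa for two raters (beyond simple percent agreement)
#'
#' Offered as an additional chance-corrected statistic; the study's reported
#' reliability is simple percent agreement, which [percent_agreement()]
#' implements.
#'
#' @inheritParams percent_agreement
#' @return kappa in \[-1, 1\].
#' @export
agreement_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating sequences differ in length")
  }
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  lev <- union(a, b)
  po <- mean(a == b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (isTRUE(all.equal(pe, 1))) return(1)
  (po - pe) / (1 - pe)
}

#' First-person-pronoun heuristic for self-referential speech
#'
#' Flags tokens whose normalized form is a first-person pronoun. This is a
#' screening aid reported separately from [classify_atypical()]: pragmatic
#' judgment (annotation) remains the only authoritative source of
#' self-referential labels.
#'
#' @param t a `ppa_transcript`.
#' @return logical vector, one element per token.
#' @export
first_person_heuristic <- function(t) {
  stopifnot(inherits(t, "ppa_transcript"))
  pron <- c("i", "i'm", "i've", "i'd", "i'll", "me", "my", "mine", "myself",
            "we", "we're", "we've", "our", "ours", "us", "ourselves")
  t$tokens$normalized %in% pron
}

#' Read a second-rater token rating file
#'
#' TSV with columns `index` (0-based token index) and `label`; tokens not
#' listed are `"none"`.
#'
#' @param path rating file.
#' @param n_tokens total token count of the transcript being rated.
#' @return character vector of per-token labels of length `n_tokens`.
#' @export
read_ratings <- function(path, n_tokens) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("index", "label") %in% names(d))) {
    stop("rating file must have columns 'index' and 'label'")
  }
  if (any(d$index < 0 | d$index >= n_tokens)) {
    stop("rating file indexes tokens outside the transcript")
  }
  bad <- setdiff(unique(d$label), c(ATYPICAL_CATEGORIES, "none"))
  if (length(bad) > 0L) {
    stop("unknown rating label(s): ", paste(bad, collapse = ", "))
  }
  labels <- rep("none", n_tokens)
  labels[d$index + 1L] <- d$label
  labels
}
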