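# Transcript parsing under the study's transcription conventions:
#   - one breath-group per line; blank lines and '#' comment lines ignored
#   - {heard->intended} (or a Unicode arrow) records a corrected phonemic
#     error; the intended word is what gets matched
#   - '&'-prefixed and/or '-'-suffixed tokens are false-start fragments
#   - 'xxx' is an unrecognizable word (counted as empty speech)
#   - inline span tags <sr> <in> <tg> <em> <fs> mark the five atypical
#     categories; [CU45:a] immediately after a token assigns a referent
#   - every token, of any kind, is one verbalization attempt ("utterance")

PPA_GROUPS <- c("svPPA", "lvPPA", "nfvPPA", "HC")

TAG_LABELS <- c(sr = "self_referential", `in` = "inability",
                tg = "tangential", em = "empty", fs = "false_start")

read_word_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Packaged filler-word list
#'
#' Filler tokens (including the bigram `"you know"`) count as verbalization
#' attempts and are classified as empty speech.
#'
#' @return character vector of normalized filler entries.
#' @export
default_fillers <- function() {
  normalize_phrase(read_word_list(
    system.file("extdata", "fillers.txt", package = "cuscore")))
}

# mark filler tokens in a token data.frame (single words and bigrams)
apply_fillers <- function(tokens, fillers) {
  if (nrow(tokens) == 0L) return(tokens)
  singles <- fillers[!grepl(" ", fillers)]
  bigrams <- strsplit(fillers[grepl(" ", fillers)], " ", fixed = TRUE)
  is_word <- tokens$kind == "word"
  tokens$kind[is_word & tokens$normalized %in% singles] <- "filler"
  if (length(bigrams) > 0L && nrow(tokens) >= 2L) {
    for (bg in bigrams) {
      for (i in seq_len(nrow(tokens) - 1L)) {
        if (tokens$kind[i] %in% c("word", "filler") &&
            tokens$kind[i + 1L] %in% c("word", "filler") &&
            tokens$index[i + 1L] == tokens$index[i] + 1L &&
            tokens$normalized[i] == bg[1] && tokens$normalized[i + 1L] == bg[2]) {
          tokens$kind[c(i, i + 1L)] <- "filler"
        }
      }
    }
  }
  tokens
}

# classify one raw whitespace token -> list(surface, normalized, kind) or NULL
classify_raw_token <- function(raw) {
  core <- sub("[,.!?;:\"()]+$", "", raw)
  m <- regmatches(core, regexec("^\\{([^}]*?)(?:→|->)([^}]*)\\}$", core))[[1]]
  if (length(m) == 3L) {
    norm <- normalize_word(m[3])
    if (!nzchar(norm)) return(NULL)
    return(list(surface = raw, normalized = norm, kind = "word"))
  }
  if (tolower(core) == "xxx") {
    return(list(surface = raw, normalized = "", kind = "unrecognizable"))
  }
  if (startsWith(core, "&") || endsWith(core, "-")) {
    return(list(surface = raw, normalized = normalize_word(core),
                kind = "false_start_fragment"))
  }
  norm <- normalize_word(raw)
  if (!nzchar(norm)) return(NULL)
  list(surface = raw, normalized = norm, kind = "word")
}

#' Tokenize one line of transcript text
#'
#' Whitespace-delimited tokens; punctuation other than apostrophes is
#' stripped from the normalized form; filler tokens are identified from the
#' packaged (or supplied) filler list; `&`-prefixed / `-`-suffixed tokens are
#' false-start fragments and `xxx` is an unrecognizable word.
#'
#' @param line a character scalar (no annotation tags).
#' @param fillers normalized filler entries, see [default_fillers()].
#' @return data.frame with columns `surface`, `normalized`, `kind`, `index`
#'   (0-based).
#' @export
tokenize <- function(line, fillers = default_fillers()) {
  raws <- strsplit(trimws(line), "\\s+")[[1]]
  raws <- raws[nzchar(raws)]
  toks <- Filter(Negate(is.null), lapply(raws, classify_raw_token))
  tokens <- if (length(toks) == 0L) {
    data.frame(surface = character(0), normalized = character(0),
               kind = character(0), index = integer(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      surface = vapply(toks, `[[`, "", "surface"),
      normalized = vapply(toks, `[[`, "", "normalized"),
      kind = vapply(toks, `[[`, "", "kind"),
      index = seq_along(toks) - 1L,
      stringsAsFactors = FALSE
    )
  }
  apply_fillers(tokens, fillers)
}

#' Read or validate a cohort manifest
#'
#' @param manifest a CSV path or a data.frame with columns `participant_id`
#'   and `group` (one of svPPA, lvPPA, nfvPPA, HC).
#' @return validated data.frame.
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                                colClasses = "character")
  }
  if (!all(c("participant_id", "group") %in% names(manifest))) {
    stop("manifest must have columns participant_id and group")
  }
  bad <- setdiff(unique(manifest$group), PPA_GROUPS)
  if (length(bad) > 0L) {
    stop("unknown group(s) in manifest: ", paste(bad, collapse = ", "),
         " (expected ", paste(PPA_GROUPS, collapse = ", "), ")")
  }
  if (anyDuplicated(manifest$participant_id)) {
    stop("duplicate participant_id in manifest")
  }
  manifest
}

#' Write a cohort manifest CSV
#' @param manifest data.frame with `participant_id`, `group`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[c("participant_id", "group")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a transcript file
#'
#' @param path transcript file; the participant id is the file name without
#'   extension.
#' @param manifest cohort manifest (path or data.frame) mapping participants
#'   to diagnostic groups.
#' @param fillers normalized filler entries.
#' @return an object of class `ppa_transcript`: `participant_id`, `group`,
#'   `tokens` (surface, normalized, kind, index, line) and `annotations`
#'   (start, end, label, payload; 0-based half-open token spans).
#' @export
parse_transcript <- function(path, manifest, fillers = default_fillers()) {
  manifest <- read_manifest(manifest)
  pid <- sub("\\.[^.]*$", "", basename(path))
  row <- manifest[manifest$participant_id == pid, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("unknown participant '", pid, "': not present in the manifest")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  parse_transcript_lines(lines, participant_id = pid, group = row$group[1],
                         fillers = fillers, file = path)
}

# core line parser (also used by the synthetic generator and the writer
# round-trip); lines are raw text including tags.
parse_transcript_lines <- function(lines, participant_id, group,
                                   fillers = default_fillers(), file = "") {
  tokens <- list()
  annotations <- list()
  open_spans <- list()   # label -> start index
  n_tok <- 0L
  content_line <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    content_line <- content_line + 1L
    padded <- gsub("(</?(?:sr|in|tg|em|fs)>)", " \\1 ", line)
    padded <- gsub("(\\[CU[0-9]+:[A-Za-z0-9]+\\])", " \\1 ", padded)
    items <- strsplit(trimws(padded), "\\s+")[[1]]
    for (item in items) {
      if (grepl("^<(sr|in|tg|em|fs)>$", item)) {
        tag <- sub("^<([a-z]+)>$", "\\1", item)
        if (!is.null(open_spans[[tag]])) {
          stop("parse error at line ", ln, if (nzchar(file)) paste0(" of ", file),
               ": tag <", tag, "> opened twice without closing")
        }
        open_spans[[tag]] <- n_tok
      } else if (grepl("^</(sr|in|tg|em|fs)>$", item)) {
        tag <- sub("^</([a-z]+)>$", "\\1", item)
        if (is.null(open_spans[[tag]])) {
          stop("parse error at line ", ln, if (nzchar(file)) paste0(" of ", file),
               ": closing tag </", tag, "> without an open tag")
        }
        start <- open_spans[[tag]]
        open_spans[[tag]] <- NULL
        if (n_tok > start) {
          annotations[[length(annotations) + 1L]] <- data.frame(
            start = start, end = n_tok, label = unname(TAG_LABELS[tag]),
            payload = "", stringsAsFactors = FALSE)
        }
      } else if (grepl("^\\[CU[0-9]+:[A-Za-z0-9]+\\]$", item)) {
        if (n_tok == 0L) {
          stop("parse error at line ", ln, if (nzchar(file)) paste0(" of ", file),
               ": referent tag ", item, " has no preceding token")
        }
        cu <- sub("^\\[CU([0-9]+):.*$", "\\1", item)
        sid <- sub("^\\[CU[0-9]+:([A-Za-z0-9]+)\\]$", "\\1", item)
        annotations[[length(annotations) + 1L]] <- data.frame(
          start = n_tok - 1L, end = n_tok, label = "referent_tag",
          payload = paste0(cu, sid), stringsAsFactors = FALSE)
      } else if (grepl("^</?[A-Za-z]+>$", item)) {
        stop("parse error at line ", ln, if (nzchar(file)) paste0(" of ", file),
             ": malformed or unknown tag ", item)
      } else {
        tk <- classify_raw_token(item)
        if (!is.null(tk)) {
          n_tok <- n_tok + 1L
          tk$index <- n_tok - 1L
          tk$line <- content_line
          tokens[[n_tok]] <- tk
        }
      }
    }
  }
  if (length(open_spans) > 0L) {
    stop("parse error", if (nzchar(file)) paste0(" in ", file),
         ": unclosed tag(s) <", paste(names(open_spans), collapse = ">, <"),
         "> at end of file")
  }
  tok_df <- if (length(tokens) == 0L) {
    data.frame(surface = character(0), normalized = character(0),
               kind = character(0), index = integer(0), line = integer(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      surface = vapply(tokens, `[[`, "", "surface"),
      normalized = vapply(tokens, `[[`, "", "normalized"),
      kind = vapply(tokens, `[[`, "", "kind"),
      index = vapply(tokens, `[[`, 0L, "index"),
      line = vapply(tokens, `[[`, 0L, "line"),
      stringsAsFactors = FALSE
    )
  }
  tok_df <- apply_fillers(tok_df, fillers)
  ann_df <- if (length(annotations) == 0L) {
    data.frame(start = integer(0), end = integer(0), label = character(0),
               payload = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, annotations)
  }
  structure(
    list(participant_id = participant_id, group = group,
         tokens = tok_df, annotations = ann_df),
    class = "ppa_transcript"
  )
}

#' Serialize a transcript back to its file grammar
#'
#' Re-emits one line per original breath group with span tags, referent tags
#' and corrected-word braces; `parse_transcript()` of the output yields an
#' identical transcript (canonical-form round trip).
#'
#' @param t a `ppa_transcript`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_transcript <- function(t, path = NULL) {
  stopifnot(inherits(t, "ppa_transcript"))
  toks <- t$tokens
  ann <- t$annotations
  spans <- ann[ann$label != "referent_tag", , drop = FALSE]
  refs <- ann[ann$label == "referent_tag", , drop = FALSE]
  label_to_tag <- stats::setNames(names(TAG_LABELS), TAG_LABELS)
  pieces <- character(0)
  lines_out <- character(0)
  cur_line <- if (nrow(toks) > 0L) toks$line[1] else 1L
  flush_line <- function() {
    if (length(pieces) > 0L) {
      lines_out <<- c(lines_out, paste(pieces, collapse = " "))
      pieces <<- character(0)
    }
  }
  for (i in seq_len(nrow(toks))) {
    if (toks$line[i] != cur_line) {
      flush_line()
      cur_line <- toks$line[i]
    }
    idx <- toks$index[i]
    opens <- spans[spans$start == idx, , drop = FALSE]
    for (j in seq_len(nrow(opens))) {
      pieces <- c(pieces, paste0("<", label_to_tag[opens$label[j]], ">"))
    }
    pieces <- c(pieces, toks$surface[i])
    rtag <- refs[refs$start == idx, , drop = FALSE]
    for (j in seq_len(nrow(rtag))) {
      cu <- sub("^([0-9]+).*$", "\\1", rtag$payload[j])
      sb <- sub("^[0-9]+", "", rtag$payload[j])
      pieces <- c(pieces, paste0("[CU", cu, ":", sb, "]"))
    }
    closes <- spans[spans$end == idx + 1L, , drop = FALSE]
    for (j in seq_len(nrow(closes))) {
      pieces <- c(pieces, paste0("</", label_to_tag[closes$label[j]], ">"))
    }
  }
  flush_line()
  if (!is.null(path)) {
    writeLines(lines_out, path, useBytes = TRUE)
    return(invisible(lines_out))
  }
  lines_out
}

#' Total utterances of a transcript
#'
#' An utterance is any verbalization attempt: real words, filler words,
#' false-start fragments and unrecognizable words all count once. This is the
#' denominator of the informativeness statistic.
#'
#' @param t a `ppa_transcript`.
#' @return non-negative integer.
#' @export
count_total_utterances <- function(t) {
  stopifnot(inherits(t, "ppa_transcript"))
  nrow(t$tokens)
}

#' @export
print.ppa_transcript <- function(x, ...) {
  cat("<ppa_transcript> ", x$participant_id, " (", x$group, "): ",
      nrow(x$tokens), " tokens, ", nrow(x$annotations), " annotations\n",
      sep = "")
  invisible(x)
}
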