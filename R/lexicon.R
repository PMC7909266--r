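# ---- normalization shared by the lexicon and the tokenizer ----

#' Normalize a word to its matchable surface form
#'
#' Lowercases, converts typographic apostrophes to `'`, and strips every
#' character that is not a letter, digit or apostrophe (so hyphens and other
#' punctuation vanish: `"T-shirt"` becomes `"tshirt"`). Apostrophes are kept
#' because contractions are single tokens (`"can't"`).
#'
#' @param x character vector of words.
#' @return character vector of normalized words (possibly empty strings).
#' @export
normalize_word <- function(x) {
  x <- tolower(x)
  x <- gsub("[’‘ʼ]", "'", x)
  gsub("[^a-z0-9']", "", x)
}

#' Normalize a phrase to a space-joined sequence of normalized words
#'
#' @param x character vector of phrases (whitespace-delimited words).
#' @return character vector; words that normalize to the empty string are
#'   dropped.
#' @export
normalize_phrase <- function(x) {
  vapply(x, function(p) {
    toks <- normalize_word(strsplit(trimws(p), "\\s+")[[1]])
    paste(toks[nzchar(toks)], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic inflection table: plural, -ing and -ed surface forms of a
# normalized word, including consonant doubling (run -> running) and e-drop
# (make -> making). Intentionally rule-based rather than a lemmatizer so that
# matching is reproducible and dependency-free.
inflect_word <- function(w) {
  if (!nzchar(w)) return(character(0))
  out <- character(0)
  last <- substr(w, nchar(w), nchar(w))
  # plural
  if (grepl("(s|x|z|ch|sh)$", w)) {
    out <- c(out, paste0(w, "es"))
  } else if (grepl("[^aeiou]y$", w)) {
    out <- c(out, sub("y$", "ies", w))
  } else {
    out <- c(out, paste0(w, "s"))
  }
  cvc <- nchar(w) >= 3 && grepl("[^aeiou][aeiou][^aeiouwxy']$", w)
  # -ing
  if (grepl("[^e]e$", w) && nchar(w) > 2) {
    out <- c(out, paste0(sub("e$", "", w), "ing"))
  } else {
    out <- c(out, paste0(w, "ing"))
  }
  if (cvc) out <- c(out, paste0(w, last, "ing"))
  # -ed
  if (grepl("e$", w)) {
    out <- c(out, paste0(w, "d"))
  } else if (grepl("[^aeiou]y$", w)) {
    out <- c(out, sub("y$", "ied", w))
  } else {
    out <- c(out, paste0(w, "ed"))
  }
  if (cvc) out <- c(out, paste0(w, last, "ed"))
  unique(out)
}

# Inflect the final word of a normalized phrase.
inflect_phrase <- function(phrase) {
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  n <- length(toks)
  forms <- inflect_word(toks[n])
  if (n == 1L) return(forms)
  prefix <- paste(toks[-n], collapse = " ")
  paste(prefix, forms)
}

# ---- referent field parsing ----

# Referent cells hold either "no-pattern", a comma-separated list of parent
# cu_ids, or composite entries joined with "+" (e.g. "8+42": one identity
# referring jointly to the woman and the big man). Returns a list with the
# raw spec and the integer ids mentioned.
parse_referents <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(list(spec = "", ids = integer(0), no_pattern = FALSE))
  if (tolower(x) %in% c("no-pattern", "no pattern", "none")) {
    return(list(spec = "no-pattern", ids = integer(0), no_pattern = TRUE))
  }
  parts <- trimws(unlist(strsplit(x, ",", fixed = TRUE)))
  ids <- suppressWarnings(as.integer(unlist(strsplit(parts, "+", fixed = TRUE))))
  list(spec = x, ids = ids, no_pattern = FALSE)
}

# ---- loading ----

#' Path to the packaged picnic-scene content-unit lexicon
#'
#' @param format `"tsv"` (default) or `"json"`; the two fixtures carry
#'   identical content.
#' @return file path of the packaged lexicon.
#' @export
cu_lexicon_path <- function(format = c("tsv", "json")) {
  format <- match.arg(format)
  fn <- paste0("picnic_cu_lexicon.", format)
  path <- system.file("extdata", fn, package = "cuscore")
  if (!nzchar(path)) stop("packaged lexicon not found: ", fn)
  path
}

#' Load a content-unit lexicon
#'
#' Reads the tab-separated lexicon dialect (columns `cu_id`, `sub_id`,
#' `category`, `variant`, `control_count`, `referents`; one row per variant
#' phrase, one row per referent sub-unit) or its JSON mirror, and builds the
#' matching tables used by [match_cus()]: normalized variant heads (with
#' parenthetical context stripped) plus a rule-based inflection expansion.
#'
#' @param path lexicon file (`.tsv`/`.txt` or `.json`).
#' @return an object of class `cu_lexicon` with elements `units` (one row per
#'   parent CU), `variants`, `subunits` and `match_table`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file does not exist: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path)
    rows <- as.data.frame(lapply(rows, as.character), stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("parse error: lexicon file is empty: ", path)
    rows <- utils::read.delim(path, sep = "\t", quote = "", fill = TRUE,
                              colClasses = "character", strip.white = FALSE,
                              stringsAsFactors = FALSE)
  }
  needed <- c("cu_id", "sub_id", "category", "variant", "control_count",
              "referents")
  for (col in needed) if (is.null(rows[[col]])) rows[[col]] <- ""
  missing_cols <- setdiff(c("cu_id", "category"), names(rows))
  if (length(missing_cols) > 0L) {
    stop("parse error: lexicon is missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- rows[needed]
  rows[] <- lapply(rows, function(x) ifelse(is.na(x), "", x))
  if (nrow(rows) == 0L) stop("parse error: lexicon has no rows: ", path)

  cu_id <- suppressWarnings(as.integer(rows$cu_id))
  bad <- which(is.na(cu_id) | cu_id < 1L)
  if (length(bad) > 0L) {
    stop("parse error in lexicon row ", bad[1] + 1L,
         ": cu_id must be a positive integer, got '", rows$cu_id[bad[1]], "'")
  }
  rows$cu_id <- cu_id

  is_sub <- nzchar(trimws(rows$sub_id))
  vrows <- rows[!is_sub & nzchar(trimws(rows$variant)), , drop = FALSE]
  srows <- rows[is_sub, , drop = FALSE]
  orphan <- rows[!is_sub & !nzchar(trimws(rows$variant)), , drop = FALSE]
  if (nrow(orphan) > 0L) {
    stop("parse error: row for CU ", orphan$cu_id[1],
         " has neither a variant nor a sub_id")
  }

  # parent-level table; category/control_count must be consistent per CU
  units <- do.call(rbind, lapply(split(vrows, vrows$cu_id), function(d) {
    cats <- unique(trimws(d$category))
    cnts <- unique(trimws(d$control_count))
    if (length(cats) != 1L) {
      stop("validation error: CU ", d$cu_id[1],
           " has conflicting categories: ", paste(cats, collapse = ", "))
    }
    if (length(cnts) != 1L) {
      stop("validation error: CU ", d$cu_id[1],
           " has conflicting control counts (duplicate cu_id definitions)")
    }
    refs <- unique(trimws(d$referents))
    refs <- refs[nzchar(refs)]
    data.frame(cu_id = d$cu_id[1], category = cats,
               control_count = suppressWarnings(as.integer(cnts)),
               parent_referents = if (length(refs)) refs[1] else "",
               stringsAsFactors = FALSE)
  }))
  rownames(units) <- NULL
  units <- units[order(units$cu_id), , drop = FALSE]

  # variants with parenthetical context stripped into a note
  context <- vapply(seq_len(nrow(vrows)), function(i) {
    m <- regmatches(vrows$variant[i], regexpr("\\(([^)]*)\\)", vrows$variant[i]))
    if (length(m)) gsub("[()]", "", m) else ""
  }, character(1))
  head_raw <- trimws(gsub("\\([^)]*\\)", " ", vrows$variant))
  variants <- data.frame(
    cu_id = vrows$cu_id,
    variant = trimws(vrows$variant),
    phrase = normalize_phrase(head_raw),
    context = context,
    stringsAsFactors = FALSE
  )
  variants <- variants[nzchar(variants$phrase), , drop = FALSE]
  # duplicate normalized heads within one CU collapse to a single entry
  variants <- variants[!duplicated(variants[c("cu_id", "phrase")]), , drop = FALSE]
  variants$n_tokens <- lengths(strsplit(variants$phrase, " ", fixed = TRUE))
  rownames(variants) <- NULL

  subunits <- if (nrow(srows) > 0L) {
    data.frame(
      cu_id = srows$cu_id,
      sub_id = trimws(srows$sub_id),
      control_count = suppressWarnings(as.integer(srows$control_count)),
      referents = trimws(srows$referents),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(cu_id = integer(0), sub_id = character(0),
               control_count = integer(0), referents = character(0),
               stringsAsFactors = FALSE)
  }
  if (anyDuplicated(subunits$sub_id)) {
    stop("validation error: duplicate sub_id in lexicon: ",
         subunits$sub_id[duplicated(subunits$sub_id)][1])
  }
  rownames(subunits) <- NULL

  lex <- structure(
    list(units = units, variants = variants, subunits = subunits,
         source = path),
    class = "cu_lexicon"
  )
  lex$match_table <- build_match_table(lex)
  lex
}

# Exact variant phrases plus inflected expansions. Expansions that collide
# with a stored variant are dropped (the stored variant wins); expansions
# generated by two different CUs are ambiguous and dropped entirely.
build_match_table <- function(lex) {
  exact <- data.frame(
    phrase = lex$variants$phrase,
    cu_id = lex$variants$cu_id,
    n_tokens = lex$variants$n_tokens,
    exact = TRUE,
    stringsAsFactors = FALSE
  )
  exp_list <- lapply(seq_len(nrow(exact)), function(i) {
    forms <- inflect_phrase(exact$phrase[i])
    if (length(forms) == 0L) return(NULL)
    data.frame(phrase = forms, cu_id = exact$cu_id[i],
               n_tokens = lengths(strsplit(forms, " ", fixed = TRUE)),
               exact = FALSE, stringsAsFactors = FALSE)
  })
  expanded <- do.call(rbind, exp_list)
  if (!is.null(expanded)) {
    expanded <- expanded[!expanded$phrase %in% exact$phrase, , drop = FALSE]
    expanded <- expanded[!duplicated(expanded[c("phrase", "cu_id")]), , drop = FALSE]
    amb <- expanded$phrase[duplicated(expanded$phrase)]
    expanded <- expanded[!expanded$phrase %in% amb, , drop = FALSE]
  }
  tab <- rbind(exact, expanded)
  rownames(tab) <- NULL
  tab
}

#' Validate a content-unit lexicon
#'
#' Checks the lexicon invariants: every CU was produced by at least
#' `min_controls` healthy controls, every CU owns at least one variant,
#' normalized variant phrases are unique across the whole lexicon, and every
#' referent id named by a sub-unit resolves to an existing parent CU.
#' Violations are returned, not raised.
#'
#' @param lex a `cu_lexicon`.
#' @param min_controls minimum number of controls per CU (default 3).
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_lexicon <- function(lex, min_controls = 3L) {
  stopifnot(inherits(lex, "cu_lexicon"))
  v <- character(0)
  low <- lex$units[is.na(lex$units$control_count) |
                     lex$units$control_count < min_controls, , drop = FALSE]
  if (nrow(low) > 0L) {
    v <- c(v, paste0("CU ", low$cu_id, ": control_count ",
                     low$control_count, " below minimum ", min_controls))
  }
  no_var <- setdiff(lex$units$cu_id, lex$variants$cu_id)
  if (length(no_var) > 0L) {
    v <- c(v, paste0("CU ", no_var, ": no variant phrases"))
  }
  dup <- lex$variants$phrase[duplicated(lex$variants$phrase)]
  if (length(dup) > 0L) {
    v <- c(v, paste0("variant phrase '", unique(dup),
                     "' belongs to more than one CU"))
  }
  if (nrow(lex$subunits) > 0L) {
    for (i in seq_len(nrow(lex$subunits))) {
      refs <- parse_referents(lex$subunits$referents[i])
      missing <- setdiff(refs$ids, lex$units$cu_id)
      if (length(missing) > 0L) {
        v <- c(v, paste0("sub-unit ", lex$subunits$sub_id[i],
                         ": referent CU ", missing,
                         " does not exist in the lexicon"))
      }
      if (!lex$subunits$cu_id[i] %in% lex$units$cu_id) {
        v <- c(v, paste0("sub-unit ", lex$subunits$sub_id[i],
                         ": parent CU ", lex$subunits$cu_id[i],
                         " does not exist"))
      }
    }
  }
  v
}

#' Expand the lexicon into unique-referent scoreable identities
#'
#' Under the unique-referent coding scheme a CU whose surface forms are
#' ambiguous between picture referents is subdivided: each referent sub-unit
#' is a separate scoreable identity, plus one parent-level "referent unknown"
#' identity for mentions the annotation does not disambiguate. CUs without
#' sub-units keep their single parent identity.
#'
#' @param lex a `cu_lexicon`.
#' @return data.frame with columns `cu_id`, `identity`, `kind`
#'   (`"parent"`, `"sub"` or `"unknown"`), carrying attributes
#'   `n_additional` (sub-identities minus subdivided parents, i.e. the net
#'   gain in scoreable concepts over the original scheme) and `n_sub`.
#' @export
expand_uniqueref <- function(lex) {
  stopifnot(inherits(lex, "cu_lexicon"))
  subdivided <- unique(lex$subunits$cu_id)
  out <- list()
  for (id in lex$units$cu_id) {
    if (id %in% subdivided) {
      subs <- lex$subunits[lex$subunits$cu_id == id, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        cu_id = id,
        identity = c(subs$sub_id, paste0(id, ":unknown")),
        kind = c(rep("sub", nrow(subs)), "unknown"),
        stringsAsFactors = FALSE
      )
    } else {
      out[[length(out) + 1L]] <- data.frame(
        cu_id = id, identity = as.character(id), kind = "parent",
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_sub") <- nrow(lex$subunits)
  attr(res, "n_additional") <- nrow(lex$subunits) - length(subdivided)
  res
}

#' Look up the content unit owning a normalized phrase
#'
#' Exact stored variants take precedence over inflected expansions. Longest-
#' match resolution across overlapping phrases is the caller's job
#' ([match_cus()]); this is a total lookup over single phrases.
#'
#' @param lex a `cu_lexicon`.
#' @param phrase a single phrase string (words separated by spaces) or a
#'   character vector of word tokens.
#' @return the owning `cu_id` as integer, or `NA_integer_` when the phrase is
#'   not in the lexicon.
#' @export
lookup_variant <- function(lex, phrase) {
  stopifnot(inherits(lex, "cu_lexicon"))
  if (length(phrase) > 1L) phrase <- paste(phrase, collapse = " ")
  phrase <- normalize_phrase(phrase)
  hit <- lex$match_table[lex$match_table$phrase == phrase, , drop = FALSE]
  if (nrow(hit) == 0L) return(NA_integer_)
  if (any(hit$exact)) hit <- hit[hit$exact, , drop = FALSE]
  hit$cu_id[1]
}

# ---- writers ----

# Reconstruct the canonical tabular rows (one row per variant, one per
# sub-unit) from a lexicon object.
lexicon_rows <- function(lex) {
  vr <- merge(lex$variants, lex$units, by = "cu_id", sort = FALSE)
  vrow <- data.frame(
    cu_id = vr$cu_id, sub_id = "", category = vr$category,
    variant = vr$variant, control_count = as.character(vr$control_count),
    referents = vr$parent_referents, stringsAsFactors = FALSE
  )
  srow <- if (nrow(lex$subunits) > 0L) {
    cat_by_cu <- stats::setNames(lex$units$category, lex$units$cu_id)
    data.frame(
      cu_id = lex$subunits$cu_id, sub_id = lex$subunits$sub_id,
      category = unname(cat_by_cu[as.character(lex$subunits$cu_id)]),
      variant = "",
      control_count = ifelse(is.na(lex$subunits$control_count), "",
                             as.character(lex$subunits$control_count)),
      referents = lex$subunits$referents, stringsAsFactors = FALSE
    )
  } else NULL
  rows <- rbind(vrow, srow)
  rows[order(rows$cu_id, rows$sub_id != "", rows$sub_id), , drop = FALSE]
}

#' Write a lexicon to the tabular dialect or its JSON mirror
#'
#' @param lex a `cu_lexicon`.
#' @param path output path; a `.json` extension selects the JSON mirror,
#'   anything else the TSV dialect.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  rows <- lexicon_rows(lex)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, dataframe = "columns", pretty = TRUE)
  } else {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @export
print.cu_lexicon <- function(x, ...) {
  cat("<cu_lexicon> ", nrow(x$units), " parent CUs, ",
      nrow(x$variants), " variant phrases, ",
      nrow(x$subunits), " referent sub-units\n", sep = "")
  cat("  match table: ", nrow(x$match_table), " phrases (",
      sum(x$match_table$exact), " exact, ",
      sum(!x$match_table$exact), " inflected)\n", sep = "")
  invisible(x)
}
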