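# Seeded synthetic-cohort generator. Each synthetic participant is built to
# a known ground truth: a target utterance count U (truncated normal), a
# target informativeness p (truncated normal), and C = round(p * U) distinct
# content units realized as randomly chosen lexicon variants, padded with
# atypical-speech spans and distractor words screened against the lexicon so
# the scoring pipeline recovers C exactly. The transcripts are plain text in
# the package's transcript grammar, so every pipeline stage is exercised.

#' Construct a group generation profile
#'
#' Defaults for the four study groups are provided by
#' [default_cohort_config()]; utterance and informativeness parameters follow
#' the study's reported group statistics, and the per-category atypical
#' rates are qualitative settings encoding the reported group ordering
#' (they have no printed values to match).
#'
#' @param group one of svPPA, lvPPA, nfvPPA, HC.
#' @param n number of participants.
#' @param utterance_mean,utterance_sd normal parameters for the total
#'   utterance count (truncated at 10).
#' @param informativeness_mean,informativeness_sd normal parameters for the
#'   informativeness proportion (truncated to \[0, 1\]).
#' @param atypical_rates named numeric vector of per-category token
#'   proportions (names from `self_referential`, `inability`, `tangential`,
#'   `empty`, `false_start`).
#' @return list of class `group_profile`.
#' @export
group_profile <- function(group, n, utterance_mean, utterance_sd,
                          informativeness_mean, informativeness_sd,
                          atypical_rates) {
  stopifnot(group %in% PPA_GROUPS, n >= 2,
            utterance_sd >= 0, informativeness_sd >= 0,
            informativeness_mean > 0, informativeness_mean < 1,
            all(names(atypical_rates) %in% ATYPICAL_CATEGORIES))
  rates <- stats::setNames(numeric(length(ATYPICAL_CATEGORIES)),
                           ATYPICAL_CATEGORIES)
  rates[names(atypical_rates)] <- atypical_rates
  structure(list(group = group, n = as.integer(n),
                 utterance_mean = utterance_mean,
                 utterance_sd = utterance_sd,
                 informativeness_mean = informativeness_mean,
                 informativeness_sd = informativeness_sd,
                 atypical_rates = rates),
            class = "group_profile")
}

#' Default cohort configuration
#'
#' Four groups with the study's sample sizes (19 svPPA, 26 lvPPA, 25 nfvPPA,
#' 31 HC), utterance-count distributions (means 135/135/97.1/150, SDs
#' 53.6/60.3/34.1/65.9) and original-method informativeness distributions
#' (means 11.1%/11.7%/23.1%/20.9%, SDs 6.46/5.18/9.45/5.67 percentage
#' points). Atypical rates are qualitative: semantic-variant speech leads on
#' self-referential and inability content, logopenic on empty speech and
#' false starts, and the non-fluent group tracks controls.
#'
#' @param seed integer seed controlling the whole corpus.
#' @return list of class `cohort_config` with `profiles` and `seed`.
#' @export
default_cohort_config <- function(seed = 1L) {
  profiles <- list(
    group_profile("svPPA", 19, 135, 53.6, 0.111, 0.0646,
                  c(self_referential = 0.08, inability = 0.06,
                    tangential = 0.03, empty = 0.08, false_start = 0.02)),
    group_profile("lvPPA", 26, 135, 60.3, 0.117, 0.0518,
                  c(self_referential = 0.01, inability = 0.06,
                    tangential = 0.01, empty = 0.15, false_start = 0.07)),
    group_profile("nfvPPA", 25, 97.1, 34.1, 0.231, 0.0945,
                  c(self_referential = 0.005, inability = 0.01,
                    tangential = 0.005, empty = 0.06, false_start = 0.02)),
    group_profile("HC", 31, 150, 65.9, 0.209, 0.0567,
                  c(self_referential = 0.005, inability = 0.005,
                    tangential = 0.005, empty = 0.05, false_start = 0.01))
  )
  structure(list(profiles = profiles, seed = as.integer(seed)),
            class = "cohort_config")
}

# one truncated-normal draw by rejection (cheap at the truncation levels
# used here)
rtrunc1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Distractor vocabulary screened against a lexicon
#'
#' Loads the packaged distractor word list and verifies that no entry
#' collides with any token of any lexicon variant or inflected form, any
#' filler, or any token of the cue/empty phrase lists. A collision is an
#' error (it would break the exact-recovery guarantee of the generator).
#'
#' @param lex a `cu_lexicon`.
#' @return character vector of safe distractor words.
#' @export
distractor_vocabulary <- function(lex) {
  words <- normalize_phrase(read_word_list(
    system.file("extdata", "distractors.txt", package = "cuscore")))
  lex_tokens <- unique(unlist(strsplit(lex$match_table$phrase, " ",
                                       fixed = TRUE)))
  reserved <- unique(c(
    lex_tokens,
    unlist(strsplit(default_fillers(), " ", fixed = TRUE)),
    unlist(strsplit(default_inability_cues(), " ", fixed = TRUE)),
    unlist(strsplit(default_empty_phrases(), " ", fixed = TRUE)),
    "xxx"
  ))
  clash <- intersect(words, reserved)
  if (length(clash) > 0L) {
    stop("distractor vocabulary collides with the lexicon or word lists: ",
         paste(clash, collapse = ", "))
  }
  words
}

# sample k distractor words (with replacement)
draw_distractors <- function(vocab, k) {
  if (k <= 0L) return(character(0))
  sample(vocab, k, replace = TRUE)
}

#' Generate one synthetic participant
#'
#' Draws the utterance count U and informativeness p, plants
#' `C = round(p * U)` distinct content units (random variant phrases),
#' fills the remaining token budget with tagged atypical spans and plain
#' distractor words, and returns both the transcript lines and the ground
#' truth. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param profile a `group_profile`.
#' @param lex a `cu_lexicon`.
#' @param participant_id id string.
#' @param vocab screened distractor vocabulary (see
#'   [distractor_vocabulary()]).
#' @return list with `lines` (transcript text), `truth` (one-row
#'   data.frame: utterances, cu_count, per-category token counts,
#'   informativeness_true).
#' @export
generate_participant <- function(profile, lex, participant_id,
                                 vocab = distractor_vocabulary(lex)) {
  stopifnot(inherits(profile, "group_profile"), inherits(lex, "cu_lexicon"))
  U <- as.integer(round(rtrunc1(profile$utterance_mean,
                                profile$utterance_sd, lower = 10)))
  p <- rtrunc1(profile$informativeness_mean, profile$informativeness_sd,
               lower = 0, upper = 1)
  C <- min(max(0L, as.integer(round(p * U))), 64L, nrow(lex$units))

  # variant choice per planted CU; shrink to fit the token budget
  pick_variants <- function(ids, shortest = FALSE) {
    vapply(ids, function(id) {
      v <- lex$variants[lex$variants$cu_id == id, , drop = FALSE]
      if (shortest) v <- v[v$n_tokens == min(v$n_tokens), , drop = FALSE]
      v$phrase[sample.int(nrow(v), 1L)]
    }, character(1))
  }
  cu_ids <- if (C > 0L) sort(sample(lex$units$cu_id, C)) else integer(0)
  phrases <- pick_variants(cu_ids)
  L <- sum(lengths(strsplit(phrases, " ", fixed = TRUE)))
  targets <- vapply(profile$atypical_rates, function(r)
    as.integer(round(r * U)), integer(1))
  shortened <- FALSE
  while (C > 0L && L + sum(targets) > U) {
    if (sum(targets) > 0L) {
      targets <- pmax(0L, targets - 1L)
    } else if (!shortened) {
      shortened <- TRUE
      phrases <- pick_variants(cu_ids, shortest = TRUE)
      L <- sum(lengths(strsplit(phrases, " ", fixed = TRUE)))
    } else {
      C <- C - 1L
      cu_ids <- cu_ids[-length(cu_ids)]
      phrases <- phrases[-length(phrases)]
      L <- sum(lengths(strsplit(phrases, " ", fixed = TRUE)))
    }
  }
  P <- U - L - sum(targets)

  subdivided <- unique(lex$subunits$cu_id)
  segments <- list()
  add_seg <- function(s) segments[[length(segments) + 1L]] <<- s

  for (k in seq_along(cu_ids)) {
    line <- phrases[k]
    if (cu_ids[k] %in% subdivided && stats::runif(1) < 0.7) {
      subs <- lex$subunits$sub_id[lex$subunits$cu_id == cu_ids[k]]
      sid <- sample(subs, 1L)
      line <- paste0(line, "[CU", cu_ids[k], ":",
                     sub(paste0("^", cu_ids[k]), "", sid), "]")
    }
    add_seg(line)
  }

  fill_tagged <- function(total, tag) {
    left <- total
    while (left > 0L) {
      k <- min(left, sample(3:6, 1L))
      add_seg(paste0("<", tag, "> ",
                     paste(draw_distractors(vocab, k), collapse = " "),
                     " </", tag, ">"))
      left <- left - k
    }
  }
  fill_tagged(targets[["self_referential"]], "sr")
  fill_tagged(targets[["tangential"]], "tg")
  fill_tagged(targets[["inability"]], "in")

  simple_fillers <- c("um", "uh", "er", "hm", "mhm")
  left <- targets[["empty"]]
  while (left > 0L) {
    k <- min(left, sample(1:3, 1L))
    toks <- sample(c(simple_fillers, "xxx"), k, replace = TRUE)
    add_seg(paste(toks, collapse = " "))
    left <- left - k
  }

  left <- targets[["false_start"]]
  while (left > 0L) {
    k <- min(left, sample(1:2, 1L))
    frags <- vapply(seq_len(k), function(i) {
      paste0("&", paste(sample(letters, sample(2:3, 1L), replace = TRUE),
                        collapse = ""), "-")
    }, character(1))
    add_seg(paste(frags, collapse = " "))
    left <- left - k
  }

  left <- P
  while (left > 0L) {
    k <- min(left, sample(3:8, 1L))
    add_seg(paste(draw_distractors(vocab, k), collapse = " "))
    left <- left - k
  }

  lines <- unlist(segments)[sample.int(length(segments))]
  truth <- data.frame(
    participant_id = participant_id, group = profile$group,
    utterances = U, cu_count = C,
    n_self_referential = targets[["self_referential"]],
    n_inability = targets[["inability"]],
    n_tangential = targets[["tangential"]],
    n_empty = targets[["empty"]],
    n_false_start = targets[["false_start"]],
    informativeness_true = C / U,
    stringsAsFactors = FALSE
  )
  list(lines = lines, truth = truth)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one transcript file per participant, a cohort manifest and a
#' ground-truth table under `out_dir`. A fixed seed yields a byte-identical
#' corpus.
#'
#' @param config a `cohort_config` (default [default_cohort_config()]).
#' @param out_dir output directory (created if needed).
#' @param lex a `cu_lexicon`; default is the packaged lexicon.
#' @return list with `dir`, `manifest` (data.frame), `truth` (data.frame)
#'   and `manifest_path` / `truth_path`.
#' @export
generate_cohort <- function(config = default_cohort_config(),
                            out_dir = tempfile("cohort_"), lex = NULL) {
  if (is.null(lex)) lex <- load_lexicon(cu_lexicon_path())
  vocab <- distractor_vocabulary(lex)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list()
  truth <- list()
  for (profile in config$profiles) {
    for (i in seq_len(profile$n)) {
      pid <- sprintf("%s_%03d", profile$group, i)
      gp <- generate_participant(profile, lex, pid, vocab)
      writeLines(gp$lines, file.path(out_dir, paste0(pid, ".txt")),
                 useBytes = TRUE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        participant_id = pid, group = profile$group, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- gp$truth
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  manifest_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_manifest(manifest, manifest_path)
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  list(dir = out_dir, manifest = manifest, truth = truth,
       manifest_path = manifest_path, truth_path = truth_path)
}

#' Validate pipeline recovery of a synthetic cohort
#'
#' Scores a generated corpus and checks: exact per-participant recovery of
#' the planted CU count by the original-scheme pipeline; group mean
#' utterances and informativeness within 2 standard errors of the configured
#' values; and the qualitative atypical ordering (semantic variant highest on
#' self-referential speech, logopenic highest on empty speech and false
#' starts). Violations are reported, not raised.
#'
#' @param cohort result of [generate_cohort()].
#' @param config the `cohort_config` used to generate it.
#' @param lex a `cu_lexicon`; default packaged lexicon.
#' @return list with `scores`, `checks` (named logical) and `violations`
#'   (character).
#' @export
recovery_check <- function(cohort, config = default_cohort_config(),
                           lex = NULL) {
  if (is.null(lex)) lex <- load_lexicon(cu_lexicon_path())
  scores <- score_transcripts(cohort$dir, cohort$manifest, lex)
  merged <- merge(scores, cohort$truth, by = c("participant_id", "group"))
  checks <- c()
  violations <- character(0)
  note <- function(name, ok, msg) {
    checks[[name]] <<- ok
    if (!ok) violations <<- c(violations, msg)
  }
  note("exact_cu_recovery",
       all(merged$raw_cu_original == merged$cu_count),
       "raw_cu_original does not equal the planted CU count everywhere")
  note("utterance_identity",
       all(merged$total_utterances == merged$utterances),
       "scored utterance totals differ from the generated token counts")
  note("uniqueref_ordering",
       all(merged$raw_cu_uniqueref >= merged$raw_cu_original),
       "unique-referent counts fell below original counts")
  for (profile in config$profiles) {
    g <- profile$group
    d <- merged[merged$group == g, , drop = FALSE]
    se_u <- profile$utterance_sd / sqrt(nrow(d))
    note(paste0("utterances_", g),
         abs(mean(d$total_utterances) - profile$utterance_mean) <= 2 * se_u,
         paste0(g, ": mean utterances outside 2 SE of the configured mean"))
    se_i <- profile$informativeness_sd / sqrt(nrow(d))
    note(paste0("informativeness_", g),
         abs(mean(d$informativeness_original) -
               profile$informativeness_mean) <= 2 * se_i,
         paste0(g, ": mean informativeness outside 2 SE of configured mean"))
  }
  by_group <- function(col) {
    vapply(split(merged[[col]], merged$group), mean, numeric(1))
  }
  sr <- by_group("prop_self_referential")
  note("sv_highest_self_referential",
       names(which.max(sr)) == "svPPA",
       "svPPA is not the group with the most self-referential speech")
  em <- by_group("prop_empty")
  fs <- by_group("prop_false_start")
  note("lv_highest_empty", names(which.max(em)) == "lvPPA",
       "lvPPA is not the group with the most empty speech")
  note("lv_highest_false_start", names(which.max(fs)) == "lvPPA",
       "lvPPA is not the group with the most false starts")
  list(scores = scores, checks = unlist(checks), violations = violations)
}
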