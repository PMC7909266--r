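# End-to-end orchestration: score a transcript directory, analyze a score
# table, or simulate a cohort, each writing reproducible outputs plus a
# machine-readable run manifest (configuration echo, package version, seed).

write_run_manifest <- function(out_dir, step, config) {
  info <- list(
    step = step,
    package = "cuscore",
    version = as.character(utils::packageVersion("cuscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  path <- file.path(out_dir, paste0("run_manifest_", step, ".json"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Score a directory of transcripts and write the score table
#'
#' @param transcripts_dir directory of `.txt` transcripts.
#' @param manifest cohort manifest (CSV path or data.frame).
#' @param out_dir output directory; receives `scores.csv`, a
#'   `match_audit.tsv` log of every CU match for coder review, and a run
#'   manifest.
#' @param lexicon lexicon path or `cu_lexicon`; default packaged lexicon.
#' @param atypical_mode see [classify_atypical()].
#' @param skip_bad skip unparseable transcripts with a warning instead of
#'   aborting.
#' @return the score data.frame, invisibly; files under `out_dir`.
#' @export
run_score <- function(transcripts_dir, manifest, out_dir,
                      lexicon = cu_lexicon_path(),
                      atypical_mode = "rules+annotation", skip_bad = FALSE) {
  lex <- if (inherits(lexicon, "cu_lexicon")) lexicon else load_lexicon(lexicon)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- score_transcripts(transcripts_dir, manifest, lex,
                              atypical_mode = atypical_mode,
                              skip_bad = skip_bad)
  audit <- attr(scores, "matches")
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(audit, file.path(out_dir, "match_audit.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_run_manifest(out_dir, "score", list(
    transcripts_dir = transcripts_dir,
    lexicon = if (inherits(lexicon, "cu_lexicon")) lexicon$source else lexicon,
    atypical_mode = atypical_mode, skip_bad = skip_bad,
    n_participants = nrow(scores)))
  invisible(scores)
}

#' Analyze a score table: summaries, ANOVA, pairwise tests, impairment
#'
#' Runs the full statistical plan on a participant score table for one or
#' both coding schemes: per-group summaries, one-way ANOVA of raw CU counts
#' and informativeness, Bonferroni-corrected pooled-variance pairwise
#' t-tests with Hedges' g, and normal-range impairment flags against the
#' control informativeness distribution.
#'
#' @param scores score table (data.frame or CSV path) from [run_score()].
#' @param out_dir output directory; one CSV set per coding scheme plus a run
#'   manifest.
#' @param method `"original"`, `"uniqueref"` or `"both"`.
#' @param alpha familywise alpha for the pairwise tests (default 0.05).
#' @return named list (per method) of lists with elements `summaries`,
#'   `anova_cu`, `anova_informativeness`, `pairwise_cu`,
#'   `pairwise_informativeness`, `impairment`; invisibly.
#' @export
run_analyze <- function(scores, out_dir,
                        method = c("both", "original", "uniqueref"),
                        alpha = 0.05) {
  method <- match.arg(method)
  if (is.character(scores)) {
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  }
  if (length(unique(scores$group)) < 2L) {
    stop("analysis requires at least two groups in the score table")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  methods <- if (method == "both") c("original", "uniqueref") else method
  results <- list()
  for (m in methods) {
    cu_col <- paste0("raw_cu_", m)
    inf_col <- paste0("informativeness_", m)
    summaries <- rbind(summarize_groups(scores, cu_col),
                       summarize_groups(scores, inf_col))
    anova_cu <- anova_oneway(scores[[cu_col]], scores$group)
    anova_inf <- anova_oneway(scores[[inf_col]], scores$group)
    pw_cu <- pairwise_ttests(scores[[cu_col]], scores$group, alpha = alpha)
    pw_inf <- pairwise_ttests(scores[[inf_col]], scores$group, alpha = alpha)
    hc <- summaries[summaries$group == "HC" & summaries$measure == inf_col, ]
    impairment <- data.frame(
      participant_id = scores$participant_id, group = scores$group,
      informativeness = scores[[inf_col]],
      impaired = if (nrow(hc) == 1L) {
        classify_impairment(hc, scores[[inf_col]])
      } else NA,
      stringsAsFactors = FALSE
    )
    utils::write.csv(summaries,
                     file.path(out_dir, paste0("summaries_", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
    anova_tab <- data.frame(
      measure = c(cu_col, inf_col),
      F = c(anova_cu$F, anova_inf$F),
      df_between = c(anova_cu$df_between, anova_inf$df_between),
      df_within = c(anova_cu$df_within, anova_inf$df_within),
      p = c(anova_cu$p, anova_inf$p))
    utils::write.csv(anova_tab,
                     file.path(out_dir, paste0("anova_", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
    pw_all <- rbind(cbind(measure = cu_col, as.data.frame(pw_cu)),
                    cbind(measure = inf_col, as.data.frame(pw_inf)))
    utils::write.csv(pw_all,
                     file.path(out_dir, paste0("pairwise_", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(impairment,
                     file.path(out_dir, paste0("impairment_", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
    results[[m]] <- list(summaries = summaries, anova_cu = anova_cu,
                         anova_informativeness = anova_inf,
                         pairwise_cu = pw_cu,
                         pairwise_informativeness = pw_inf,
                         impairment = impairment)
  }
  write_run_manifest(out_dir, "analyze",
                     list(method = method, alpha = alpha,
                          n_participants = nrow(scores)))
  invisible(results)
}

#' Simulate a synthetic cohort (orchestration wrapper)
#'
#' @param out_dir output corpus directory.
#' @param config a `cohort_config`; default [default_cohort_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return the [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(out_dir, config = default_cohort_config(),
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config, out_dir)
  write_run_manifest(out_dir, "simulate", list(
    seed = config$seed,
    groups = vapply(config$profiles, function(p) p$group, character(1)),
    n = vapply(config$profiles, function(p) p$n, integer(1))))
  invisible(cohort)
}
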