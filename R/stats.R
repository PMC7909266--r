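# Group-level statistics for the four-group design (svPPA, lvPPA, nfvPPA,
# HC): group summaries, one-way ANOVA from raw scores (via stats::aov) or
# from printed summary statistics, pooled-variance pairwise t-tests with a
# Bonferroni-adjusted alpha, Hedges' g with the small-sample correction, and
# a normal-range impairment classification against the control distribution.

#' Per-group n, mean and sample SD of a score measure
#'
#' @param scores data.frame with a `group` column (e.g. the output of
#'   [score_transcripts()]).
#' @param measure name of the numeric column to summarize.
#' @return data.frame with columns `group`, `measure`, `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator).
#' @export
summarize_groups <- function(scores, measure) {
  if (!measure %in% names(scores)) stop("no such measure column: ", measure)
  if (!"group" %in% names(scores)) stop("scores must have a 'group' column")
  out <- do.call(rbind, lapply(split(scores, scores$group), function(d) {
    if (nrow(d) < 2L) {
      stop("group '", d$group[1], "' has fewer than 2 participants")
    }
    x <- d[[measure]]
    data.frame(group = d$group[1], measure = measure, n = nrow(d),
               mean = mean(x), sd = stats::sd(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA from raw values
#'
#' Classical between/within decomposition via [stats::aov()]. When every
#' group has zero variance and the means are equal, F is defined as 0.
#'
#' @param values numeric vector of scores.
#' @param groups group labels, same length.
#' @return list of class `ppa_anova`: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (stats::var(values) == 0) {  # constant response: F defined as 0
    return(structure(list(F = 0, df_between = dfb, df_within = dfw, p = 1),
                     class = "ppa_anova"))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  F <- tab[["F value"]][1]
  dfb <- as.integer(tab[["Df"]][1])
  dfw <- as.integer(tab[["Df"]][2])
  if (is.na(F)) {  # zero within-group variance, unequal means
    F <- Inf
  }
  p <- if (is.infinite(F)) 0 else stats::pf(F, dfb, dfw, lower.tail = FALSE)
  structure(list(F = F, df_between = dfb, df_within = dfw, p = p),
            class = "ppa_anova")
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F test from per-group (n, mean, SD) only, so printed
#' summary tables can be re-analyzed without the raw scores:
#' \deqn{F = \frac{\sum_i n_i (m_i - \bar m)^2 / (k-1)}
#'            {\sum_i (n_i - 1) s_i^2 / (N-k)}}
#' with \eqn{\bar m} the n-weighted grand mean. Agrees with [anova_oneway()]
#' on the raw data to numerical precision.
#'
#' @param summaries data.frame with columns `n`, `mean`, `sd` (one row per
#'   group), e.g. from [summarize_groups()].
#' @return list of class `ppa_anova`: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_from_summary <- function(summaries) {
  stopifnot(all(c("n", "mean", "sd") %in% names(summaries)))
  k <- nrow(summaries)
  if (k < 2L) stop("need at least 2 group summaries")
  n <- summaries$n
  m <- summaries$mean
  s <- summaries$sd
  if (any(n < 2L)) stop("every group needs n >= 2")
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw == 0) {
    if (isTRUE(all.equal(msb, 0))) {
      F <- 0
    } else {
      warning("zero within-group variance with unequal means: F is infinite")
      F <- Inf
    }
  } else {
    F <- msb / msw
  }
  p <- if (is.infinite(F)) 0 else stats::pf(F, dfb, dfw, lower.tail = FALSE)
  structure(list(F = F, df_between = dfb, df_within = as.integer(dfw), p = p),
            class = "ppa_anova")
}

#' @export
print.ppa_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Hedges' g from two group summaries
#'
#' Standardized mean difference with pooled SD and the small-sample
#' correction \eqn{J = 1 - 3/(4N - 9)} (N the combined sample size):
#' \deqn{g = J\,\frac{m_a - m_b}{s_p},\qquad
#'       s_p^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a + n_b - 2}.}
#' By convention the reference group (HC) is passed first so that patient
#' deficits on a higher-is-better measure come out positive.
#'
#' @param a,b lists or one-row data.frames with `n`, `mean`, `sd`.
#' @return numeric g (antisymmetric under argument reversal).
#' @export
hedges_g <- function(a, b) {
  na <- a$n; nb <- b$n
  sp2 <- ((na - 1) * a$sd^2 + (nb - 1) * b$sd^2) / (na + nb - 2)
  diff <- a$mean - b$mean
  if (sp2 == 0) {
    if (isTRUE(all.equal(diff, 0))) return(0)
    warning("zero pooled SD with unequal means: effect size is infinite")
    return(sign(diff) * Inf)
  }
  J <- 1 - 3 / (4 * (na + nb) - 9)
  J * diff / sqrt(sp2)
}

#' Pairwise pooled-variance t-tests with Bonferroni-adjusted alpha
#'
#' Two-sided Student t-tests (pooled variance, matching the pooled-SD
#' convention of Hedges' g; Welch available via `welch = TRUE`) for every
#' pair of groups. Significance is declared at `alpha / m` where `m` is the
#' number of comparisons; the adjusted alpha is compared unrounded and
#' displayed rounded to 3 decimals. The reference group, when present, is
#' always the first member of a pair so effect-size signs follow the
#' [hedges_g()] convention.
#'
#' @param values numeric scores.
#' @param groups group labels, same length.
#' @param alpha familywise alpha (default 0.05).
#' @param reference group to order first within pairs (default `"HC"`).
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return data.frame of class `ppa_pairwise` with one row per pair:
#'   `group1`, `group2`, `t`, `df`, `p`, `g`, `significant`; the number of
#'   comparisons and the adjusted alpha (unrounded and display form) are
#'   attached as attributes `m`, `alpha_adjusted`, `alpha_display`.
#' @export
pairwise_ttests <- function(values, groups, alpha = 0.05, reference = "HC",
                            welch = FALSE) {
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) < 2L) stop("need at least 2 groups")
  if (reference %in% levs) levs <- c(reference, setdiff(levs, reference))
  pairs <- utils::combn(levs, 2L)
  m <- ncol(pairs)
  alpha_adj <- alpha / m
  rows <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- values[groups == g1]; y <- values[groups == g2]
    tt <- stats::t.test(x, y, var.equal = !welch)
    sa <- list(n = length(x), mean = mean(x), sd = stats::sd(x))
    sb <- list(n = length(y), mean = mean(y), sd = stats::sd(y))
    data.frame(group1 = g1, group2 = g2,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, g = hedges_g(sa, sb),
               significant = tt$p.value < alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "alpha_display") <- round(alpha_adj, 3)
  class(out) <- c("ppa_pairwise", class(out))
  out
}

#' Flag participants below the control normal range
#'
#' The normal range is the control mean plus/minus 1.96 control SDs (a
#' normal-range interval over the HC distribution, not a confidence interval
#' of the mean). A participant is impaired when the score falls strictly
#' below the lower bound (one-sided: only deficits are abnormal for
#' informativeness); a value exactly at the bound is not impaired.
#'
#' @param hc one-row summary (`n`, `mean`, `sd`) of the control group.
#' @param values numeric participant scores.
#' @param z half-width of the normal range in SD units (default 1.96).
#' @return logical vector of impairment flags.
#' @export
classify_impairment <- function(hc, values, z = 1.96) {
  lower <- hc$mean - z * hc$sd
  values < lower
}

#' Packaged reference group summaries from the original study cohort
#'
#' Reported (n, mean, SD) per group for raw CU counts and informativeness
#' (as percent) under both coding schemes, plus total utterance counts.
#'
#' @param measure optional filter (`"raw_cu"`, `"informativeness_pct"`,
#'   `"utterances"`).
#' @param method optional filter (`"original"`, `"uniqueref"`).
#' @return data.frame with columns `method`, `group`, `measure`, `n`,
#'   `mean`, `sd`.
#' @export
reference_summaries <- function(measure = NULL, method = NULL) {
  path <- system.file("extdata", "reference_cohort_summaries.csv",
                      package = "cuscore")
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  d$method[is.na(d$method)] <- ""
  if (!is.null(measure)) d <- d[d$measure == measure, , drop = FALSE]
  if (!is.null(method)) d <- d[d$method == method, , drop = FALSE]
  rownames(d) <- NULL
  d
}
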