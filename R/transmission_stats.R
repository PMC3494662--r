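## Inheritance and transmission statistics: chi-square tests for sex-ratio
## distortion and departure from autosomal-dominant expectation, cross-stage
## transmission comparisons, Welch's t from group summaries, germline
## mosaicism from sperm-FISH counts, and the AI-record bound on the timing
## of male embryonic death.  Standard distributions and the exact binomial
## interval are delegated to stats::.

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = as.numeric(statistic), df = as.numeric(df),
                 p = as.numeric(p), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.3g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' No continuity correction is applied: the statistic is the plain Pearson
#' chi-square with 1 df.
#'
#' @param table 2x2 matrix of non-negative counts with positive marginals.
#' @return a `test_result` (statistic, df, p, method).
#' @export
chi2_independence_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_hemidel("table must be 2x2", "hemidel_stats_error")
  if (any(table < 0))
    stop_hemidel("counts must be non-negative", "hemidel_stats_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_hemidel("zero marginal in 2x2 table", "hemidel_stats_error")
  ## p-values are asymptotic; the small-expected-count warning is suppressed
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(ct$statistic, ct$parameter, ct$p.value,
              "Pearson chi-square (independence, no continuity correction)")
}

#' Pearson chi-square goodness-of-fit test
#'
#' @param observed vector of non-negative counts (total > 0).
#' @param expected_proportions probability vector of the same length,
#'   summing to 1, all cells positive.
#' @return a `test_result` with df = length(observed) - 1.
#' @export
chi2_goodness_of_fit <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions))
    stop_hemidel("observed and expected lengths differ", "hemidel_stats_error")
  if (any(expected_proportions <= 0))
    stop_hemidel("zero expected cell", "hemidel_stats_error")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop_hemidel("expected proportions must sum to 1", "hemidel_stats_error")
  if (sum(observed) <= 0)
    stop_hemidel("total observed count must be positive", "hemidel_stats_error")
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected_proportions))
  test_result(ct$statistic, ct$parameter, ct$p.value,
              "Pearson chi-square (goodness of fit)")
}

#' Compare transmission distributions between two developmental stages
#'
#' Goodness-of-fit of the later stage's observed 4-cell counts against the
#' earlier stage's cell proportions (df = 3 before any pooling).  A zero
#' cell in the reference is pooled with the same-carrier opposite-sex cell
#' before testing; if the pooled reference cell is still zero the test
#' errors.
#'
#' @param observed later-stage counts: a [transmission_counts()], 2x2
#'   matrix, or named 4-vector.
#' @param reference earlier-stage counts giving the expected proportions.
#' @return a `test_result`.
#' @export
stage_comparison <- function(observed, reference) {
  obs <- as_count_vector(observed)
  ref <- as_count_vector(reference)
  if (sum(ref) <= 0)
    stop_hemidel("reference stage has no counts", "hemidel_stats_error")
  pooled <- FALSE
  if (any(ref == 0)) {
    ## pool each zero reference cell with the same-carrier opposite-sex cell
    partner <- c(M.del = "F.del", M.wt = "F.wt", F.del = "M.del", F.wt = "M.wt")
    keep <- rep(TRUE, 4); names(keep) <- names(ref)
    for (cell in names(ref)[ref == 0]) {
      if (!keep[[cell]]) next
      p <- partner[[cell]]
      if (!keep[[p]] || ref[[p]] == 0)
        stop_hemidel("zero reference cell after pooling", "hemidel_stats_error")
      ref[[p]] <- ref[[p]] + ref[[cell]]
      obs[[p]] <- obs[[p]] + obs[[cell]]
      keep[[cell]] <- FALSE
    }
    obs <- obs[keep]; ref <- ref[keep]
    pooled <- TRUE
  }
  res <- chi2_goodness_of_fit(obs, ref / sum(ref))
  res$method <- paste0("stage comparison (later stage vs earlier-stage proportions",
                       if (pooled) ", zero cells pooled", ")")
  res
}

#' Welch's two-sample t test from group summaries
#'
#' Computes the Welch statistic and Welch-Satterthwaite degrees of freedom
#' from means, SDs and sample sizes, with a two-sided p-value.
#'
#' @param mean1,sd1,n1 summary of group 1 (n1 >= 2, sd1 > 0).
#' @param mean2,sd2,n2 summary of group 2.
#' @return a `test_result`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop_hemidel("each group needs n >= 2", "hemidel_stats_error")
  if (sd1 <= 0 || sd2 <= 0)
    stop_hemidel("group SDs must be positive", "hemidel_stats_error")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  test_result(t, df, p, "Welch's t-test (two-sided, from summaries)")
}

#' Estimate germline mosaicism from sperm-FISH carrier counts
#'
#' Each mosaic germline cell is heterozygous for the deletion and transmits
#' it to half its gametes, so the carrier-sperm fraction estimates m/2 and
#' mosaicism is twice the observed fraction (capped at 1).  The confidence
#' interval is the exact binomial (Clopper-Pearson) interval on the sperm
#' fraction, doubled and capped at 1.
#'
#' @param k carrier (deletion-bearing) spermatozoa counted.
#' @param n total spermatozoa scored (n > 0, 0 <= k <= n).
#' @param ci_level confidence level (default 0.95).
#' @return list of class `mosaicism_estimate` with `k`, `n`,
#'   `sperm_fraction`, `mosaicism`, `ci`, `ci_level`.
#' @export
mosaicism_from_sperm <- function(k, n, ci_level = 0.95) {
  if (n <= 0) stop_hemidel("n must be positive", "hemidel_stats_error")
  if (k < 0 || k > n) stop_hemidel("k must lie in [0, n]", "hemidel_stats_error")
  bt <- stats::binom.test(k, n, conf.level = ci_level)
  structure(list(k = as.integer(k), n = as.integer(n),
                 sperm_fraction = k / n,
                 mosaicism = min(1, 2 * k / n),
                 ci = pmin(1, 2 * as.numeric(bt$conf.int)),
                 ci_level = ci_level),
            class = "mosaicism_estimate")
}

#' Configuration for AI-record filtering and the lethality window
#'
#' @param gestation_days average gestation length.
#' @param cycle_days average sexual cycle length.
#' @param low_fertility_min_failures consecutive failures that mark a cow
#'   low-fertility.
#' @param adjacent_ai_max_gap_days an AI followed by another AI for the same
#'   cow within this many days is an artifact.
#' @return list of class `lethality_config`.
#' @export
lethality_config <- function(gestation_days = 285L, cycle_days = 21L,
                             low_fertility_min_failures = 3L,
                             adjacent_ai_max_gap_days = 1L) {
  vals <- c(gestation_days, cycle_days, low_fertility_min_failures,
            adjacent_ai_max_gap_days)
  if (any(vals <= 0))
    stop_hemidel("all lethality-config values must be positive",
                 "hemidel_config_error")
  structure(list(gestation_days = gestation_days, cycle_days = cycle_days,
                 low_fertility_min_failures = low_fertility_min_failures,
                 adjacent_ai_max_gap_days = adjacent_ai_max_gap_days),
            class = "lethality_config")
}

#' Filter AI failure records, discarding known artifacts
#'
#' Failure records are discarded in a fixed rule order, each discard
#' attributed to the first matching rule so category counts stay disjoint:
#' (1) superovulation-flagged records; (2) records with another AI for the
#' same cow within `adjacent_ai_max_gap_days` after them; (3) all failures
#' of low-fertility cows (>= `low_fertility_min_failures` consecutive
#' failures).  Success records are used to detect adjacency but are neither
#' retained nor discarded.
#'
#' @param records an [ai_records()] table (successes and failures).
#' @param cfg a [lethality_config()].
#' @return list with `retained` (clean failure records) and `discarded`
#'   (failures with a `reason` column).
#' @export
filter_ai_records <- function(records, cfg = lethality_config()) {
  fail <- records[records$outcome == "failure", , drop = FALSE]
  if (nrow(fail) == 0)
    return(list(retained = fail, discarded = cbind(fail, reason = character(0))))
  reason <- rep(NA_character_, nrow(fail))

  reason[fail$superovulation] <- "superovulation"

  for (i in which(is.na(reason))) {
    same_cow <- records$cow_id == fail$cow_id[i]
    gap <- records$ai_day - fail$ai_day[i]
    if (any(same_cow & gap > 0 & gap <= cfg$adjacent_ai_max_gap_days))
      reason[i] <- "adjacent_ai"
  }

  lf_cows <- unique(fail$cow_id[
    fail$consecutive_failures_for_cow >= cfg$low_fertility_min_failures])
  reason[is.na(reason) & fail$cow_id %in% lf_cows] <- "low_fertility"

  retained <- fail[is.na(reason), , drop = FALSE]
  discarded <- fail[!is.na(reason), , drop = FALSE]
  discarded$reason <- reason[!is.na(reason)]
  rownames(retained) <- rownames(discarded) <- NULL
  list(retained = retained, discarded = discarded)
}

#' Per-record gestation-length bounds and their maximum from failed AIs
#'
#' For a failed AI followed by another AI, the conceptus (if any) died at
#' most `next_ai_day - ai_day - cycle_days` days into gestation; for a
#' failed AI followed by a calving, at most
#' `next_calving_day - ai_day - gestation_days - cycle_days` days.
#' Non-positive bounds are flagged inconsistent and excluded from the
#' maximum.
#'
#' @param retained clean failure records (each with a next event), as
#'   returned by [filter_ai_records()].
#' @param cfg a [lethality_config()].
#' @return list with `bounds` (data.frame: cow_id, ai_day, next_event,
#'   bound_days, valid) and `max_bound_days` (NA when no valid bound
#'   exists).
#' @export
lethality_window <- function(retained, cfg = lethality_config()) {
  if (nrow(retained) == 0 || all(retained$next_event == "none"))
    stop_hemidel("no retained record carries a next event",
                 "hemidel_stats_error")
  rec <- retained[retained$next_event != "none", , drop = FALSE]
  gap <- as.numeric(rec$next_event_day - rec$ai_day)
  bound <- ifelse(rec$next_event == "ai",
                  gap - cfg$cycle_days,
                  gap - cfg$gestation_days - cfg$cycle_days)
  valid <- bound > 0
  bounds <- data.frame(cow_id = rec$cow_id, ai_day = rec$ai_day,
                       next_event = rec$next_event, bound_days = bound,
                       valid = valid)
  list(bounds = bounds,
       max_bound_days = if (any(valid)) max(bound[valid]) else NA_real_)
}

#' Estimate male-carrier lethality from birth counts
#'
#' Method of moments: with equal conception rates by sex, the deficit of
#' male carriers relative to female carriers at birth estimates the male
#' death probability, `lambda_hat = 1 - M.del / F.del`.
#'
#' @param birth a [transmission_counts()] (or 4-cell table) at birth.
#' @return point estimate of lambda.
#' @export
estimate_male_lethality <- function(birth) {
  v <- as_count_vector(birth)
  if (v[["F.del"]] == 0)
    stop_hemidel("no female carriers at birth; lethality not estimable",
                 "hemidel_stats_error")
  1 - v[["M.del"]] / v[["F.del"]]
}

#' Assemble the full inheritance/transmission report
#'
#' Runs, on the supplied count tables and AI records: the sex-by-phenotype
#' independence test at birth, the goodness-of-fit test against the
#' autosomal-dominant expectation of equal quarters, all pairwise stage
#' comparisons, the sperm-derived mosaicism estimate, the male-lethality
#' moment estimate, and the AI-record lethality window.
#'
#' @param birth [transmission_counts()] at birth (required).
#' @param sperm,blastocyst optional [transmission_counts()] for the earlier
#'   stages.
#' @param ai optional [ai_records()] table.
#' @param cfg a [lethality_config()].
#' @return list of class `inheritance_report`.
#' @export
inheritance_report <- function(birth, sperm = NULL, blastocyst = NULL,
                               ai = NULL, cfg = lethality_config()) {
  bv <- as_count_vector(birth)
  ## sex x carrier table: rows M/F, cols del/wt
  tab <- matrix(bv[c("M.del", "M.wt", "F.del", "F.wt")], nrow = 2, byrow = TRUE,
                dimnames = list(c("M", "F"), c("del", "wt")))
  out <- list(
    birth_counts = bv,
    independence_sex_phenotype = chi2_independence_2x2(tab),
    dominant_gof = chi2_goodness_of_fit(bv, rep(0.25, 4)),
    stage_tests = list(),
    mosaicism = NULL,
    lambda_hat = tryCatch(estimate_male_lethality(birth),
                          hemidel_error = function(e) NA_real_),
    sex_ratio = list(
      carriers = unname(bv[["M.del"]] / max(1, bv[["F.del"]])),
      non_carriers = unname(bv[["M.wt"]] / max(1, bv[["F.wt"]]))),
    lethality = NULL)
  if (!is.null(sperm) && !is.null(blastocyst)) {
    out$stage_tests <- list(
      sperm_vs_blastocyst = stage_comparison(blastocyst, sperm),
      blastocyst_vs_birth = stage_comparison(birth, blastocyst),
      sperm_vs_birth = stage_comparison(birth, sperm))
  }
  if (!is.null(sperm)) {
    sv <- as_count_vector(sperm)
    out$mosaicism <- mosaicism_from_sperm(sv[["M.del"]] + sv[["F.del"]],
                                          sum(sv))
  }
  if (!is.null(ai)) {
    flt <- filter_ai_records(ai, cfg)
    lw <- if (nrow(flt$retained) > 0 && any(flt$retained$next_event != "none"))
      lethality_window(flt$retained, cfg) else NULL
    out$lethality <- list(
      n_retained = nrow(flt$retained),
      n_discarded = nrow(flt$discarded),
      discard_reasons = table(flt$discarded$reason),
      max_bound_days = if (is.null(lw)) NA_real_ else lw$max_bound_days)
  }
  structure(out, class = "inheritance_report")
}
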