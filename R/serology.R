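#' Background-subtract ELISA readings
#'
#' Each mouse's streptavidin-only reading is subtracted from the mean of its
#' duplicate peptide-well readings, compensating inter-individual differences
#' in background binding. Negative corrected values are retained (the rank
#' test downstream is unaffected), and samples whose streptavidin background
#' exceeds the peptide signal are flagged.
#'
#' @param samples Data frame with columns `od_rep1`, `od_rep2`,
#'   `od_streptavidin` (e.g. from [simulate_serology()] or a TSV).
#' @return The input with two added columns: `corrected_od` and
#'   `high_background` (logical).
#' @examples
#' background_subtract(data.frame(od_rep1 = 0.5, od_rep2 = 0.7,
#'                                od_streptavidin = 0.2))$corrected_od  # 0.4
#' @export
background_subtract <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("od_rep1", "od_rep2", "od_streptavidin") %in%
                  names(samples)))
  if (anyNA(samples$od_rep1) || anyNA(samples$od_rep2)) {
    stop("both duplicate readings must be present for every sample")
  }
  mean_od <- (samples$od_rep1 + samples$od_rep2) / 2
  samples$corrected_od <- mean_od - samples$od_streptavidin
  samples$high_background <- samples$od_streptavidin > mean_od
  samples
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of two cohorts
#'
#' Uses the exact null distribution when `n_case * n_control <= 400` and the
#' pooled values carry no ties, and otherwise the normal approximation with
#' tie and continuity correction. The mode actually used is recorded in the
#' result.
#'
#' @param case,control Numeric vectors of (corrected) OD values; both
#'   non-empty.
#' @return List with `statistic` (the U statistic of the case group),
#'   `p_value`, `n_case`, `n_control`, `median_case`, `median_control`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
mann_whitney <- function(case, control) {
  if (length(case) == 0 || length(control) == 0) {
    stop("both groups must be non-empty")
  }
  stopifnot(is.numeric(case), is.numeric(control),
            all(is.finite(case)), all(is.finite(control)))
  pooled <- c(case, control)
  if (length(unique(pooled)) == 1L) {
    # degenerate: every observation tied; no evidence either way
    return(list(statistic = length(case) * length(control) / 2, p_value = 1,
                n_case = length(case), n_control = length(control),
                median_case = stats::median(case),
                median_control = stats::median(control),
                method = "normal_approx"))
  }
  no_ties <- !anyDuplicated(pooled)
  exact <- no_ties && (length(case) * length(control) <= 400)
  wt <- stats::wilcox.test(case, control, exact = exact, correct = TRUE,
                           alternative = "two.sided")
  list(
    statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    n_case = length(case),
    n_control = length(control),
    median_case = stats::median(case),
    median_control = stats::median(control),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Per-peptide cohort comparison of a serology table
#'
#' Background-subtracts the table and runs a two-sided Mann-Whitney test of
#' case against control corrected ODs for each peptide (optionally
#' stratified by age group).
#'
#' @param samples Serology data frame with `cohort` (`case`/`control`),
#'   `peptide_id`, the three OD columns, and optionally `age_weeks`.
#' @param stratify_by_age If `TRUE`, compare cohorts within each
#'   `age_weeks` value separately.
#' @return Data frame with one row per peptide (and age group): `peptide_id`,
#'   `age_weeks` (if stratified), `statistic`, `p_value`, `n_case`,
#'   `n_control`, `median_case`, `median_control`, `method`, `stars`.
#' @export
compare_cohorts <- function(samples, stratify_by_age = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("cohort", "peptide_id") %in% names(samples)),
            all(samples$cohort %in% c("case", "control")))
  samples <- background_subtract(samples)
  keys <- if (stratify_by_age) {
    stopifnot("age_weeks" %in% names(samples))
    unique(samples[, c("peptide_id", "age_weeks")])
  } else {
    data.frame(peptide_id = unique(samples$peptide_id),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- samples$peptide_id == keys$peptide_id[i]
    if (stratify_by_age) sel <- sel & samples$age_weeks == keys$age_weeks[i]
    sub <- samples[sel, , drop = FALSE]
    mw <- mann_whitney(sub$corrected_od[sub$cohort == "case"],
                       sub$corrected_od[sub$cohort == "control"])
    cbind(keys[i, , drop = FALSE],
          data.frame(statistic = mw$statistic, p_value = mw$p_value,
                     n_case = mw$n_case, n_control = mw$n_control,
                     median_case = mw$median_case,
                     median_control = mw$median_control,
                     method = mw$method,
                     stars = significance_stars(mw$p_value),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
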