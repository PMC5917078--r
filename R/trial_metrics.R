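# CONSORT-style flow percentages, group-comparison test selection and
# questionnaire threshold classification.

#' Trial-flow percentages from a screening log
#'
#' Computes the funnel percentages on the denominators used in trial
#' reports: eligible/screened, approached/eligible, consented/approached
#' (uptake) and completed/enrolled (retention), each to one decimal.
#' Zero denominators give `NA` rather than an error.
#'
#' @param log Flow-log data frame (see [read_flow_log()]); the funnel
#'   invariant is validated.
#' @return A list of class `flow_metrics` with the counts, percentages and
#'   group-wise enrolment/completion tables (when a `group` column exists).
#' @export
#' @examples
#' # 300 screened, 212 eligible -> 70.7% eligible
flow_metrics <- function(log) {
  log <- validate_flow_log(log)
  n_screened <- sum(log$screened)
  n_eligible <- sum(log$eligible)
  n_approached <- sum(log$approached)
  n_consented <- sum(log$consented)
  n_enrolled <- sum(log$enrolled)
  n_completed <- sum(log$completed_followup)
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else NA_real_
  out <- list(
    n_screened = n_screened, n_eligible = n_eligible,
    n_approached = n_approached, n_consented = n_consented,
    n_enrolled = n_enrolled, n_completed = n_completed,
    pct_eligible = pct(n_eligible, n_screened),
    pct_approached = pct(n_approached, n_eligible),
    pct_uptake = pct(n_consented, n_approached),
    pct_retention = pct(n_completed, n_enrolled))
  if ("group" %in% names(log)) {
    out$enrolled_by_group <- table(log$group[log$enrolled])
    out$completed_by_group <- table(log$group[log$completed_followup])
  }
  class(out) <- "flow_metrics"
  out
}

#' @export
print.flow_metrics <- function(x, ...) {
  cat(sprintf("Screened %d -> eligible %d (%.1f%%) -> approached %d (%.1f%%) -> consented %d (%.1f%%)\n",
              x$n_screened, x$n_eligible, x$pct_eligible,
              x$n_approached, x$pct_approached, x$n_consented, x$pct_uptake))
  cat(sprintf("Enrolled %d -> completed follow-up %d (%.1f%%)\n",
              x$n_enrolled, x$n_completed, x$pct_retention))
  invisible(x)
}

#' Categorical comparison with small-cell test selection
#'
#' Applies the rule "chi-square when n >= 5, Fisher exact when n < 5": the
#' Fisher exact test is selected when any cell falls below 5, otherwise a
#' Pearson chi-square (no continuity correction). `rule = "expected"`
#' switches the criterion to expected cell counts.
#'
#' @param table A two-way contingency table (matrix of non-negative integer
#'   counts with positive margins).
#' @param rule Whether the <5 rule applies to `"observed"` (default) or
#'   `"expected"` cell counts.
#' @return A list: `test` (`"chi_square"` or `"fisher_exact"`), `statistic`
#'   (chi-square statistic; `NA` for Fisher) and `p_value` (two-sided).
#' @export
select_categorical_test <- function(table, rule = c("observed", "expected")) {
  rule <- match.arg(rule)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) stop("table must hold non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero")
  crit <- if (rule == "observed") table else outer(rowSums(table), colSums(table)) / sum(table)
  if (any(crit < 5)) {
    ft <- stats::fisher.test(table)
    list(test = "fisher_exact", statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(test = "chi_square", statistic = unname(ct$statistic), p_value = ct$p.value)
  }
}

#' Two-group or k-group continuous comparison
#'
#' Independent two-sample t test (pooled variance) when two groups are
#' given, one-way ANOVA otherwise; two-sided p values, alpha reported
#' alongside. With pooled variances the two-group ANOVA F equals t squared.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector aligned with `values` (>= 2 groups, each
#'   with >= 2 observations).
#' @param alpha Significance level carried in the result (default 0.05).
#' @return A list: `test` (`"t_test"` or `"anova"`), `statistic`, `df`,
#'   `p_value`, `alpha`.
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- as.factor(group)
  if (length(values) != length(group)) stop("values and group lengths differ")
  sizes <- table(group)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("insufficient data: group '", names(sizes)[sizes < 2][1], "' has fewer than 2 values")
  if (length(sizes) == 2) {
    tt <- stats::t.test(values ~ group, var.equal = TRUE)
    list(test = "t_test", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, alpha = alpha)
  } else {
    ft <- stats::oneway.test(values ~ group, var.equal = TRUE)
    list(test = "anova", statistic = unname(ft$statistic),
         df = unname(ft$parameter), p_value = ft$p.value, alpha = alpha)
  }
}

#' Questionnaire and anthropometric threshold bands
#'
#' Band classifiers for the instruments used to describe the sample:
#' * `hads_band()` — Hospital Anxiety and Depression Scale subscale score
#'   (0-21): normal 0-7, borderline 8-10, abnormal 11-21;
#' * `fatigue_severe()` — FACIT-Fatigue score (0-52): severe when < 30;
#' * `sppb_limited()` — Short Physical Performance Battery (0-12): mobility
#'   limitation when < 10;
#' * `bmi_class()` — body-mass index (kg/m^2): underweight < 18.5, normal
#'   [18.5, 25), overweight [25, 30], obese > 30. The printed overweight
#'   and obese bands overlap at exactly 30; the partition keeps 30 in the
#'   overweight band.
#'
#' Out-of-range scores are an error.
#'
#' @param score Numeric vector of instrument scores.
#' @return A factor of band labels.
#' @name descriptor_bands
NULL

check_range <- function(score, lo, hi, what) {
  if (any(is.na(score) | score < lo | score > hi))
    stop(what, " score out of range [", lo, ", ", hi, "]")
}

#' @rdname descriptor_bands
#' @export
hads_band <- function(score) {
  check_range(score, 0, 21, "HADS")
  cut(score, breaks = c(-Inf, 7, 10, 21), labels = c("normal", "borderline", "abnormal"))
}

#' @rdname descriptor_bands
#' @export
fatigue_severe <- function(score) {
  check_range(score, 0, 52, "fatigue")
  score < 30
}

#' @rdname descriptor_bands
#' @export
sppb_limited <- function(score) {
  check_range(score, 0, 12, "SPPB")
  score < 10
}

#' @rdname descriptor_bands
#' @export
bmi_class <- function(score) {
  if (any(is.na(score) | score <= 0)) stop("BMI must be positive")
  out <- ifelse(score < 18.5, "underweight",
                ifelse(score < 25, "normal",
                       ifelse(score <= 30, "overweight", "obese")))
  factor(out, levels = c("underweight", "normal", "overweight", "obese"))
}

#' Classify a patient's descriptive measures
#'
#' @param hads_anxiety,hads_depression HADS subscale scores (0-21), optional.
#' @param fatigue FACIT-Fatigue score (0-52), optional.
#' @param sppb SPPB score (0-12), optional.
#' @param bmi Body-mass index in kg/m^2, optional.
#' @return A list with one entry per supplied instrument.
#' @seealso [descriptor_bands]
#' @export
classify_descriptors <- function(hads_anxiety = NULL, hads_depression = NULL,
                                 fatigue = NULL, sppb = NULL, bmi = NULL) {
  out <- list()
  if (!is.null(hads_anxiety)) out$hads_anxiety <- hads_band(hads_anxiety)
  if (!is.null(hads_depression)) out$hads_depression <- hads_band(hads_depression)
  if (!is.null(fatigue)) out$fatigue_severe <- fatigue_severe(fatigue)
  if (!is.null(sppb)) out$sppb_limited <- sppb_limited(sppb)
  if (!is.null(bmi)) out$bmi_class <- bmi_class(bmi)
  out
}
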