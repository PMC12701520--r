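#' 2x2 contingency table of quartile group by LATE-NC status
#'
#' @param a,b,c_,d counts: `a` = Q1 & LATE+, `b` = Q1 & LATE-, `c_` = Q3-Q4
#'   & LATE+, `d` = Q3-Q4 & LATE-.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c_, d) {
  counts <- c(a = a, b = b, c = c_, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_lateq("counts must be non-negative integers")
  }
  structure(as.list(counts), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2, 2,
         dimnames = list(quartile = c("Q1", "Q3-Q4"),
                         late = c("LATE+", "LATE-")))
}

#' Build the autopsy quartile x LATE-NC contingency table
#'
#' Restricts to intermediate/high ADNC subjects, classifies adjusted HV
#' against the amyloid-positive-derived cut-offs (Q1: strictly below `q25`;
#' Q3-Q4: strictly above `q50`; the Q2 band is excluded), and applies the
#' LATE-NC rule TDP-43 stage >= `late_stage_min`.
#'
#' @param autopsy_subjects data frame with `hv_adjusted`, `late_nc_stage`,
#'   `adnc_level` and `subject_id` columns.
#' @param cutoffs a [compute_quartile_cutoffs()] result.
#' @param late_stage_min minimum TDP-43 stage counting as LATE-NC+ (default 1).
#' @return a [contingency_2x2()] with an `"n_excluded_q2"` attribute.
#' @export
contingency_from_groups <- function(autopsy_subjects, cutoffs,
                                    late_stage_min = 1) {
  stopifnot(inherits(cutoffs, "quartile_cutoffs"))
  d <- autopsy_subjects[autopsy_subjects$adnc_level %in%
                          c("intermediate", "high"), , drop = FALSE]
  bad <- !is.finite(d$late_nc_stage)
  if (any(bad)) {
    stop_lateq("missing LATE-NC stage for subject(s): %s",
               paste(d$subject_id[bad], collapse = ", "))
  }
  if (any(!is.finite(d$hv_adjusted))) {
    stop_lateq("missing adjusted HV in autopsy table")
  }
  late <- d$late_nc_stage >= late_stage_min
  q1 <- d$hv_adjusted < cutoffs$q25
  q34 <- d$hv_adjusted > cutoffs$q50
  tab <- contingency_2x2(sum(q1 & late), sum(q1 & !late),
                         sum(q34 & late), sum(q34 & !late))
  attr(tab, "n_excluded_q2") <- sum(!q1 & !q34)
  tab
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided p value by probability-mass ordering (summing noncentral-at-1
#' hypergeometric probabilities of tables as or more extreme than the
#' observed one) and the conditional maximum-likelihood odds ratio under
#' Fisher's noncentral hypergeometric distribution (the estimand reported by
#' [stats::fisher.test()]); the estimate is `Inf` when `b * c = 0` and `0`
#' when `a * d = 0`.
#'
#' @param table a [contingency_2x2()] or 2x2 matrix.
#' @return list with `p` (two-sided) and `or` (conditional-MLE odds ratio).
#' @export
fisher_exact <- function(table) {
  m <- if (inherits(table, "contingency_2x2")) as.matrix(table)
       else as.matrix(table)
  if (any(m < 0)) stop_lateq("counts must be non-negative")
  ft <- fisher.test(m)
  list(p = ft$p.value, or = unname(ft$estimate))
}

#' LATE-NC+ frequencies per quartile group
#'
#' @param table a [contingency_2x2()].
#' @return named vector of percentages: `q1` = `100 * a / (a + b)`,
#'   `q3q4` = `100 * c / (c + d)`.
#' @export
enrichment_frequencies <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if ((table$a + table$b) == 0 || (table$c + table$d) == 0) {
    stop_lateq("empty quartile row")
  }
  c(q1 = 100 * table$a / (table$a + table$b),
    q3q4 = 100 * table$c / (table$c + table$d))
}

#' ROC curve for low-volume screening of LATE-NC
#'
#' Direction convention: lower adjusted HV is more suspect, so a subject is
#' called positive when `score <= threshold`. The curve sweeps all unique
#' score values (plus a below-all sentinel); the area under the curve is
#' computed by the trapezoid rule over the resulting operating points, which
#' with tied scores grouped equals the midrank (Wilcoxon rank-sum)
#' concordance probability.
#'
#' @param scores numeric scores (adjusted HV, mm^3).
#' @param labels logical or 0/1 LATE-NC+ indicator.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, and the Youden-optimal operating point.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop_lateq("both classes must be present")
  }
  if (any(!is.finite(scores))) stop_lateq("non-finite scores")
  thr <- c(min(scores) - 1, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[labels] <= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] > t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_threshold = thr[best],
                 youden_sens = sens[best], youden_spec = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC=%.3f  Youden threshold=%.4g (sens=%.2f, spec=%.2f)\n",
              x$auc, x$youden_threshold, x$youden_sens, x$youden_spec))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Maximizes `J = sensitivity + specificity - 1`; ties are broken toward the
#' more specific threshold.
#'
#' @param roc a [roc_curve()] result.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  list(threshold = roc$youden_threshold,
       sensitivity = roc$youden_sens,
       specificity = roc$youden_spec)
}

#' Sensitivity and specificity at a fixed threshold
#'
#' `sensitivity = P(score <= threshold | LATE+)`,
#' `specificity = P(score > threshold | LATE-)`.
#'
#' @inheritParams roc_curve
#' @param threshold score cut-off.
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec_at_threshold <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop_lateq("both classes must be present")
  c(sensitivity = mean(scores[labels] <= threshold),
    specificity = mean(scores[!labels] > threshold))
}
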