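#' Minimum-hemisphere hippocampal volume
#'
#' LATE-NC is frequently asymmetric, so stratification uses the total
#' hippocampal volume (anterior + posterior) of the more atrophic, i.e.
#' smaller, hemisphere rather than the mean of the two.
#'
#' @param hv_left,hv_right per-hemisphere total hippocampal volumes (mm^3);
#'   vectors are accepted.
#' @return `pmin(hv_left, hv_right)`.
#' @export
min_hemisphere_hv <- function(hv_left, hv_right) {
  if (any(!is.finite(hv_left)) || any(!is.finite(hv_right))) {
    stop_lateq("missing hemisphere volume: both sides are required (no fallback to the other hemisphere)")
  }
  if (any(hv_left <= 0) || any(hv_right <= 0)) {
    stop_lateq("hemisphere volumes must be > 0")
  }
  pmin(hv_left, hv_right)
}

#' Fit the cognitively-unimpaired volume-adjustment regression
#'
#' Ordinary least squares of minimum-hemisphere hippocampal volume on age at
#' MRI and intracranial volume (ICV), fitted in cognitively unimpaired (CU)
#' subjects only. Sex is deliberately not a covariate: ICV accounts for sex
#' differences in head size. The CU covariate means are stored so adjustment
#' re-centres other subjects at the CU reference.
#'
#' @param cu_subjects data frame with columns `hv_left_total`,
#'   `hv_right_total`, `age_mri`, `icv` (CU subjects only).
#' @return an object of class `cu_fit`: intercept, `beta_age` (mm^3/year),
#'   `beta_icv` (mm^3/mm^3), CU covariate means, `n_cu`, `resid_sd`.
#' @export
fit_cu_adjustment <- function(cu_subjects) {
  need <- c("hv_left_total", "hv_right_total", "age_mri", "icv")
  miss <- setdiff(need, names(cu_subjects))
  if (length(miss)) stop_lateq("missing columns: %s", paste(miss, collapse = ", "))
  n <- nrow(cu_subjects)
  if (n < 3) stop_lateq("need >= 3 CU subjects to fit the adjustment (got %d)", n)
  hv <- min_hemisphere_hv(cu_subjects$hv_left_total, cu_subjects$hv_right_total)
  X <- cbind(1, cu_subjects$age_mri, cu_subjects$icv)
  if (qr(X)$rank < 3) {
    stop_lateq("singular design: CU ages/ICVs do not span a full-rank covariate matrix")
  }
  fit <- lm(hv ~ age_mri + icv, data = cu_subjects)
  res <- residuals(fit)
  structure(list(
    intercept = unname(coef(fit)[1]),
    beta_age = unname(coef(fit)["age_mri"]),
    beta_icv = unname(coef(fit)["icv"]),
    mean_age_cu = mean(cu_subjects$age_mri),
    mean_icv_cu = mean(cu_subjects$icv),
    n_cu = n,
    resid_sd = if (n > 3) sqrt(sum(res^2) / (n - 3)) else 0), class = "cu_fit")
}

#' @export
print.cu_fit <- function(x, ...) {
  cat(sprintf("<cu_fit> n_cu=%d  beta_age=%.3f mm^3/yr  beta_icv=%.3g  resid_sd=%.1f mm^3\n",
              x$n_cu, x$beta_age, x$beta_icv, x$resid_sd))
  invisible(x)
}

#' Age/ICV-adjust a hippocampal volume
#'
#' Removes the CU-estimated covariate structure while keeping the mm^3
#' scale: `adjusted = raw - beta_age * (age - mean_age_cu) -
#' beta_icv * (icv - mean_icv_cu)`. A subject at the CU covariate means is
#' unchanged.
#'
#' @param raw_hv raw minimum-hemisphere HV (mm^3); vectorized.
#' @param age age at MRI (years).
#' @param icv intracranial volume (mm^3).
#' @param fit a [fit_cu_adjustment()] result.
#' @return adjusted HV (mm^3).
#' @export
adjust_hv <- function(raw_hv, age, icv, fit) {
  stopifnot(inherits(fit, "cu_fit"))
  raw_hv - fit$beta_age * (age - fit$mean_age_cu) -
    fit$beta_icv * (icv - fit$mean_icv_cu)
}

#' Quartile cut-offs from the amyloid-positive distribution
#'
#' The 25th and 50th empirical percentiles of adjusted HV among
#' amyloid-positive cognitively impaired subjects, using the
#' linear-interpolation quantile convention (R type 7).
#'
#' @param adjusted_hvs adjusted HVs (mm^3) of the amyloid-positive CI
#'   reference sample; n >= 8 finite values.
#' @param type quantile type passed to [stats::quantile()] (default 7,
#'   linear interpolation between order statistics).
#' @return object of class `quartile_cutoffs`: `q25`, `q50`, `n_ref`.
#' @export
compute_quartile_cutoffs <- function(adjusted_hvs, type = 7) {
  x <- adjusted_hvs[is.finite(adjusted_hvs)]
  if (length(x) < length(adjusted_hvs)) {
    stop_lateq("non-finite adjusted HVs in the quartile reference sample")
  }
  if (length(x) < 8) {
    stop_lateq("need >= 8 adjusted HVs to derive quartile cut-offs (got %d)", length(x))
  }
  q <- unname(quantile(x, c(0.25, 0.5), type = type))
  structure(list(q25 = q[1], q50 = q[2], n_ref = length(x)),
            class = "quartile_cutoffs")
}

#' @export
print.quartile_cutoffs <- function(x, ...) {
  cat(sprintf("<quartile_cutoffs> q25=%.1f mm^3  q50=%.1f mm^3  (n_ref=%d)\n",
              x$q25, x$q50, x$n_ref))
  invisible(x)
}

#' Assign quartile-based group labels
#'
#' Amyloid-positive CI subjects: adjusted HV strictly below `q25` ->
#' `AD+sLATE+`; strictly above `q50` -> `AD+sLATE-`; in `[q25, q50]` ->
#' `EXCLUDED_Q2` (boundary values fall in the excluded band, honouring the
#' strict `percentile < 25` / `percentile > 50` definitions).
#' Amyloid-negative CI subjects below the *same* amyloid-positive-derived
#' `q25` -> `AD-sLATE+`; otherwise `UNCLASSIFIED`. Amyloid-negative CU ->
#' `Abeta-CU`; amyloid-positive CU -> `UNCLASSIFIED`.
#'
#' @param adjusted_hv adjusted HV per subject (mm^3).
#' @param abeta_positive logical amyloid status per subject; must be
#'   non-missing for every CI subject.
#' @param impaired logical: CI (`TRUE`) vs CU (`FALSE`).
#' @param cutoffs a [compute_quartile_cutoffs()] result.
#' @param subject_id optional ids used in error messages.
#' @return factor of labels in
#'   `c("AD+sLATE-","AD+sLATE+","AD-sLATE+","Abeta-CU","EXCLUDED_Q2","UNCLASSIFIED")`.
#' @export
assign_groups <- function(adjusted_hv, abeta_positive, impaired, cutoffs,
                          subject_id = NULL) {
  stopifnot(inherits(cutoffs, "quartile_cutoffs"))
  n <- length(adjusted_hv)
  stopifnot(length(abeta_positive) == n, length(impaired) == n)
  ids <- subject_id %||% as.character(seq_len(n))
  bad <- impaired & is.na(abeta_positive)
  if (any(bad)) {
    stop_lateq("missing amyloid status for CI subject(s): %s",
               paste(ids[bad], collapse = ", "))
  }
  if (any(impaired & !is.finite(adjusted_hv))) {
    stop_lateq("missing adjusted HV for CI subject(s): %s",
               paste(ids[impaired & !is.finite(adjusted_hv)], collapse = ", "))
  }
  lab <- rep("UNCLASSIFIED", n)
  ci_pos <- impaired & !is.na(abeta_positive) & abeta_positive
  ci_neg <- impaired & !is.na(abeta_positive) & !abeta_positive
  lab[ci_pos & adjusted_hv < cutoffs$q25] <- "AD+sLATE+"
  lab[ci_pos & adjusted_hv > cutoffs$q50] <- "AD+sLATE-"
  lab[ci_pos & adjusted_hv >= cutoffs$q25 & adjusted_hv <= cutoffs$q50] <-
    "EXCLUDED_Q2"
  lab[ci_neg & adjusted_hv < cutoffs$q25] <- "AD-sLATE+"
  lab[!impaired & !is.na(abeta_positive) & !abeta_positive] <- "Abeta-CU"
  factor(lab, levels = c(GROUPS, "EXCLUDED_Q2", "UNCLASSIFIED"))
}

#' Stratify a subject table end-to-end
#'
#' Convenience wrapper chaining the full stratification stage: fits the CU
#' adjustment regression on amyloid-negative CU subjects, adjusts everyone's
#' minimum-hemisphere HV, derives quartile cut-offs from amyloid-positive CI
#' subjects, and assigns group labels.
#'
#' @param subjects subject data frame (see [generate_cohort()] /
#'   [read_subject_table()] for the column contract). Amyloid status is taken
#'   from `amyloid_suvr` + `tracer` via [amyloid_status()].
#' @param quantile_type quantile convention (see [compute_quartile_cutoffs()]).
#' @return list with `subjects` (input plus `hv_min`, `hv_adjusted`,
#'   `abeta_positive`, `group_assigned` columns), `cu_fit`, `cutoffs`.
#' @export
stratify_cohort <- function(subjects, quantile_type = 7) {
  abeta <- amyloid_status(subjects$amyloid_suvr, subjects$tracer)
  impaired <- subjects$status == "CI"
  cu_ref <- subjects[!impaired & !abeta, , drop = FALSE]
  fit <- fit_cu_adjustment(cu_ref)
  hv_min <- min_hemisphere_hv(subjects$hv_left_total, subjects$hv_right_total)
  hv_adj <- adjust_hv(hv_min, subjects$age_mri, subjects$icv, fit)
  cutoffs <- compute_quartile_cutoffs(hv_adj[impaired & abeta],
                                      type = quantile_type)
  subjects$hv_min <- hv_min
  subjects$hv_adjusted <- hv_adj
  subjects$abeta_positive <- abeta
  subjects$group_assigned <- assign_groups(hv_adj, abeta, impaired, cutoffs,
                                           subjects$subject_id)
  list(subjects = subjects, cu_fit = fit, cutoffs = cutoffs)
}
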