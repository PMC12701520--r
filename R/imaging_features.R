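#' Hippocampal asymmetry index
#'
#' `abs((L - R) / (L + R)) * 200`: the absolute left-right volume difference
#' as a percentage of the mean hemisphere volume. Higher values indicate
#' greater asymmetry; range `[0, 200]`. Symmetric in its arguments and
#' invariant to scaling both hemispheres by a common positive factor.
#'
#' @param left,right hemisphere volumes (mm^3), both `>= 0`; vectorized.
#' @return percent-scale asymmetry index.
#' @export
asymmetry_index <- function(left, right) {
  if (any(left < 0) || any(right < 0)) stop_lateq("volumes must be >= 0")
  if (any(left + right == 0)) {
    stop_lateq("asymmetry index undefined when L + R = 0")
  }
  abs((left - right) / (left + right)) * 200
}

#' ERC/PHC thickness ratio
#'
#' Ratio of entorhinal (ERC) to parahippocampal (PHC) cortical thickness.
#' Lower ratios indicate disproportionate anterior medial temporal lobe
#' thinning, a pattern suggestive of TDP-43 co-pathology.
#'
#' @param erc_thickness,phc_thickness thickness in mm; PHC must be > 0.
#' @return `erc / phc`; vectorized.
#' @export
erc_phc_ratio <- function(erc_thickness, phc_thickness) {
  if (any(phc_thickness <= 0)) {
    stop_lateq("ERC/PHC ratio undefined for PHC thickness <= 0")
  }
  erc_thickness / phc_thickness
}

#' Amyloid-PET positivity
#'
#' Tracer-specific SUVR thresholds: positive iff SUVR >= 1.11 for
#' florbetapir and >= 1.08 for florbetaben. Unknown tracers are an error
#' (there is no default threshold).
#'
#' @param suvr amyloid-PET SUVR (> 0); vectorized.
#' @param tracer `"florbetapir"` or `"florbetaben"` (recycled if scalar).
#' @return logical: `TRUE` = amyloid-positive.
#' @export
amyloid_status <- function(suvr, tracer) {
  if (any(suvr <= 0)) stop_lateq("SUVR must be > 0")
  tracer <- rep_len(as.character(tracer), length(suvr))
  known <- c(florbetapir = 1.11, florbetaben = 1.08)
  bad <- !(tracer %in% names(known))
  if (any(bad)) {
    stop_lateq("unknown amyloid tracer(s): %s (no default threshold)",
               paste(unique(tracer[bad]), collapse = ", "))
  }
  unname(suvr >= known[tracer])
}

#' Fit a two-component Gaussian mixture to a cohort's ROI tau SUVRs
#'
#' Separates non-pathologic from pathologic tau-PET signal per region of
#' interest by fitting a univariate two-component unequal-variance Gaussian
#' mixture (EM via mclust, whose hierarchical-clustering initialisation is
#' deterministic, so no random restarts are needed). Components are ordered
#' by mean: the higher-mean component is pathologic. Fitting is cohort-wise
#' so posteriors are comparable across subjects.
#'
#' @param suvr numeric vector of one ROI's SUVRs across the cohort (>= 20
#'   finite values).
#' @return object of class `tau_gmm_fit`: `mu_neg`, `sd_neg`, `mu_pos`,
#'   `sd_pos`, `weight_pos`, `converged`. A failed or degenerate EM fit is
#'   returned with `converged = FALSE` (downstream treats its posteriors as 0).
#' @export
fit_tau_gmm <- function(suvr) {
  x <- suvr[is.finite(suvr)]
  if (length(x) < 20) {
    stop_lateq("need >= 20 finite SUVRs to fit a mixture (got %d)", length(x))
  }
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters) ||
      any(!is.finite(fit$parameters$mean))) {
    return(structure(list(mu_neg = NA_real_, sd_neg = NA_real_,
                          mu_pos = NA_real_, sd_pos = NA_real_,
                          weight_pos = NA_real_, converged = FALSE),
                     class = "tau_gmm_fit"))
  }
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  pro <- fit$parameters$pro
  o <- order(mu)
  converged <- all(is.finite(c(mu, sdv, pro))) && all(sdv > 0) &&
    all(pro > 0) && all(pro < 1)
  structure(list(mu_neg = mu[o[1]], sd_neg = sdv[o[1]],
                 mu_pos = mu[o[2]], sd_pos = sdv[o[2]],
                 weight_pos = pro[o[2]], converged = converged),
            class = "tau_gmm_fit")
}

#' Pathologic posterior probability under a fitted tau mixture
#'
#' @param suvr SUVR value(s).
#' @param fit a [fit_tau_gmm()] result. Non-converged fits give posterior 0.
#' @return posterior probability in `[0, 1]` that the signal is pathologic.
#' @export
tau_pathologic_posterior <- function(suvr, fit) {
  stopifnot(inherits(fit, "tau_gmm_fit"))
  if (!isTRUE(fit$converged)) return(rep(0, length(suvr)))
  d_pos <- fit$weight_pos * dnorm(suvr, fit$mu_pos, fit$sd_pos)
  d_neg <- (1 - fit$weight_pos) * dnorm(suvr, fit$mu_neg, fit$sd_neg)
  p <- d_pos / (d_pos + d_neg)
  p[!is.finite(p)] <- as.numeric(suvr[!is.finite(p)] > fit$mu_neg)
  pmin(pmax(p, 0), 1)
}

#' Tau-MaX: posterior-weighted tau extent and magnitude
#'
#' A combined measure of tau extent and magnitude:
#' `sum over ROIs of p_r * max(0, (SUVR_r - mu_neg_r) / sd_neg_r)`, where
#' `p_r` is the pathologic posterior from the cohort-wise Gaussian mixture
#' and the magnitude term is the SUVR elevation above the non-pathologic
#' component in its own SD units. Extent enters through how many ROIs carry
#' non-negligible posterior. Non-negative and monotone non-decreasing in any
#' single ROI's SUVR.
#'
#' @param roi_suvrs named numeric vector, one SUVR per ROI.
#' @param fits named list of [fit_tau_gmm()] results (one per ROI).
#' @param roi_set character vector of ROI names to sum over (e.g.
#'   `tau_roi_sets()$global` or `$temporal`).
#' @return unitless Tau-MaX value.
#' @export
tau_max <- function(roi_suvrs, fits, roi_set) {
  missing_vals <- setdiff(roi_set, names(roi_suvrs))
  missing_fits <- setdiff(roi_set, names(fits))
  if (length(missing_vals) || length(missing_fits)) {
    stop_lateq("missing ROI value(s)/fit(s): %s",
               paste(union(missing_vals, missing_fits), collapse = ", "))
  }
  total <- 0
  for (r in roi_set) {
    f <- fits[[r]]
    if (!isTRUE(f$converged)) next
    p <- tau_pathologic_posterior(roi_suvrs[[r]], f)
    total <- total + p * max(0, (roi_suvrs[[r]] - f$mu_neg) / f$sd_neg)
  }
  total
}

#' Compute LATE-suggestive imaging features for a subject table
#'
#' Adds the hippocampal asymmetry index (raw volumes), the minimum-hemisphere
#' ERC/PHC thickness ratio, amyloid positivity, and Gaussian-mixture Tau-MaX
#' (global and temporal meta-ROI) computed from the cohort-wise per-ROI
#' mixture fits.
#'
#' @param subjects subject data frame with hemisphere HV columns, thickness
#'   columns (`erc_thk_left`, ..., `phc_thk_right`), `amyloid_suvr`,
#'   `tracer`, and per-ROI `tau_*` columns.
#' @param hemisphere `"min"` (default; matches the HV convention) or
#'   `"mean"` for the ERC/PHC ratio.
#' @return list with `features` (data frame: `subject_id`,
#'   `asymmetry_index`, `erc_phc_ratio`, `abeta_positive`,
#'   `taumax_global_gmm`, `taumax_temporal_gmm`) and `gmm_fits`.
#' @export
compute_imaging_features <- function(subjects, hemisphere = c("min", "mean")) {
  hemisphere <- match.arg(hemisphere)
  combine <- if (hemisphere == "min") pmin else function(a, b) (a + b) / 2
  erc <- combine(subjects$erc_thk_left, subjects$erc_thk_right)
  phc <- combine(subjects$phc_thk_left, subjects$phc_thk_right)
  rois <- tau_roi_sets()
  fits <- lapply(setNames(rois$global, rois$global), function(r) {
    fit_tau_gmm(subjects[[paste0("tau_", r)]])
  })
  tau_mat <- as.matrix(subjects[, paste0("tau_", rois$global), drop = FALSE])
  colnames(tau_mat) <- rois$global
  tmax_g <- apply(tau_mat, 1, tau_max, fits = fits, roi_set = rois$global)
  tmax_t <- apply(tau_mat, 1, tau_max, fits = fits, roi_set = rois$temporal)
  features <- data.frame(
    subject_id = subjects$subject_id,
    asymmetry_index = asymmetry_index(subjects$hv_left_total,
                                      subjects$hv_right_total),
    erc_phc_ratio = erc_phc_ratio(erc, phc),
    abeta_positive = amyloid_status(subjects$amyloid_suvr, subjects$tracer),
    taumax_global_gmm = tmax_g,
    taumax_temporal_gmm = tmax_t,
    stringsAsFactors = FALSE)
  list(features = features, gmm_fits = fits)
}
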