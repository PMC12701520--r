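#' Tau-PET region-of-interest sets
#'
#' Named ROI sets used for per-ROI tau SUVR columns and Tau-MaX summaries:
#' a temporal meta-ROI (early Braak-region composite) and a global cortical
#' set that extends it with lateral/posterior association regions.
#'
#' @return a list with character vectors `temporal` and `global`.
#' @export
tau_roi_sets <- function() {
  temporal <- c("entorhinal", "amygdala", "parahippocampal", "fusiform",
                "inferior_temporal", "middle_temporal")
  global <- c(temporal, "lateral_occipital", "precuneus",
              "posterior_cingulate", "supramarginal", "lateral_frontal",
              "lateral_parietal")
  list(temporal = temporal, global = global)
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the published group structure of an ADNI-like AD
#' continuum cohort: adjusted hippocampal volume (HV) means/SDs and Tau-MaX
#' means/SDs per group, higher left-right asymmetry in the suspected-LATE
#' groups, anterior-predominant medial temporal lobe (MTL) cortical thinning
#' in those groups, and group-specific cognitive intercepts and slopes.
#' Group labels are `"AD+sLATE-"` (amyloid-positive, higher HV),
#' `"AD+sLATE+"` (amyloid-positive, lowest-quartile HV), `"AD-sLATE+"`
#' (amyloid-negative, lowest-quartile HV) and `"Abeta-CU"` (amyloid-negative
#' cognitively unimpaired reference).
#'
#' @param group_sizes named integer vector, subjects per group.
#' @param hv_group_means,hv_group_sds adjusted-scale minimum-hemisphere HV
#'   mean and SD per group (mm^3).
#' @param asymmetry_pct_by_group mean absolute left-right percent volume
#'   difference per group (the generator draws half-normal deviates with this
#'   mean).
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param age_mean,age_sd age at MRI distribution (years).
#' @param beta_age,beta_icv true adjustment coefficients used to map
#'   adjusted-scale HV to raw HV (mm^3/year, mm^3/mm^3).
#' @param taumax_group_means,taumax_group_sds global Tau-MaX mean and SD per
#'   group (unitless).
#' @param taumax_temporal_means,taumax_temporal_sds temporal meta-ROI Tau-MaX
#'   mean and SD per group.
#' @param education_group_means,education_sd years of education.
#' @param p_male probability of male sex.
#' @param cognitive_intercepts,cognitive_slopes group x domain matrices
#'   (SD-units and SD-units/year) for domains memory, exec, language.
#' @param residual_sds per-domain visit-level residual SD (SD-units).
#' @param random_intercept_sd,random_slope_sd subject random-effect SDs for
#'   the cognitive trajectories.
#' @param visit_schedule visit times in years from baseline, strictly
#'   increasing.
#' @param subregion_fractions list controlling the split of hemisphere HV
#'   into anterior/posterior hippocampus (`ah_fraction`), the amygdala-to-HV
#'   ratio, base MTL cortical thicknesses (mm) and per-group thickness scale
#'   factors (anterior-predominant thinning in suspected-LATE groups).
#' @param enrichment_odds Q1 vs Q3-Q4 odds ratio linking low adjusted HV to
#'   LATE neuropathologic change in the autopsy arm.
#' @param autopsy_hv_mean,autopsy_hv_sd adjusted HV distribution in the
#'   autopsy arm (mm^3).
#' @param autopsy_late_prevalence marginal LATE-NC+ prevalence targeted by
#'   the autopsy-arm calibration.
#' @param seed default master seed.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    group_sizes = c("AD+sLATE-" = 115, "AD+sLATE+" = 58,
                    "AD-sLATE+" = 20, "Abeta-CU" = 193),
    hv_group_means = c("AD+sLATE-" = 3194, "AD+sLATE+" = 2237,
                       "AD-sLATE+" = 2075, "Abeta-CU" = 3282),
    hv_group_sds = c("AD+sLATE-" = 241, "AD+sLATE+" = 229,
                     "AD-sLATE+" = 292, "Abeta-CU" = 361),
    asymmetry_pct_by_group = c("AD+sLATE-" = 4, "AD+sLATE+" = 10,
                               "AD-sLATE+" = 10, "Abeta-CU" = 3),
    icv_mean = 1.45e6, icv_sd = 1.4e5,
    age_mean = 75, age_sd = 7.5,
    beta_age = -25, beta_icv = 1.5e-3,
    taumax_group_means = c("AD+sLATE-" = 12.7, "AD+sLATE+" = 30.4,
                           "AD-sLATE+" = 2.5, "Abeta-CU" = 0.4),
    taumax_group_sds = c("AD+sLATE-" = 18.6, "AD+sLATE+" = 28.2,
                         "AD-sLATE+" = 3.9, "Abeta-CU" = 1.7),
    taumax_temporal_means = c("AD+sLATE-" = 21.4, "AD+sLATE+" = 44.2,
                              "AD-sLATE+" = 5.5, "Abeta-CU" = 0.5),
    taumax_temporal_sds = c("AD+sLATE-" = 26.0, "AD+sLATE+" = 30.9,
                            "AD-sLATE+" = 7.8, "Abeta-CU" = 2.0),
    education_group_means = c("AD+sLATE-" = 16.1, "AD+sLATE+" = 15.3,
                              "AD-sLATE+" = 17.4, "Abeta-CU" = 16.3),
    education_sd = 2.5,
    p_male = 0.55,
    cognitive_intercepts = rbind(
      "AD+sLATE-" = c(memory = -0.7, exec = -0.6, language = -0.5),
      "AD+sLATE+" = c(memory = -1.3, exec = -1.0, language = -0.8),
      "AD-sLATE+" = c(memory = -1.1, exec = -0.8, language = -0.9),
      "Abeta-CU"  = c(memory =  0.0, exec =  0.0, language =  0.0)),
    cognitive_slopes = rbind(
      "AD+sLATE-" = c(memory = -0.15, exec = -0.18, language = -0.12),
      "AD+sLATE+" = c(memory = -0.30, exec = -0.35, language = -0.30),
      "AD-sLATE+" = c(memory = -0.28, exec = -0.18, language = -0.14),
      "Abeta-CU"  = c(memory = -0.02, exec = -0.02, language = -0.01)),
    residual_sds = c(memory = 0.25, exec = 0.25, language = 0.25),
    random_intercept_sd = 0.30,
    random_slope_sd = 0.06,
    visit_schedule = 0:5,
    subregion_fractions = list(
      ah_fraction = 0.56,
      amygdala_to_hv = 0.55,
      thickness_base = c(erc = 3.2, ba35 = 2.9, ba36 = 3.0, phc = 2.7),
      thickness_scale = rbind(
        "AD+sLATE-" = c(erc = 0.93, ba35 = 0.93, ba36 = 0.96, phc = 0.97),
        "AD+sLATE+" = c(erc = 0.80, ba35 = 0.84, ba36 = 0.92, phc = 0.96),
        "AD-sLATE+" = c(erc = 0.80, ba35 = 0.85, ba36 = 0.93, phc = 0.97),
        "Abeta-CU"  = c(erc = 1.00, ba35 = 1.00, ba36 = 1.00, phc = 1.00)),
      thickness_cv = 0.06),
    enrichment_odds = 13.8,
    autopsy_hv_mean = 2900, autopsy_hv_sd = 450,
    autopsy_late_prevalence = 0.48,
    seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes, hv_group_means = hv_group_means,
    hv_group_sds = hv_group_sds,
    asymmetry_pct_by_group = asymmetry_pct_by_group,
    icv_mean = icv_mean, icv_sd = icv_sd,
    age_mean = age_mean, age_sd = age_sd,
    beta_age = beta_age, beta_icv = beta_icv,
    taumax_group_means = taumax_group_means,
    taumax_group_sds = taumax_group_sds,
    taumax_temporal_means = taumax_temporal_means,
    taumax_temporal_sds = taumax_temporal_sds,
    education_group_means = education_group_means,
    education_sd = education_sd, p_male = p_male,
    cognitive_intercepts = cognitive_intercepts,
    cognitive_slopes = cognitive_slopes,
    residual_sds = residual_sds,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    visit_schedule = visit_schedule,
    subregion_fractions = subregion_fractions,
    enrichment_odds = enrichment_odds,
    autopsy_hv_mean = autopsy_hv_mean, autopsy_hv_sd = autopsy_hv_sd,
    autopsy_late_prevalence = autopsy_late_prevalence,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$group_sizes < 0)) {
    stop_lateq("configuration error: negative group sizes")
  }
  sds <- c(cfg$hv_group_sds, cfg$icv_sd, cfg$age_sd, cfg$taumax_group_sds,
           cfg$taumax_temporal_sds, cfg$education_sd, cfg$residual_sds)
  if (any(sds <= 0)) {
    stop_lateq("configuration error: all SDs must be > 0")
  }
  if (cfg$random_intercept_sd < 0 || cfg$random_slope_sd < 0) {
    stop_lateq("configuration error: random-effect SDs must be >= 0")
  }
  if (any(diff(cfg$visit_schedule) <= 0)) {
    stop_lateq("configuration error: visit times must be strictly increasing")
  }
  groups <- names(cfg$group_sizes)
  for (fld in c("hv_group_means", "hv_group_sds", "asymmetry_pct_by_group",
                "taumax_group_means", "taumax_group_sds")) {
    if (!all(groups %in% names(cfg[[fld]]))) {
      stop_lateq("configuration error: %s missing groups", fld)
    }
  }
  invisible(cfg)
}

set_seed_strict <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

# Gamma draws matching a target mean and SD exactly; non-negative and
# right-skewed, appropriate for Tau-MaX-like burden measures with near-zero
# group means but large SDs.
rgamma_moments <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  rgamma(n, shape = shape, rate = rate)
}

# Half-normal with given mean: scale = mean / sqrt(2/pi).
rhalfnorm_mean <- function(n, mean) {
  abs(rnorm(n, 0, mean / sqrt(2 / pi)))
}

#' Generate a synthetic cross-sectional + longitudinal cohort
#'
#' Draws a subject table and a longitudinal visit table with the group
#' structure the downstream stages assume. Adjusted-scale HV targets are
#' drawn per group, then mapped to raw hemisphere volumes through the true
#' age/ICV coefficients, so that the cognitively-unimpaired adjustment
#' regression recovers the planted coefficients and the adjusted values
#' recover the configured group means. Left-right asymmetry is injected by
#' multiplicative factors `(1 - d/2, 1 + d/2)` applied to a common base, with
#' `d` half-normal at the group-specific mean; the smaller hemisphere equals
#' the adjusted-scale target so the minimum-hemisphere convention sees the
#' configured distribution. Cognitive scores follow
#' `intercept + slope * t + b0_i + b1_i * t + noise`.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed (defaults to `config$seed`); each output
#'   table uses its own derived stream.
#' @return a list with data frames `subjects` and `visits`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  groups <- names(config$group_sizes)
  n_total <- sum(config$group_sizes)
  group <- rep(groups, times = config$group_sizes)

  set_seed_strict(derive_seed(seed, "subjects"))
  age <- rnorm(n_total, config$age_mean, config$age_sd)
  icv <- rnorm(n_total, config$icv_mean, config$icv_sd)
  sex <- ifelse(runif(n_total) < config$p_male, "M", "F")
  education <- pmax(8, rnorm(n_total,
                             config$education_group_means[group],
                             config$education_sd))

  # adjusted-scale HV target; raw min-hemisphere HV adds back the covariate
  # structure that the CU regression later removes
  hv_adj <- rnorm(n_total, config$hv_group_means[group],
                  config$hv_group_sds[group])
  hv_min_raw <- hv_adj + config$beta_age * (age - config$age_mean) +
    config$beta_icv * (icv - config$icv_mean)
  hv_min_raw <- pmax(hv_min_raw, 200)

  delta <- rhalfnorm_mean(n_total, config$asymmetry_pct_by_group[group] / 100)
  delta <- pmin(delta, 1.5)
  base <- hv_min_raw / (1 - delta / 2)
  hv_other <- base * (1 + delta / 2)
  left_is_min <- runif(n_total) < 0.5
  hv_left <- ifelse(left_is_min, hv_min_raw, hv_other)
  hv_right <- ifelse(left_is_min, hv_other, hv_min_raw)

  sf <- config$subregion_fractions
  frac_l <- pmin(0.7, pmax(0.4, rnorm(n_total, sf$ah_fraction, 0.02)))
  frac_r <- pmin(0.7, pmax(0.4, rnorm(n_total, sf$ah_fraction, 0.02)))
  ah_left <- hv_left * frac_l
  ph_left <- hv_left - ah_left
  ah_right <- hv_right * frac_r
  ph_right <- hv_right - ah_right
  amygdala_left <- sf$amygdala_to_hv * hv_left * exp(rnorm(n_total, 0, 0.08))
  amygdala_right <- sf$amygdala_to_hv * hv_right * exp(rnorm(n_total, 0, 0.08))

  thk <- list()
  for (region in names(sf$thickness_base)) {
    mu <- sf$thickness_base[[region]] * sf$thickness_scale[group, region]
    thk[[paste0(region, "_thk_left")]] <-
      mu * exp(rnorm(n_total, 0, sf$thickness_cv))
    thk[[paste0(region, "_thk_right")]] <-
      mu * exp(rnorm(n_total, 0, sf$thickness_cv))
  }

  abeta_pos <- group %in% c("AD+sLATE-", "AD+sLATE+")
  tracer <- ifelse(runif(n_total) < 0.5, "florbetapir", "florbetaben")
  thr <- ifelse(tracer == "florbetapir", 1.11, 1.08)
  amyloid_suvr <- ifelse(abeta_pos,
                         thr + rgamma(n_total, shape = 2, scale = 0.15),
                         pmax(0.8, thr - 0.005 - rgamma(n_total, shape = 2,
                                                        scale = 0.03)))

  taumax_global <- rgamma_moments(n_total,
                                  config$taumax_group_means[group],
                                  config$taumax_group_sds[group])
  taumax_temporal <- rgamma_moments(n_total,
                                    config$taumax_temporal_means[group],
                                    config$taumax_temporal_sds[group])

  # per-ROI tau SUVR: two-component mixture; the pathologic-component
  # probability increases with the configured group tau burden so the
  # cohort-level GMM stage has identifiable structure and the computed
  # Tau-MaX preserves the configured group ordering
  rois <- tau_roi_sets()$global
  m_g <- config$taumax_group_means[group]
  p_path <- m_g / (m_g + 8)
  mu_path <- 1.5 + pmin(0.7, 0.02 * m_g)
  tau_cols <- matrix(NA_real_, n_total, length(rois),
                     dimnames = list(NULL, paste0("tau_", rois)))
  for (j in seq_along(rois)) {
    is_path <- runif(n_total) < p_path
    tau_cols[, j] <- pmax(0.3, ifelse(is_path,
                                      rnorm(n_total, mu_path, 0.25),
                                      rnorm(n_total, 1.0, 0.08)))
  }

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_total)),
    group_label = group,
    status = ifelse(group == "Abeta-CU", "CU", "CI"),
    age_mri = age, sex = sex, education = education, icv = icv,
    ah_left = ah_left, ah_right = ah_right,
    ph_left = ph_left, ph_right = ph_right,
    hv_left_total = ah_left + ph_left,
    hv_right_total = ah_right + ph_right,
    amygdala_left = amygdala_left, amygdala_right = amygdala_right,
    amyloid_suvr = amyloid_suvr, tracer = tracer,
    taumax_global = taumax_global, taumax_temporal = taumax_temporal,
    pet_interval = runif(n_total, 0, 1),
    stringsAsFactors = FALSE)
  subjects <- cbind(subjects, as.data.frame(thk), as.data.frame(tau_cols))

  set_seed_strict(derive_seed(seed, "visits"))
  times <- config$visit_schedule
  n_vis <- length(times)
  b0 <- rnorm(n_total, 0, config$random_intercept_sd)
  b1 <- rnorm(n_total, 0, config$random_slope_sd)
  idx <- rep(seq_len(n_total), each = n_vis)
  tt <- rep(times, times = n_total)
  visits <- data.frame(
    subject_id = subjects$subject_id[idx],
    time_years = tt,
    age_at_visit = subjects$age_mri[idx] + tt,
    stringsAsFactors = FALSE)
  for (dom in colnames(config$cognitive_intercepts)) {
    mu <- config$cognitive_intercepts[group[idx], dom] +
      (config$cognitive_slopes[group[idx], dom] + b1[idx]) * tt + b0[idx]
    visits[[dom]] <- mu + rnorm(length(idx), 0, config$residual_sds[[dom]])
  }
  list(subjects = subjects, visits = visits)
}

# Expected LATE+ probability within a quartile band of the standardized
# negated-HV score z ~ N(0,1), under P(LATE+ | z) = plogis(a + b z).
.band_prob <- function(a, b, lo, hi) {
  num <- integrate(function(z) plogis(a + b * z) * dnorm(z), lo, hi,
                   rel.tol = 1e-10)$value
  num / (pnorm(hi) - pnorm(lo))
}

# Solve (a, b) so the Q1 vs Q3-Q4 odds ratio equals `odds` and the marginal
# LATE+ prevalence equals `prev`. Q1 on the HV scale is the top quartile of
# z = -(hv - mean)/sd; Q3-Q4 is the bottom half. Solutions are memoized:
# the root-finding is deterministic, so repeated simulation replicates at
# the same settings reuse the calibration.
.calibration_cache <- new.env(parent = emptyenv())

calibrate_enrichment <- function(odds, prev) {
  stopifnot(odds > 0, prev > 0, prev < 1)
  key <- sprintf("%.12g|%.12g", odds, prev)
  cached <- .calibration_cache[[key]]
  if (!is.null(cached)) return(cached)
  z75 <- qnorm(0.75)
  or_given_b <- function(b) {
    a <- uniroot(function(a) .band_prob(a, b, -8, 8) - prev,
                 c(-20, 20), tol = 1e-10)$root
    p1 <- .band_prob(a, b, z75, 8)
    p2 <- .band_prob(a, b, -8, 0)
    list(a = a, lor = qlogis(p1) - qlogis(p2))
  }
  target <- log(odds)
  b <- uniroot(function(b) or_given_b(b)$lor - target,
               c(-10, 10), tol = 1e-10)$root
  out <- c(a = or_given_b(b)$a, b = b)
  .calibration_cache[[key]] <- out
  out
}

#' Generate a synthetic autopsy cohort
#'
#' Draws an autopsy validation arm restricted to intermediate/high Alzheimer's
#' disease neuropathologic change (ADNC). LATE-NC positivity (TDP-43 stage
#' >= 1) follows a logistic link on the standardized, negated adjusted HV,
#' with intercept and slope calibrated numerically so the population odds
#' ratio between the lowest HV quartile (Q1) and the upper half (Q3-Q4)
#' equals `config$enrichment_odds` and the marginal LATE+ prevalence equals
#' `config$autopsy_late_prevalence`.
#'
#' @param config a [cohort_config()].
#' @param n number of autopsy subjects (>= 8).
#' @param seed master integer seed.
#' @return a subject data frame with `hv_adjusted`, `late_nc_stage` (0-3) and
#'   `adnc_level` columns plus raw hemisphere volumes consistent with the
#'   planted adjustment coefficients.
#' @export
generate_autopsy_cohort <- function(config, n, seed = config$seed) {
  validate_cohort_config(config)
  if (config$enrichment_odds <= 0) {
    stop_lateq("configuration error: enrichment_odds must be > 0")
  }
  if (n < 8) {
    stop_lateq("autopsy cohort needs n >= 8 for meaningful quartiles (got %d)", n)
  }
  ab <- calibrate_enrichment(config$enrichment_odds,
                             config$autopsy_late_prevalence)
  set_seed_strict(derive_seed(seed, "autopsy"))
  hv_adj <- rnorm(n, config$autopsy_hv_mean, config$autopsy_hv_sd)
  z <- -(hv_adj - config$autopsy_hv_mean) / config$autopsy_hv_sd
  late_pos <- runif(n) < plogis(ab["a"] + ab["b"] * z)
  stage <- ifelse(late_pos, sample(1:3, n, replace = TRUE,
                                   prob = c(0.4, 0.4, 0.2)), 0L)

  age <- rnorm(n, config$age_mean, config$age_sd)
  icv <- rnorm(n, config$icv_mean, config$icv_sd)
  hv_min_raw <- pmax(200, hv_adj + config$beta_age * (age - config$age_mean) +
                       config$beta_icv * (icv - config$icv_mean))
  delta <- rhalfnorm_mean(n, ifelse(late_pos, 0.10, 0.04))
  base <- hv_min_raw / (1 - pmin(delta, 1.5) / 2)
  hv_other <- base * (1 + pmin(delta, 1.5) / 2)
  left_is_min <- runif(n) < 0.5
  data.frame(
    subject_id = sprintf("A%04d", seq_len(n)),
    status = "CI",
    age_mri = age, icv = icv,
    hv_left_total = ifelse(left_is_min, hv_min_raw, hv_other),
    hv_right_total = ifelse(left_is_min, hv_other, hv_min_raw),
    hv_adjusted = hv_adj,
    adnc_level = sample(c("intermediate", "high"), n, replace = TRUE),
    late_nc_stage = as.integer(stage),
    stringsAsFactors = FALSE)
}

#' Simulate monotone biomarker trajectories for trajectory-model checks
#'
#' Generates longitudinal (subject, age, value) observations from either a
#' linear (`value = L0 + rate * age`-style, common rate) or logistic growth
#' curve `value(age) = L / (1 + exp(-k * (age - t0_i)))` with per-subject
#' onset ages, plus observation noise. Used to exercise trajectory-model
#' recovery against known time-from-threshold truth.
#'
#' @param n subjects.
#' @param n_visits visits per subject, spaced `visit_gap` years apart.
#' @param shape `"logistic"` or `"linear"`.
#' @param L,k logistic asymptote and steepness (per year).
#' @param rate linear growth rate (units/year).
#' @param t0_mean,t0_sd per-subject logistic midpoint age (years).
#' @param age_entry_range uniform range of baseline ages.
#' @param noise_sd observation noise SD (same units as value).
#' @param visit_gap years between visits.
#' @param seed integer seed.
#' @return data frame with `subject_id`, `age`, `value`, `t0` (the subject's
#'   true logistic midpoint, `NA` for linear).
#' @export
simulate_trajectories <- function(n = 200, n_visits = 4, shape = "logistic",
                                  L = 100, k = 0.25, rate = 2,
                                  t0_mean = 75, t0_sd = 6,
                                  age_entry_range = c(60, 85),
                                  noise_sd = 5, visit_gap = 1.5, seed = 1) {
  shape <- match.arg(shape, c("logistic", "linear"))
  set_seed_strict(derive_seed(seed, "trajectories"))
  t0 <- rnorm(n, t0_mean, t0_sd)
  age0 <- runif(n, age_entry_range[1], age_entry_range[2])
  idx <- rep(seq_len(n), each = n_visits)
  age <- age0[idx] + rep(seq_len(n_visits) - 1, times = n) * visit_gap
  true_val <- if (shape == "logistic") {
    L / (1 + exp(-k * (age - t0[idx])))
  } else {
    rate * (age - min(age_entry_range))
  }
  data.frame(
    subject_id = sprintf("T%04d", idx),
    age = age,
    value = true_val + rnorm(length(age), 0, noise_sd),
    t0 = if (shape == "logistic") t0[idx] else NA_real_,
    stringsAsFactors = FALSE)
}
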