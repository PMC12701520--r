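#' SILA configuration
#'
#' Parameters for the sampled iterative local approximation (SILA)
#' trajectory model: rate sampling, robust LOESS smoothing, and Euler
#' integration anchored at a positivity threshold.
#'
#' @param positivity_threshold biomarker value defining positivity (curve
#'   time 0).
#' @param dt Euler integration step (years, > 0).
#' @param loess_span LOESS span fraction in (0, 1].
#' @param robust_iters robust reweighting passes for the LOESS rate fit.
#' @param extrapolation_years how far (years) the curve and onset estimates
#'   may extend beyond the observed data (3 for tau, 5 for cognition).
#' @param truncate_to_observed clamp estimated onset ages into the observed
#'   age range of the fitting sample.
#' @param min_rate positive floor (units/year) on the smoothed rate, which
#'   guarantees a strictly monotone, invertible curve.
#' @return list of class `sila_config`.
#' @export
sila_config <- function(positivity_threshold, dt = 0.05, loess_span = 0.5,
                        robust_iters = 2, extrapolation_years = 3,
                        truncate_to_observed = TRUE, min_rate = 1e-4) {
  stopifnot(is.finite(positivity_threshold), dt > 0,
            loess_span > 0, loess_span <= 1,
            robust_iters >= 0, extrapolation_years >= 0, min_rate > 0)
  structure(list(positivity_threshold = positivity_threshold, dt = dt,
                 loess_span = loess_span, robust_iters = robust_iters,
                 extrapolation_years = extrapolation_years,
                 truncate_to_observed = truncate_to_observed,
                 min_rate = min_rate),
            class = "sila_config")
}

#' Cognitive impairment threshold from unimpaired scores
#'
#' 1.5 SD below the cognitively unimpaired mean, scaled by -1 because the
#' trajectory model associates higher values with greater disease severity:
#' `threshold = -(mean_cu - k * sd_cu)`. On the negated-score scale, values
#' above the threshold are impaired.
#'
#' @param cu_scores composite scores of unimpaired subjects (>= 3 values).
#' @param k SD multiplier (default 1.5).
#' @return impairment threshold on the negated scale.
#' @export
impairment_threshold <- function(cu_scores, k = 1.5) {
  x <- cu_scores[is.finite(cu_scores)]
  if (length(x) < 3) stop_lateq("need >= 3 unimpaired scores (got %d)", length(x))
  s <- sd(x)
  if (s == 0 && k > 0) {
    warning("zero variance in unimpaired scores; threshold = -mean")
    return(-mean(x))
  }
  -(mean(x) - k * s)
}

#' Fit a SILA biomarker trajectory
#'
#' Estimates a value-vs-time-from-positivity curve from longitudinal
#' observations: (1) per subject, adjacent-visit rates `dvalue/dage` are
#' assigned to the midpoint value; (2) the rate-vs-value relation is
#' smoothed with robust (symmetric-family) LOESS; (3) smoothed rates are
#' floored at `min_rate` so the curve is strictly monotone; (4) the rate
#' field is integrated with Euler steps of `dt` years outward from the
#' positivity threshold (forward while values remain below the observed
#' maximum plus the extrapolation allowance, backward likewise), which
#' anchors the curve at exactly time 0 at the threshold.
#'
#' @param long_data data frame with columns `subject_id`, `age` (years) and
#'   `value`; at least 20 subjects with >= 2 observations each.
#' @param config a [sila_config()].
#' @return object of class `sila_curve`: `grid` (data frame `value`,
#'   `time`), `threshold`, `value_range` and `age_range` of the fitting
#'   sample, `config`, and the internal rate function.
#' @export
sila_fit <- function(long_data, config) {
  stopifnot(inherits(config, "sila_config"))
  need <- c("subject_id", "age", "value")
  miss <- setdiff(need, names(long_data))
  if (length(miss)) stop_lateq("missing columns: %s", paste(miss, collapse = ", "))
  d <- long_data[is.finite(long_data$age) & is.finite(long_data$value), ]
  nobs <- table(d$subject_id)
  if (sum(nobs >= 2) < 20) {
    stop_lateq("SILA needs >= 20 subjects with >= 2 observations (got %d)",
               sum(nobs >= 2))
  }
  rates <- do.call(rbind, lapply(split(d, d$subject_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    s <- s[order(s$age), ]
    da <- diff(s$age)
    keep <- da > 0
    data.frame(mid = ((head(s$value, -1) + tail(s$value, -1)) / 2)[keep],
               rate = (diff(s$value) / da)[keep])
  }))
  if (is.null(rates) || nrow(rates) < 5 || diff(range(rates$mid)) == 0) {
    stop_lateq("degenerate rate sample: value ranges do not overlap usefully")
  }
  # local-quadratic smoothing: rate-vs-value profiles are peaked, and a
  # local-linear fit systematically attenuates the peak
  lo <- loess(rate ~ mid, data = rates, span = config$loess_span,
              degree = 2, family = "symmetric",
              control = loess.control(surface = "direct",
                                      iterations = config$robust_iters + 1))
  vrange <- range(rates$mid)
  rate_fun <- function(v) {
    pmax(config$min_rate,
         predict(lo, newdata = data.frame(mid = pmin(pmax(v, vrange[1]),
                                                     vrange[2]))))
  }
  obs_vrange <- range(d$value)
  obs_arange <- range(d$age)
  horizon <- diff(obs_arange) + 2 * config$extrapolation_years + 1

  integrate_dir <- function(sign) {
    v <- config$positivity_threshold
    t <- 0
    vv <- numeric(0)
    tt <- numeric(0)
    extra <- 0
    repeat {
      v_next <- v + sign * rate_fun(v) * config$dt
      t_next <- t + sign * config$dt
      inside <- if (sign > 0) v_next <= obs_vrange[2] else v_next >= obs_vrange[1]
      if (!inside) extra <- extra + config$dt
      if (extra > config$extrapolation_years || abs(t_next) > horizon) break
      vv <- c(vv, v_next)
      tt <- c(tt, t_next)
      v <- v_next
      t <- t_next
    }
    list(value = vv, time = tt)
  }
  fwd <- integrate_dir(+1)
  bwd <- integrate_dir(-1)
  grid <- data.frame(value = c(rev(bwd$value), config$positivity_threshold,
                               fwd$value),
                     time = c(rev(bwd$time), 0, fwd$time))
  structure(list(grid = grid, threshold = config$positivity_threshold,
                 value_range = obs_vrange, age_range = obs_arange,
                 config = config, rate_fun = rate_fun),
            class = "sila_curve")
}

#' @export
print.sila_curve <- function(x, ...) {
  cat(sprintf("<sila_curve> threshold=%.3g  values [%.3g, %.3g]  time [%.2f, %.2f] yr\n",
              x$threshold, min(x$grid$value), max(x$grid$value),
              min(x$grid$time), max(x$grid$time)))
  invisible(x)
}

#' Time from positivity for a biomarker value
#'
#' Inverse interpolation on the monotone SILA grid. Values beyond the grid
#' are extended linearly with the terminal slope and capped at
#' `extrapolation_years` beyond the grid's time range; capped values are
#' flagged in the `"extrapolated"` attribute.
#'
#' @param curve a [sila_fit()] result.
#' @param value biomarker value(s); finite.
#' @return years from positivity (negative before positivity), with a
#'   logical `"extrapolated"` attribute.
#' @export
sila_time_lookup <- function(curve, value) {
  stopifnot(inherits(curve, "sila_curve"))
  if (any(!is.finite(value))) stop_lateq("non-finite biomarker value")
  g <- curve$grid
  t_out <- approx(g$value, g$time, xout = value, rule = 1)$y
  extrap <- rep(FALSE, length(value))
  cap <- curve$config$extrapolation_years
  hi <- value > max(g$value)
  if (any(hi)) {
    k <- nrow(g)
    slope <- (g$time[k] - g$time[k - 1]) / (g$value[k] - g$value[k - 1])
    t_raw <- g$time[k] + (value[hi] - g$value[k]) * slope
    t_out[hi] <- pmin(t_raw, g$time[k] + cap)
    extrap[hi] <- TRUE
  }
  lo <- value < min(g$value)
  if (any(lo)) {
    slope <- (g$time[2] - g$time[1]) / (g$value[2] - g$value[1])
    t_raw <- g$time[1] + (value[lo] - g$value[1]) * slope
    t_out[lo] <- pmax(t_raw, g$time[1] - cap)
    extrap[lo] <- TRUE
  }
  structure(t_out, extrapolated = extrap)
}

#' Estimate biomarker-onset age for one subject
#'
#' Onset age is anchored on the final event point (the last observation):
#' `onset = age_last - time_from_positivity(value_last)`. When
#' `truncate_to_observed` is set, estimates are clamped into the age range
#' observed in the curve's fitting sample and flagged.
#'
#' @param observations data frame with `age` and `value` for one subject
#'   (>= 1 row).
#' @param curve a [sila_fit()] result.
#' @return estimated onset age (years) with logical attributes `"truncated"`
#'   and `"extrapolated"`.
#' @export
sila_estimate_onset_age <- function(observations, curve) {
  stopifnot(inherits(curve, "sila_curve"))
  if (!nrow(observations)) stop_lateq("empty observation list")
  last <- observations[which.max(observations$age), ]
  tfp <- sila_time_lookup(curve, last$value)
  onset <- last$age - as.numeric(tfp)
  truncated <- FALSE
  if (isTRUE(curve$config$truncate_to_observed)) {
    clamped <- min(max(onset, curve$age_range[1]), curve$age_range[2])
    truncated <- clamped != onset
    onset <- clamped
  }
  structure(onset, truncated = truncated,
            extrapolated = attr(tfp, "extrapolated"))
}

#' Anchor cognitive visits to estimated tau-onset age
#'
#' Replaces the chronological time axis with time from estimated tau onset:
#' `anchored_time = age_at_visit - tau_onset_age`. Anchoring is only
#' meaningful for subjects in groups with tau positivity; requesting it for
#' a subject without an onset estimate is an explicit error.
#'
#' @param visits visit data frame with `subject_id` and `age_at_visit`.
#' @param tau_onset_age named numeric vector of per-subject onset ages.
#' @return `visits` with an `anchored_time` column (years from tau onset).
#' @export
anchor_cognition_to_tau <- function(visits, tau_onset_age) {
  onset <- tau_onset_age[visits$subject_id]
  missing_ids <- unique(visits$subject_id[is.na(onset)])
  if (length(missing_ids)) {
    stop_lateq("no tau-onset age for subject(s) %s: anchoring is only valid for groups with tau positivity",
               paste(head(missing_ids, 5), collapse = ", "))
  }
  visits$anchored_time <- visits$age_at_visit - unname(onset)
  visits
}

#' Estimate impairment onset from anchored cognitive trajectories
#'
#' Fits one SILA curve per group to negated domain scores on the anchored
#' time axis and estimates each subject's impairment-onset time from the
#' final event point. Scores are negated because the trajectory model
#' associates higher values with greater severity.
#'
#' @param anchored_visits output of [anchor_cognition_to_tau()] with the
#'   domain score column and a `group` column.
#' @param domain score column name (`"memory"`, `"exec"`, `"language"`).
#' @param threshold impairment threshold on the negated scale (from
#'   [impairment_threshold()]).
#' @param config a [sila_config()]; `positivity_threshold` is overridden
#'   with `threshold` and cognition uses `extrapolation_years = 5` by
#'   convention.
#' @return list with `curves` (per group) and `onsets` (data frame
#'   `subject_id`, `group`, `onset_time` in anchored years).
#' @export
estimate_impairment_onset <- function(anchored_visits, domain, threshold,
                                      config = sila_config(threshold,
                                                           extrapolation_years = 5)) {
  config$positivity_threshold <- threshold
  out <- list()
  onsets <- NULL
  for (g in unique(anchored_visits$group)) {
    dg <- anchored_visits[anchored_visits$group == g, ]
    long <- data.frame(subject_id = dg$subject_id, age = dg$anchored_time,
                       value = -dg[[domain]])
    curve <- sila_fit(long, config)
    out[[g]] <- curve
    per_subj <- vapply(split(long, long$subject_id), function(s) {
      as.numeric(sila_estimate_onset_age(s[, c("age", "value")], curve))
    }, numeric(1))
    onsets <- rbind(onsets, data.frame(subject_id = names(per_subj),
                                       group = g,
                                       onset_time = unname(per_subj),
                                       stringsAsFactors = FALSE))
  }
  list(curves = out, onsets = onsets)
}

#' Cognitive-domain linear mixed model with slope contrasts
#'
#' Fits `score ~ time + group + age + education + global Tau-MaX +
#' PET interval + time:group + (1 + time | subject)` and reports
#' group-specific slopes and all pairwise slope contrasts (t tests on the
#' time x group interaction). A singular random-effects fit is refitted with
#' a random intercept only and flagged.
#'
#' @param visits visit data frame: `subject_id`, `time_years`, domain score
#'   columns.
#' @param subjects subject data frame: `subject_id`, `age_mri`, `education`,
#'   `taumax_global`, `pet_interval`, and the grouping column.
#' @param domain score column name.
#' @param group_col grouping column in `subjects` (default `group_label`).
#' @return object of class `domain_lme`: `fit`, `slopes` (per-group time
#'   trends), `contrasts` (pairwise slope differences with SE, t, p),
#'   `singular_refit`, `domain`.
#' @export
fit_domain_lme <- function(visits, subjects, domain,
                           group_col = "group_label") {
  need_v <- c("subject_id", "time_years", domain)
  need_s <- c("subject_id", "age_mri", "education", "taumax_global",
              "pet_interval", group_col)
  miss <- c(setdiff(need_v, names(visits)), setdiff(need_s, names(subjects)))
  if (length(miss)) stop_lateq("missing columns: %s", paste(miss, collapse = ", "))
  d <- merge(visits[, need_v], subjects[, need_s], by = "subject_id")
  d <- d[complete.cases(d), ]
  d$group <- factor(d[[group_col]])
  d$time <- d$time_years
  d$score <- d[[domain]]
  if (var(d$time) == 0) {
    stop_lateq("time column is constant: no longitudinal information")
  }
  form <- score ~ time + group + age_mri + education + taumax_global +
    pet_interval + time:group + (1 + time | subject_id)
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(form, data = d)))
  singular_refit <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    form2 <- score ~ time + group + age_mri + education + taumax_global +
      pet_interval + time:group + (1 | subject_id)
    fit <- suppressWarnings(suppressMessages(lmerTest::lmer(form2, data = d)))
    singular_refit <- TRUE
  }
  trends <- emmeans::emtrends(fit, ~ group, var = "time",
                              lmer.df = "satterthwaite")
  slopes <- as.data.frame(summary(trends))
  contrasts <- as.data.frame(summary(emmeans::contrast(trends,
                                                       method = "pairwise")))
  structure(list(fit = fit, slopes = slopes, contrasts = contrasts,
                 singular_refit = singular_refit, domain = domain),
            class = "domain_lme")
}

#' @export
print.domain_lme <- function(x, ...) {
  cat(sprintf("<domain_lme> domain=%s%s\n", x$domain,
              if (x$singular_refit) " (random-intercept refit)" else ""))
  print(x$contrasts)
  invisible(x)
}
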