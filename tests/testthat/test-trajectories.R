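test_that("impairment threshold is 1.5 SD below the CU mean on the negated scale", {
  set.seed(1)
  z <- rnorm(5000)
  thr <- impairment_threshold(z)
  expect_lt(abs(thr - 1.5), 0.1)
  expect_warning(t0 <- impairment_threshold(rep(0.7, 5)), "zero variance")
  expect_equal(t0, -0.7)
  x <- c(0.3 - 0.35, 0.3, 0.3 + 0.35)  # mean 0.3, sd 0.35
  expect_equal(impairment_threshold(x), -(0.3 - 1.5 * sd(x)))
  expect_error(impairment_threshold(c(1, 2)), ">= 3")
})

test_that("linear growth yields a linear curve with closed-form lookups", {
  d <- simulate_trajectories(n = 60, n_visits = 4, shape = "linear", rate = 2,
                             noise_sd = 0.3, seed = 5)
  cfg <- sila_config(positivity_threshold = 20, dt = 0.05)
  cv <- sila_fit(d, cfg)
  expect_equal(as.numeric(sila_time_lookup(cv, 20)), 0)  # exact anchor
  for (v in c(10, 24, 30, 40)) {
    expect_lt(abs(as.numeric(sila_time_lookup(cv, v)) - (v - 20) / 2),
              0.35)  # O(dt) + rate-estimation error
  }
  # duplicating every subject leaves the curve unchanged
  d2 <- rbind(d, transform(d, subject_id = paste0(subject_id, "_dup")))
  cv2 <- sila_fit(d2, cfg)
  expect_equal(cv$grid$time, cv2$grid$time, tolerance = 1e-6)
})

test_that("the curve is invariant to subject order and uniform time shifts", {
  d <- simulate_trajectories(n = 40, n_visits = 4, shape = "logistic",
                             noise_sd = 3, seed = 9)
  cfg <- sila_config(positivity_threshold = 25, dt = 0.05)
  cv <- sila_fit(d, cfg)
  perm <- d[sample(nrow(d)), ]
  expect_equal(sila_fit(perm, cfg)$grid, cv$grid, tolerance = 1e-10)
  shifted <- transform(d, age = age + 7)
  cv_s <- sila_fit(shifted, cfg)
  expect_equal(cv_s$grid$value, cv$grid$value, tolerance = 1e-10)
  expect_equal(cv_s$grid$time, cv$grid$time, tolerance = 1e-10)
  # strict monotonicity (invertibility)
  expect_true(all(diff(cv$grid$value) > 0))
})

test_that("time lookup interpolates linearly and caps extrapolation", {
  d <- simulate_trajectories(n = 60, n_visits = 4, shape = "linear", rate = 2,
                             noise_sd = 0.3, seed = 5)
  cfg <- sila_config(positivity_threshold = 20, dt = 0.05,
                     extrapolation_years = 3)
  cv <- sila_fit(d, cfg)
  g <- cv$grid
  k <- 10
  vmid <- (g$value[k] + g$value[k + 1]) / 2
  tmid <- g$time[k] + (vmid - g$value[k]) / (g$value[k + 1] - g$value[k]) *
    (g$time[k + 1] - g$time[k])
  expect_equal(as.numeric(sila_time_lookup(cv, vmid)), tmid,
               tolerance = 1e-10)
  big <- max(g$value) + 1000
  t_big <- sila_time_lookup(cv, big)
  expect_equal(as.numeric(t_big), max(g$time) + 3, tolerance = 1e-10)
  expect_true(attr(t_big, "extrapolated"))
  expect_error(sila_time_lookup(cv, NA), "non-finite")
})

test_that("onset ages follow the final event point with truncation flags", {
  d <- simulate_trajectories(n = 60, n_visits = 4, shape = "linear", rate = 2,
                             noise_sd = 0.3, seed = 5)
  cfg <- sila_config(positivity_threshold = 20, dt = 0.05,
                     truncate_to_observed = FALSE)
  cv <- sila_fit(d, cfg)
  on1 <- sila_estimate_onset_age(data.frame(age = 75, value = 20), cv)
  expect_equal(as.numeric(on1), 75, tolerance = 1e-8)
  on2 <- sila_estimate_onset_age(data.frame(age = 80, value = 20 + 2 * 2), cv)
  expect_lt(abs(as.numeric(on2) - 78), 0.3)
  # truncation clamps to the observed age range and flags it
  cfg_t <- sila_config(20, dt = 0.05, truncate_to_observed = TRUE)
  cv_t <- sila_fit(d, cfg_t)
  low <- sila_estimate_onset_age(data.frame(age = 30, value = 20), cv_t)
  expect_equal(as.numeric(low), cv_t$age_range[1])
  expect_true(attr(low, "truncated"))
  expect_error(sila_estimate_onset_age(d[0, ], cv), "empty")
})

test_that("estimated subject onset ages track the planted logistic truth", {
  d <- simulate_trajectories(n = 200, n_visits = 4, shape = "logistic",
                             L = 100, k = 0.25, t0_mean = 75, t0_sd = 6,
                             noise_sd = 5, seed = 31)
  thr <- 20
  cv <- sila_fit(d, sila_config(thr, dt = 0.05))
  # true crossing age: value(t) = thr  =>  t = t0 + logit(thr/L)/k
  true_onset <- tapply(d$t0, d$subject_id, unique) + qlogis(thr / 100) / 0.25
  est <- vapply(split(d, d$subject_id), function(s) {
    as.numeric(sila_estimate_onset_age(s[, c("age", "value")], cv))
  }, numeric(1))
  expect_gt(cor(est, true_onset[names(est)]), 0.9)
})

test_that("anchoring uses tau-onset time and fails loudly without onsets", {
  visits <- data.frame(subject_id = rep(c("s1", "s2"), each = 3),
                       age_at_visit = c(70, 71, 72, 80, 81, 82),
                       memory = rnorm(6))
  onset <- c(s1 = 70, s2 = 78)
  av <- anchor_cognition_to_tau(visits, onset)
  expect_equal(av$anchored_time, c(0, 1, 2, 2, 3, 4))
  shifted <- transform(visits, age_at_visit = age_at_visit + 3)
  av2 <- anchor_cognition_to_tau(shifted, onset + 3)
  expect_equal(av2$anchored_time, av$anchored_time)
  expect_error(anchor_cognition_to_tau(visits, c(s1 = 70)),
               "tau positivity")
})

test_that("groups crossing impairment two years apart are resolved", {
  # two groups with identical shapes but a 2-year offset in anchored time
  set.seed(12)
  n <- 150
  make_group <- function(label, offset) {
    t0 <- rnorm(n, 2 + offset, 1.5)
    start <- runif(n, -6, 2)
    idx <- rep(seq_len(n), each = 4)
    tt <- start[idx] + rep(0:3, n) * 1.5
    data.frame(subject_id = sprintf("%s%03d", label, idx),
               group = label,
               anchored_time = tt,
               memory = -(1.5 / (1 + exp(-0.9 * (tt - t0[idx]))) +
                            rnorm(length(tt), 0, 0.075)))
  }
  av <- rbind(make_group("A", 0), make_group("B", 2))
  # threshold at half the plateau: group A crosses at ~2, B at ~4
  res <- estimate_impairment_onset(av, "memory", threshold = 0.75,
                                   config = sila_config(0.75, dt = 0.05,
                                                        extrapolation_years = 5,
                                                        truncate_to_observed = FALSE))
  med <- tapply(res$onsets$onset_time, res$onsets$group, median)
  expect_lt(abs((med[["B"]] - med[["A"]]) - 2), 0.5)
})

test_that("domain mixed model behaves under null and contract violations", {
  cfg <- cohort_config(
    group_sizes = c("AD+sLATE-" = 40, "AD+sLATE+" = 40,
                    "AD-sLATE+" = 0, "Abeta-CU" = 10),
    cognitive_slopes = rbind(
      "AD+sLATE-" = c(memory = -0.2, exec = -0.2, language = -0.2),
      "AD+sLATE+" = c(memory = -0.2, exec = -0.2, language = -0.2),
      "AD-sLATE+" = c(memory = -0.2, exec = -0.2, language = -0.2),
      "Abeta-CU"  = c(memory = 0, exec = 0, language = 0)),
    visit_schedule = 0:4)
  co <- generate_cohort(cfg, 23)
  keep <- co$subjects$group_label %in% c("AD+sLATE-", "AD+sLATE+")
  f <- fit_domain_lme(co$visits, co$subjects[keep, ], "memory")
  expect_lt(abs(f$contrasts$estimate[1]), 2.5 * f$contrasts$SE[1])
  # slope contrasts are antisymmetric: one contrast row per ordered pair
  expect_equal(nrow(f$contrasts), 1)
  # no longitudinal information is an error
  v0 <- co$visits[co$visits$time_years == 0, ]
  expect_error(fit_domain_lme(v0, co$subjects[keep, ], "memory"),
               "no longitudinal information")
})
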