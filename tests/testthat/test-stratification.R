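test_that("minimum-hemisphere HV follows the min convention with explicit missing-data errors", {
  expect_equal(min_hemisphere_hv(3000, 2800), 2800)
  expect_equal(min_hemisphere_hv(3100, 3100), 3100)
  expect_equal(min_hemisphere_hv(1400 + 1500, 1500 + 1500), 2900)
  expect_error(min_hemisphere_hv(NA, 2800), "missing hemisphere")
  expect_error(min_hemisphere_hv(-1, 2800), "> 0")
})

test_that("CU adjustment recovers exact coefficients without noise", {
  age <- c(60, 65, 70, 75, 80, 85)
  icv <- c(1.3e6, 1.5e6, 1.4e6, 1.6e6, 1.35e6, 1.55e6)
  cu <- data.frame(age_mri = age, icv = icv,
                   hv_left_total = 5000 - 10 * age + 0.001 * icv,
                   hv_right_total = 5000 - 10 * age + 0.001 * icv + 1)
  fit <- fit_cu_adjustment(cu)
  expect_equal(fit$beta_age, -10, tolerance = 1e-8)
  expect_equal(fit$beta_icv, 0.001, tolerance = 1e-8)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-6)

  cu$hv_left_total <- cu$hv_right_total <- 3000
  fit0 <- fit_cu_adjustment(cu)
  expect_equal(fit0$beta_age, 0, tolerance = 1e-8)
  expect_equal(fit0$beta_icv, 0, tolerance = 1e-8)

  cu$age_mri <- 70  # constant age: rank-deficient design
  expect_error(fit_cu_adjustment(cu), "singular")
  expect_error(fit_cu_adjustment(cu[1:2, ]), ">= 3 CU")
})

test_that("CU adjustment recovers planted coefficients within 3 SE at n = 193", {
  set.seed(42)
  n <- 193
  age <- rnorm(n, 74, 7)
  icv <- rnorm(n, 1.45e6, 1.4e5)
  hv <- 3000 - 25 * (age - 74) + 1.5e-3 * (icv - 1.45e6) + rnorm(n, 0, 300)
  cu <- data.frame(age_mri = age, icv = icv, hv_left_total = hv,
                   hv_right_total = hv + 50)
  fit <- fit_cu_adjustment(cu)
  sfit <- summary(stats::lm(hv ~ age + icv))$coefficients
  expect_lt(abs(fit$beta_age - (-25)), 3 * sfit["age", "Std. Error"])
  expect_lt(abs(fit$beta_icv - 1.5e-3), 3 * sfit["icv", "Std. Error"])
})

test_that("adjustment formula is the stated covariate re-centring", {
  fit <- structure(list(beta_age = -10, beta_icv = 0,
                        mean_age_cu = 70, mean_icv_cu = 1.4e6),
                   class = "cu_fit")
  expect_equal(adjust_hv(3000, 70, 1.4e6, fit), 3000)   # at CU means
  # 5 y above mean age with beta_age = -10: the age-expected 50 mm^3 loss is
  # credited back, raw - beta_age * (age - mean) = 3000 + 50
  expect_equal(adjust_hv(3000, 75, 1.4e6, fit), 3050)
  fit0 <- structure(list(beta_age = 0, beta_icv = 0,
                         mean_age_cu = 70, mean_icv_cu = 1.4e6),
                    class = "cu_fit")
  expect_equal(adjust_hv(c(2500, 3000), c(60, 90), c(1e6, 2e6), fit0),
               c(2500, 3000))
})

test_that("quartile cut-offs use the linear-interpolation convention", {
  q <- compute_quartile_cutoffs(1:100)
  expect_equal(q$q25, 25.75)
  expect_equal(q$q50, 50.5)
  qc <- compute_quartile_cutoffs(rep(7, 10))
  expect_equal(qc$q25, 7)
  expect_equal(qc$q50, 7)
  # interpolation convention agrees with the independent order-statistic
  # formula h = (n - 1) p + 1 on arbitrary samples
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(8:40, 1), 2800, 400)
    q3 <- compute_quartile_cutoffs(x)
    expect_equal(q3$q25, quantile_oracle(x, 0.25), tolerance = 1e-12)
    expect_equal(q3$q50, quantile_oracle(x, 0.50), tolerance = 1e-12)
  }
  expect_error(compute_quartile_cutoffs(1:7), ">= 8")
  expect_error(compute_quartile_cutoffs(c(1:8, NA)), "non-finite")
})

test_that("group assignment follows the strict quartile band rules", {
  cuts <- structure(list(q25 = 2500, q50 = 2850, n_ref = 100),
                    class = "quartile_cutoffs")
  lab <- assign_groups(c(2400, 2500, 2700, 2850, 2900, 2400, 2600, 3000, 2400),
                       c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                       c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                       cuts)
  expect_equal(as.character(lab),
               c("AD+sLATE+", "EXCLUDED_Q2", "EXCLUDED_Q2", "EXCLUDED_Q2",
                 "AD+sLATE-", "AD-sLATE+", "UNCLASSIFIED", "Abeta-CU",
                 "Abeta-CU"))
  expect_error(assign_groups(2400, NA, TRUE, cuts, subject_id = "S1"),
               "S1")
})

test_that("assignment agrees with the rank-based brute-force classifier", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    adj <- rnorm(n, 2800, 400)
    impaired <- runif(n) < 0.7
    abeta <- runif(n) < 0.6
    if (sum(impaired & abeta) < 8) next
    cuts <- compute_quartile_cutoffs(adj[impaired & abeta])
    got <- as.character(assign_groups(adj, abeta, impaired, cuts))
    expect_identical(got, assign_oracle(adj, abeta, impaired))
  }
})

test_that("partition and monotonicity invariants hold", {
  set.seed(3)
  n <- 60
  adj <- rnorm(n, 2800, 400)
  impaired <- rep(c(TRUE, FALSE), c(45, 15))
  abeta <- runif(n) < 0.6
  cuts <- compute_quartile_cutoffs(adj[impaired & abeta])
  lab <- assign_groups(adj, abeta, impaired, cuts)
  expect_equal(sum(table(lab)), n)          # exactly one label per subject
  # lowering an AD+sLATE+ subject's volume cannot flip it to AD+sLATE-
  idx <- which(lab == "AD+sLATE+")[1]
  adj2 <- adj
  adj2[idx] <- adj2[idx] - 500
  lab2 <- assign_groups(adj2, abeta, impaired, cuts)
  expect_equal(as.character(lab2[idx]), "AD+sLATE+")
})

test_that("planted group structure is recovered on a well-separated cohort", {
  co <- generate_cohort(separated_config(), 13)
  st <- stratify_cohort(co$subjects)
  planted_low <- co$subjects$group_label == "AD+sLATE+"
  rec <- mean(st$subjects$group_assigned[planted_low] == "AD+sLATE+")
  expect_gte(rec, 0.99)
})
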