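test_that("contingency construction applies the ADNC filter, Q2 exclusion and stage rule", {
  cuts <- structure(list(q25 = 2500, q50 = 2850, n_ref = 173),
                    class = "quartile_cutoffs")
  # 15 subjects below q25 (13 LATE+), 39 above q50 (12 LATE+), 3 in Q2,
  # plus 2 low-ADNC subjects that must be filtered out
  aut <- data.frame(
    subject_id = sprintf("A%02d", 1:59),
    hv_adjusted = c(seq(2100, 2450, length.out = 15),
                    seq(2900, 3400, length.out = 39),
                    c(2600, 2700, 2800),
                    c(2200, 3000)),
    late_nc_stage = c(rep(c(1L, 2L, 3L), length.out = 13), 0L, 0L,
                      rep(c(1L, 0L), c(12, 27)),
                      0L, 1L, 0L,
                      3L, 3L),
    adnc_level = c(rep("high", 57), "low", "none"))
  tab <- contingency_from_groups(aut, cuts)
  expect_equal(tab$a, 13)
  expect_equal(tab$b, 2)
  expect_equal(tab$c + tab$d, 39)
  expect_equal(tab$c, 12)
  expect_equal(attr(tab, "n_excluded_q2"), 3)

  # stage exactly 1 counts as LATE-NC positive
  one <- data.frame(subject_id = c("x1", "x2"), hv_adjusted = c(2000, 3000),
                    late_nc_stage = c(1L, 1L), adnc_level = "intermediate")
  t1 <- contingency_from_groups(one, cuts)
  expect_equal(c(t1$a, t1$c), c(1, 1))

  zero <- transform(one, late_nc_stage = 0L)
  t0 <- contingency_from_groups(zero, cuts)
  expect_equal(c(t0$a, t0$c), c(0, 0))

  miss <- transform(one, late_nc_stage = NA_integer_)
  expect_error(contingency_from_groups(miss, cuts), "x1")
})

test_that("exact test reproduces the published enrichment statistics", {
  tab <- contingency_2x2(13, 2, 12, 27)
  fe <- fisher_exact(tab)
  expect_equal(round(fe$or, 1), 13.8)
  expect_lt(fe$p, 0.001)
  freq <- enrichment_frequencies(tab)
  expect_equal(round(freq[["q1"]], 1), 86.7)
  expect_equal(round(freq[["q3q4"]], 1), 30.8)
})

test_that("exact test handles exchangeable and degenerate tables", {
  fe <- fisher_exact(contingency_2x2(5, 5, 5, 5))
  expect_equal(fe$or, 1, tolerance = 1e-6)
  expect_equal(fe$p, 1)
  expect_equal(fisher_exact(contingency_2x2(3, 0, 0, 3))$or, Inf)
  expect_equal(fisher_exact(contingency_2x2(0, 3, 3, 0))$or, 0)
  expect_equal(fisher_exact(contingency_2x2(2, 1, 1, 2))$p,
               fisher_p_oracle(2, 1, 1, 2), tolerance = 1e-12)
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("exact p matches exhaustive enumeration on random small tables", {
  set.seed(6)
  for (i in 1:100) {
    total <- sample(4:40, 1)
    cts <- as.vector(stats::rmultinom(1, total, runif(4, 0.1, 1)))
    expect_equal(fisher_exact(contingency_2x2(cts[1], cts[2], cts[3], cts[4]))$p,
                 fisher_p_oracle(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-9)
  }
})

test_that("conditional-MLE odds ratio is monotone in cell a at fixed margins", {
  r1 <- 15; r2 <- 39; c1 <- 25
  a_range <- max(0, c1 - r2):min(r1, c1)
  a_range <- a_range[a_range >= 1 & (r1 - a_range) >= 1 &
                       (c1 - a_range) >= 1 & (r2 - c1 + a_range) >= 1]
  ors <- vapply(a_range, function(a) {
    fisher_exact(contingency_2x2(a, r1 - a, c1 - a, r2 - (c1 - a)))$or
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("enrichment frequencies are plain row percentages", {
  expect_equal(enrichment_frequencies(contingency_2x2(0, 5, 3, 3))[["q1"]], 0)
  expect_equal(enrichment_frequencies(contingency_2x2(4, 4, 1, 1))[["q1"]], 50)
  expect_error(enrichment_frequencies(contingency_2x2(0, 0, 3, 3)),
               "empty quartile row")
})

test_that("ROC follows the low-volume-positive convention with midrank AUC", {
  # perfectly separated: all LATE+ have the lowest volumes
  sc <- c(2000, 2100, 2200, 3000, 3100, 3200)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_curve(sc, lb)
  expect_equal(r$auc, 1)
  yo <- youden_optimal(r)
  expect_equal(yo$sensitivity + yo$specificity - 1, 1)

  set.seed(14)
  big <- roc_curve(rnorm(4000, 2800, 300), rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(big$auc - 0.5), 0.03)

  # hand-built 6-point set with a tie, against all-pairs concordance
  sc2 <- c(2400, 2500, 2500, 2700, 2900, 3000)
  lb2 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_curve(sc2, lb2)$auc, auc_oracle(sc2, lb2))
  for (i in 1:20) {
    n <- sample(10:40, 1)
    s <- sample(seq(2000, 3000, by = 50), n, replace = TRUE)  # forced ties
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(roc_curve(s, l)$auc, auc_oracle(s, l), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- rnorm(200, 2800, 300)
  l <- runif(200) < plogis(-(s - 2800) / 200)
  if (any(l) && !all(l)) {
    auc_proc <- as.numeric(pROC::auc(pROC::roc(
      response = l, predictor = s, direction = ">", quiet = TRUE)))
    expect_equal(roc_curve(s, l)$auc, auc_proc, tolerance = 1e-10)
  }
})

test_that("Youden optimum matches exhaustive search with the specificity tie rule", {
  set.seed(7)
  s <- rnorm(80, 2800, 250)
  l <- runif(80) < plogis(-(s - 2800) / 150)
  if (any(l) && !all(l)) {
    r <- roc_curve(s, l)
    thrs <- c(min(s) - 1, sort(unique(s)))
    j <- vapply(thrs, function(t) {
      mean(s[l] <= t) + mean(s[!l] > t) - 1
    }, numeric(1))
    expect_equal(r$youden_sens + r$youden_spec - 1, max(j), tolerance = 1e-12)
  }
  # constructed tie: thresholds 1 and 3 both give J = 0.5
  st <- c(1, 2, 3, 4)
  lt <- c(TRUE, FALSE, TRUE, FALSE)
  rt <- roc_curve(st, lt)
  expect_equal(rt$youden_threshold, 1)  # the more specific of the tied pair
  expect_equal(rt$youden_spec, 1)
})

test_that("sensitivity/specificity at a threshold match hand counts", {
  s <- c(2100, 2200, 2300, 2400, 2500, 2600, 2700, 2800, 2900, 3000)
  l <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  ss <- sens_spec_at_threshold(s, l, 2450)
  expect_equal(ss[["sensitivity"]], 3 / 4)
  expect_equal(ss[["specificity"]], 5 / 6)
  expect_equal(unname(sens_spec_at_threshold(s, l, 2000)), c(0, 1))
  expect_equal(unname(sens_spec_at_threshold(s, l, 3100)), c(1, 0))
})
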