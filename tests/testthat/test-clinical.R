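# IHC aggregation, contingency/correlation tests, Kaplan-Meier and log-rank.

test_that("site dichotomization follows the 0/1-low, 2/3-high scale", {
  expect_identical(dichotomize_site(c(0, 1, 2, 3)),
                   c("low", "low", "high", "high"))
  expect_identical(dichotomize_site(NA), NA_character_)
  expect_error(dichotomize_site(4), class = "cointf_validation_error")
  expect_error(dichotomize_site(-1), class = "cointf_validation_error")
})

test_that("patient summaries average usable sites with the midpoint rule", {
  sites <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    site_id = paste0("s", 1:5),
    site_type = c("bone", "bone", "bone", "soft", "soft"),
    ihc_score = c(3, 3, 1, 2, NA),
    usable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  pats <- data.frame(patient_id = c("P1", "P2", "P3"),
                     docetaxel_treated = TRUE,
                     time_diagnosis = c(1, 2, 3), event_diagnosis = TRUE)
  sm <- summarize_patients(clinical_table(sites, pats))
  expect_equal(sm$mean_bone, c(3, 1, NA))
  expect_identical(sm$class_bone, c("high", "low", NA))
  # (1, 2) averages to 1.5 -> high under the midpoint-inclusive rule
  sites2 <- sites
  sites2$ihc_score <- c(1, 2, 1, 2, NA)
  sm2 <- summarize_patients(clinical_table(sites2, pats))
  expect_equal(sm2$mean_bone[1], 1.5)
  expect_identical(sm2$class_bone[1], "high")
  # patient with no usable site is flagged, not dropped
  expect_true("P3" %in% sm$patient_id)
  expect_identical(sm$class_all[3], NA_character_)
})

test_that("simulated cohorts reproduce the configured score distribution", {
  cfg <- sim_config(n_patients = 400, seed = 27)
  cc <- simulate_clinical_cohort(cfg)
  cls <- cc$truth$srf_class[cc$clinical$sites$patient_id]
  p_high_low <- mean(cc$clinical$sites$ihc_score[cls == "low"] >= 2)
  expected <- sum(cfg$score_probs_low[3:4])
  n <- sum(cls == "low")
  expect_lt(abs(p_high_low - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("positivity table is additive and rounds half away from zero", {
  ct <- cohort_from_site_counts(20, 32, 9, 22)
  pos <- site_positivity_table(ct)
  ov <- pos[pos$compartment == "overall", ]
  expect_identical(ov$n_sites,
                   sum(pos$n_sites[pos$compartment != "overall"]))
  expect_identical(ov$n_positive,
                   sum(pos$n_positive[pos$compartment != "overall"]))
  expect_true(all(pos$pct_positive + pos$pct_negative == 100))
  # all-negative cohort
  ct0 <- cohort_from_site_counts(0, 10, 0, 5)
  pos0 <- site_positivity_table(ct0)
  expect_true(all(pos0$pct_positive == 0))
  expect_error(site_positivity_table(
    clinical_table(data.frame(patient_id = "P1", site_id = "s", site_type = "bone",
                              ihc_score = NA, usable = FALSE),
                   data.frame(patient_id = "P1", docetaxel_treated = TRUE,
                              time_diagnosis = 1, event_diagnosis = TRUE))),
    class = "cointf_validation_error")
})

test_that("Fisher exact matches hand computation and fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10))
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)),
               class = "cointf_validation_error")
  set.seed(61)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("chi-square matches the (O-E)^2/E formula on 1 df", {
  tab <- matrix(c(20, 32, 9, 22), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cs <- chi_square(tab)
  expect_equal(cs$statistic, sum((tab - E)^2 / E))
  expect_equal(cs$p.value, pchisq(cs$statistic, 1, lower.tail = FALSE))
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "cointf_validation_error")
})

test_that("spearman is the mid-rank Pearson correlation, monotone-invariant", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman(x, x), 1)
  expect_equal(spearman(1:6, 6:1), -1)
  y <- c(2, 2, 3, 1, 5, 5, 4, 1)
  expect_equal(spearman(x, y), cor(rank(x), rank(y)))
  expect_equal(spearman(exp(x), y^3), spearman(x, y))
  expect_error(spearman(1:2, 2:1), class = "cointf_validation_error")
  expect_error(spearman(rep(1, 5), 1:5), class = "cointf_validation_error")
})

test_that("Kaplan-Meier matches the hand-computed product-limit steps", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$curves$n_risk, c(3, 2, 1))
  # censoring: S drops only at events; events precede censorings at ties
  km2 <- km_estimate(c(1, 1, 2), c(TRUE, FALSE, TRUE))
  ev <- km2$curves[km2$curves$n_event > 0, ]
  expect_equal(ev$surv, c(2 / 3, 0))
  # median undefined when the curve never reaches 0.5
  km3 <- km_estimate(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(km3$medians))
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)),
               class = "cointf_validation_error")
})

test_that("log-rank is zero for identical groups and detects planted hazards", {
  t0 <- c(1, 2, 3, 4, 5)
  lr <- logrank_test(rep(t0, 2), rep(TRUE, 10), rep(c("a", "b"), each = 5))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p.value, 1, tolerance = 1e-6)
  # strong planted hazard ratio rejects in nearly all cohorts
  rej <- 0
  for (s in 1:40) {
    cfg <- sim_config(seed = s, n_patients = 200, hazard_ratio = 3)
    cc <- simulate_clinical_cohort(cfg)
    cls <- cc$truth$srf_class[cc$clinical$patients$patient_id]
    lr <- logrank_test(cc$clinical$patients$time_crpc,
                       cc$clinical$patients$event_crpc, cls)
    rej <- rej + (lr$p.value < 0.05)
  }
  expect_gte(rej / 40, 0.95)
  expect_error(logrank_test(t0, rep(TRUE, 5), factor(rep("a", 5), levels = c("a", "b"))),
               class = "cointf_validation_error")
})

test_that("KM is invariant to the order of tied event/censor records", {
  t1 <- c(2, 2, 2, 3)
  e1 <- c(TRUE, FALSE, TRUE, TRUE)
  perm <- c(2, 3, 1, 4)
  k1 <- km_estimate(t1, e1)
  k2 <- km_estimate(t1[perm], e1[perm])
  expect_equal(k1$curves, k2$curves)
})

test_that("clinical_validation ties the pieces together coherently", {
  cfg <- sim_config(seed = 77, hazard_ratio = 6, n_patients = 120, censor_rate = 0.02)
  cc <- simulate_clinical_cohort(cfg)
  cv <- suppressMessages(clinical_validation(cc$clinical))
  expect_identical(cv$positivity$compartment, c("overall", "bone", "soft"))
  expect_true(all(cv$stats$baseline == c("diagnosis", "crpc", "bonemet")))
  # a strong marker-linked hazard shows up as negative correlation with time
  expect_true(all(cv$stats$spearman_rho < 0))
  expect_true(any(cv$stats$logrank_p < 0.05))
})
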