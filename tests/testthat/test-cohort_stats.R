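test_that("IHC H-score multiplies intensity by extension tenths", {
  expect_equal(ihc_score(3, 100), 30L)
  expect_equal(ihc_score(0, 0), 0L)
  expect_equal(ihc_score(2, 50), 10L)
  expect_equal(ihc_score(c(1, 2, 3), c(10, 30, 70)), c(1L, 6L, 21L))
  expect_error(ihc_score(4, 10), "intensity")
  expect_error(ihc_score(2, 55), "multiple of 10")
  expect_error(ihc_score(0, 50), "exactly when")
})

test_that("membrane/cytoplasm ratios count positive cases per stage", {
  cohort <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:24),
    stage = rep(c("Ta", "T4"), c(20, 4)),
    grade = "high",
    intensity = c(rep(2, 18), 0, 0, rep(2, 4)),
    extension = c(rep(50L, 18), 0L, 0L, rep(50L, 4)),
    location = c(rep("membrane_and_cytoplasm", 7), rep("cytoplasm", 11),
                 rep("negative", 2), rep("membrane_and_cytoplasm", 4)),
    followup_months = 10, event = 0L
  )
  out <- membrane_cytoplasm_ratio(cohort)
  ta <- out[out$stage == "Ta", ]
  expect_equal(ta$ratio, 7 / 11, tolerance = 1e-12)  # hand division: 0.636...
  expect_false(ta$undefined)
  t4 <- out[out$stage == "T4", ]
  expect_true(t4$undefined)  # no cytoplasm-only cases: undefined, not Inf
  expect_true(is.na(t4$ratio))
  # zero membrane cases give ratio 0
  cohort$location[cohort$stage == "Ta"][1:7] <- "cytoplasm"
  expect_equal(membrane_cytoplasm_ratio(cohort)$ratio[1], 0)
})

test_that("association_test auto-selects Fisher exactly when a cell < 5", {
  balanced <- matrix(c(10, 10, 10, 10), 2)
  res <- association_test(balanced)
  expect_equal(res$method, "chi2")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  sparse <- matrix(c(1, 8, 9, 2), 2)
  res2 <- association_test(sparse)
  expect_equal(res2$method, "fisher")
  expect_equal(res2$p_value, fisher_enumeration_oracle(sparse), tolerance = 1e-12)

  # boundary: a cell equal to 5 keeps chi-square
  expect_equal(association_test(matrix(c(5, 6, 7, 8), 2))$method, "chi2")
  expect_equal(association_test(matrix(c(4, 6, 7, 8), 2))$method, "fisher")

  # Pearson statistic against the closed-form hand computation
  tab <- matrix(c(50, 90, 50, 10), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - expected)^2 / expected)
  res3 <- association_test(tab)
  expect_equal(res3$statistic, hand, tolerance = 1e-12)
  expect_lt(res3$p_value, 0.001)

  expect_error(association_test(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("Kaplan-Meier/log-rank matches a hand-worked risk-set table", {
  dat <- tibble::tibble(
    group = rep(c("A", "B"), each = 3),
    followup_months = c(2, 4, 6, 3, 5, 7),
    event = c(1L, 1L, 0L, 1L, 0L, 1L)
  )
  fit <- km_logrank(dat)
  # hand table: event times 2,3,4,7; O_A = 2, E_A = 0.5+0.4+0.5+0 = 1.4,
  # V = 0.25+0.24+0.25+0 = 0.74; statistic = 0.6^2 / 0.74
  expect_equal(fit$logrank$statistic, 0.36 / 0.74, tolerance = 1e-9)
  expect_equal(fit$logrank$p_value,
               stats::pchisq(0.36 / 0.74, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # KM curve for A: drops to 2/3 at t=2, to 1/3 at t=4
  a <- fit$curves[fit$curves$group == "A", ]
  expect_equal(a$survival, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # restricted mean of A over [0, 7]: 1*2 + (2/3)*2 + (1/3)*3
  expect_equal(fit$groups$restricted_mean[fit$groups$group == "A"],
               2 + 4 / 3 + 1, tolerance = 1e-12)
})

test_that("KM curves are non-increasing step functions starting at 1", {
  sim <- simulate_cohort(cohort_size = 120, seed = 31)
  cohort <- sim$cohort
  cohort$group <- ifelse(cohort$location == "membrane_and_cytoplasm",
                         "membrane", "other")
  fit <- km_logrank(cohort, group = "group")
  for (gr in unique(fit$curves$group)) {
    s <- fit$curves$survival[fit$curves$group == gr]
    expect_true(all(s <= 1 & s >= 0))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("log-rank is label-symmetric and degenerates correctly", {
  dat <- tibble::tibble(
    group = rep(c("A", "B"), each = 4),
    followup_months = c(1, 3, 5, 8, 2, 4, 6, 9),
    event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L)
  )
  fit <- km_logrank(dat)
  swapped <- dat
  swapped$group <- ifelse(dat$group == "A", "B", "A")
  expect_equal(km_logrank(swapped)$logrank$statistic, fit$logrank$statistic,
               tolerance = 1e-12)
  # identical event patterns in both groups -> statistic 0, p 1
  same <- tibble::tibble(group = rep(c("A", "B"), each = 3),
                         followup_months = rep(c(1, 2, 3), 2),
                         event = rep(1L, 6))
  fs <- km_logrank(same)
  expect_equal(fs$logrank$statistic, 0, tolerance = 1e-12)
  expect_equal(fs$logrank$p_value, 1, tolerance = 1e-12)
  # all censored -> error-free fit with undefined p
  cens <- tibble::tibble(group = rep(c("A", "B"), each = 3),
                         followup_months = 1:6, event = 0L)
  fc <- km_logrank(cens)
  expect_true(is.na(fc$logrank$p_value))
  expect_error(km_logrank(dat[dat$group == "A", ]), "two groups")
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  sim <- simulate_cohort(cohort_size = 150, seed = 44)
  cohort <- sim$cohort
  cohort$group <- ifelse(cohort$location == "membrane_and_cytoplasm",
                         "membrane", "other")
  fit <- km_logrank(cohort, group = "group")
  ref <- survival::survdiff(
    survival::Surv(followup_months, event) ~ group, data = cohort)
  expect_equal(fit$logrank$statistic, ref$chisq, tolerance = 1e-8)
})

test_that("Cox fit matches grid-search and survival-package oracles", {
  sim <- simulate_cohort(cohort_size = 60, seed = 17)
  cohort <- sim$cohort
  cohort$membrane <- as.integer(cohort$location == "membrane_and_cytoplasm")
  fit <- cox_fit(cohort, "membrane")
  expect_true(fit$converged)
  # brute-force grid maximization of the partial likelihood
  beta_grid <- cox_grid_oracle(cohort$followup_months, cohort$event,
                               cohort$membrane)
  expect_equal(fit$terms$estimate, beta_grid, tolerance = 1e-4)
  skip_if_not_installed("survival")
  ref <- survival::coxph(
    survival::Surv(followup_months, event) ~ membrane, data = cohort,
    ties = "efron")
  expect_equal(fit$terms$estimate, unname(stats::coef(ref)), tolerance = 1e-7)
  expect_equal(fit$terms$std_error,
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
})

test_that("Cox handles ties (Efron = Breslow when tie-free) and degenerate data", {
  sim <- simulate_cohort(cohort_size = 80, seed = 9)
  cohort <- sim$cohort
  cohort$membrane <- as.integer(cohort$location == "membrane_and_cytoplasm")
  skip_if_not_installed("survival")
  # tie-free continuous times: Efron and Breslow coincide
  ref_breslow <- survival::coxph(
    survival::Surv(followup_months, event) ~ membrane, data = cohort,
    ties = "breslow")
  fit <- cox_fit(cohort, "membrane")
  expect_equal(fit$terms$estimate, unname(stats::coef(ref_breslow)),
               tolerance = 1e-6)
  # heavy ties: agree with survival's Efron handling
  tied <- cohort
  tied$followup_months <- ceiling(tied$followup_months / 20)
  fit_t <- cox_fit(tied, "membrane")
  ref_t <- survival::coxph(
    survival::Surv(followup_months, event) ~ membrane, data = tied,
    ties = "efron")
  expect_equal(fit_t$terms$estimate, unname(stats::coef(ref_t)),
               tolerance = 1e-6)
  # constant covariate: HR 1, p 1, flagged, never silent
  flat <- cohort; flat$membrane <- 1L
  ff <- cox_fit(flat, "membrane")
  expect_equal(ff$terms$hazard_ratio, 1)
  expect_equal(ff$terms$p_value, 1)
  expect_equal(ff$flag, "no_information")
  expect_error(cox_fit(cohort[cohort$event == 0, ], "membrane"),
               "at least one event")
})

test_that("multivariate Cox adjusts the membrane phenotype for stage", {
  sim <- simulate_cohort(cohort_size = 400, seed = 77)
  cohort <- sim$cohort
  cohort$membrane <- as.integer(cohort$location == "membrane_and_cytoplasm")
  cohort$invasive <- as.integer(cohort$stage %in% c("T2", "T3", "T4", "MET"))
  fit <- cox_fit(cohort, c("membrane", "invasive"))
  expect_true(fit$converged)
  skip_if_not_installed("survival")
  ref <- survival::coxph(
    survival::Surv(followup_months, event) ~ membrane + invasive,
    data = cohort, ties = "efron")
  expect_equal(fit$terms$estimate, unname(stats::coef(ref)), tolerance = 1e-6)
})

test_that("tidy/glance/autoplot methods expose fits as tables and plots", {
  sim <- simulate_cohort(cohort_size = 100, seed = 5)
  cohort <- sim$cohort
  cohort$group <- ifelse(cohort$location == "membrane_and_cytoplasm",
                         "membrane", "other")
  fit <- km_logrank(cohort, group = "group")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(autoplot(fit), "ggplot")
  cohort$membrane <- as.integer(cohort$group == "membrane")
  cf <- cox_fit(cohort, "membrane")
  expect_named(tidy(cf), c("term", "estimate", "hazard_ratio", "std_error",
                           "statistic", "p_value"))
  expect_true(glance(cf)$converged)
})
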