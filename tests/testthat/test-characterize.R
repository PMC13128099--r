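test_that("kaplan-meier equals the empirical survival function with no censoring", {
  set.seed(1)
  t_ <- sample(1:50, 30, replace = TRUE)
  km <- km_estimator(t_, rep(1, 30))
  at <- sort(unique(t_))
  emp <- vapply(at, function(u) mean(t_ > u), numeric(1))
  expect_equal(km_survival_at(km, at), emp, tolerance = 1e-12)
  # single subject with an event at t = 10
  km1 <- km_estimator(10, 1)
  expect_equal(km_survival_at(km1, c(5, 9.9)), c(1, 1))
  expect_equal(km_survival_at(km1, c(10, 20)), c(0, 0))
})

test_that("kaplan-meier matches hand-computed product-limit values on a censored fixture", {
  # six subjects: events at 1, 3, 4, 6; censored at 2 and 5
  # S(1) = 5/6; S(3) = 5/6 * 3/4 = 5/8; S(4) = 5/8 * 2/3 = 5/12; S(6) = 0
  km <- km_estimator(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(km_survival_at(km, c(1, 3, 4, 6)),
               c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)
  expect_true(all(diff(km$table$survival) <= 0))
  expect_equal(km_survival_at(km, 0.5), 1)
  # confidence bounds bracket the estimate
  mid <- km$table$n_event > 0 & km$table$survival > 0
  expect_true(all(km$table$lower[mid] <= km$table$survival[mid] + 1e-12))
  expect_true(all(km$table$upper[mid] >= km$table$survival[mid] - 1e-12))
})

test_that("an all-censored sample gives a flat flagged curve", {
  km <- km_estimator(c(3, 7, 9), c(0, 0, 0))
  expect_true(km$all_censored)
  expect_equal(km_survival_at(km, c(1, 5, 10)), c(1, 1, 1))
})

test_that("log-rank is near-null for identical groups and detects a hazard-ratio-3 contrast", {
  set.seed(2)
  t_ <- rexp(80); e <- rbinom(80, 1, 0.8)
  lr <- logrank_test(c(t_, t_), c(e, e), rep(1:2, each = 80))
  expect_gt(lr$p_value, 0.9)
  expect_lt(lr$statistic, 0.05)
  # hazard ratio 3, n = 200 per arm, most runs significant
  hits <- vapply(1:20, function(r) {
    set.seed(100 + r)
    ta <- rexp(200, 1); tb <- rexp(200, 3)
    logrank_test(c(ta, tb), rep(1, 400), rep(1:2, each = 200))$p_value < 1e-3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_true(is.na(logrank_test(c(1, 2), c(0, 0), c(1, 2))$p_value))
})

test_that("log-rank p-values are invariant to time rescaling and uniform under permutation", {
  set.seed(3)
  t_ <- rexp(60); e <- rbinom(60, 1, 0.7); grp <- rep(1:2, 30)
  a <- logrank_test(t_, e, grp)
  b <- logrank_test(t_ * 1000, e, grp)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  ps <- vapply(1:400, function(r) {
    set.seed(r)
    logrank_test(t_, e, sample(grp))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("transition statistics recover the generator sojourns per cluster", {
  coh <- cached_cohort(1000, seed = 77)
  gt <- coh$ground_truth
  tl <- data.frame(patient_id = gt$patient_id,
                   first_record_date = gt$first_mci_date - 400,
                   first_mci_date = gt$first_mci_date,
                   first_ad_date = gt$first_ad_date)
  assignments <- setNames(gt$subtype, gt$patient_id)
  ts_ <- transition_stats(assignments, tl)
  cfg <- coh$config
  for (z in 1:4) {
    se <- cfg$mci_to_ad_sojourn_sd_days[z] / sqrt(ts_$n[z])
    expect_lt(abs(ts_$mci_to_ad_mean[z] -
                    cfg$mci_to_ad_sojourn_mean_days[z]), 3 * se)
  }
  # all patients in one cluster reproduce the whole-cohort statistics
  one <- transition_stats(setNames(rep(1L, nrow(gt)), gt$patient_id), tl)
  expect_equal(one$mci_to_ad_mean,
               mean(as.numeric(gt$first_ad_date - gt$first_mci_date)))
  # singleton cluster: mean defined, sd flagged NA
  single <- transition_stats(setNames(c(1L, rep(2L, nrow(gt) - 1L)),
                                      gt$patient_id), tl)
  expect_false(is.na(single$mci_to_ad_mean[1]))
  expect_true(is.na(single$mci_to_ad_sd[1]))
})

test_that("prevalence contrasts: identical clusters are null, a planted contrast hits the smallest tier", {
  set.seed(4)
  n <- 400
  X <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(sprintf("P%03d", 1:n),
                              c("f_same", "f_planted", "f_rare")))
  cl <- setNames(rep(1:2, each = n / 2), rownames(X))
  X[, "f_planted"] <- as.integer(cl == 1)   # present only in cluster 1
  res <- prevalence_tests(cl, X)
  expect_true(all(res$prevalence >= 0 & res$prevalence <= 1))
  planted <- res$tests[res$tests$feature == "f_planted", ]
  expect_equal(planted$tier, "****")
  same <- res$tests[res$tests$feature == "f_same", ]
  expect_equal(same$tier, "ns")
  # chi-square p matches the closed-form contingency computation
  a <- X[cl == 1, "f_same"]; b <- X[cl == 2, "f_same"]
  tab <- rbind(c(sum(a), length(a) - sum(a)), c(sum(b), length(b) - sum(b)))
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_)^2 / exp_)
  expect_equal(same$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical profiles correlate perfectly; planted contrast lowers r
  two <- prevalence_tests(cl, X[, c("f_same", "f_rare")])
  expect_gt(two$profile_correlation[1, 2], 0.9)
})

test_that("chi-square p-values match the contingency oracle over random tables", {
  set.seed(5)
  for (r in 1:50) {
    tab <- matrix(sample(5:80, 4, replace = TRUE), 2)
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_ < 5)) next
    stat <- sum((tab - exp_)^2 / exp_)
    want <- pchisq(stat, 1, lower.tail = FALSE)
    got <- stats::chisq.test(tab, correct = FALSE)$p.value
    expect_equal(got, want, tolerance = 1e-10)
  }
})
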