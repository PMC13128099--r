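test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(subtype_proportions = c(0.5, 0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(generator_config(mci_to_ad_sojourn_mean_days =
                                  c(-1, 100, 100, 100)), "positive")
  expect_error(generator_config(separation = 1.5), "separation")
  expect_error(generator_config(censoring_prob = 2), "censoring_prob")
})

test_that("the same config and seed give a byte-identical cohort; different seeds differ", {
  cfg <- generator_config(n_patients = 15, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(generator_config(n_patients = 15, seed = 22))
  expect_false(identical(a$diagnoses, c$diagnoses))
})

test_that("every patient satisfies the inclusion rules by construction", {
  coh <- cached_cohort(120, seed = 31)
  gt <- coh$ground_truth
  # monotone timelines
  expect_true(all(gt$first_mci_date < gt$first_ad_date))
  conv <- as.numeric(gt$first_ad_date - gt$first_mci_date)
  expect_true(all(conv > 180))
  expect_true(all(gt$age_at_first_mci >= 50))
  # a year of record on both sides of the index
  tl <- state_timelines(coh)
  tl <- tl[match(gt$patient_id, tl$patient_id), ]
  expect_true(all(as.numeric(gt$first_mci_date - tl$first_record_date) >= 365))
  expect_true(all(as.numeric(tl$last_record_date - gt$first_mci_date) >= 365))
  # so the cohort filter excludes nobody
  expect_equal(sum(cohort_filter(coh)$ledger$excluded), 0L)
  # encounter dates strictly increasing per patient
  recs <- encounter_records(coh)
  expect_true(all(vapply(recs, function(r) !is.unsorted(r$date,
                                                        strictly = TRUE),
                         logical(1))))
  # no state-marker codes before their onset dates
  dx <- coh$diagnoses
  mci_first <- setNames(gt$first_mci_date, gt$patient_id)
  ad_first <- setNames(gt$first_ad_date, gt$patient_id)
  mm <- dx$code %in% progphen:::MCI_ICD_CODES
  expect_true(all(dx$date[mm] >= mci_first[dx$patient_id[mm]]))
  aa <- dx$code %in% progphen:::AD_ICD_CODES
  expect_true(all(dx$date[aa] >= ad_first[dx$patient_id[aa]]))
})

test_that("configured sojourn means are recovered within three standard errors", {
  # per-subphenotype MCI-to-AD sojourns: S1 854/577, S2 1236/725, S3 952/628,
  # S4 805/563 days (the generator defaults)
  coh <- cached_cohort(1000, seed = 77)
  cfg <- coh$config
  smry <- ground_truth_summary(coh)
  for (z in 1:4) {
    se <- cfg$mci_to_ad_sojourn_sd_days[z] / sqrt(smry$n[z])
    expect_lt(abs(smry$mci_to_ad_mean[z] -
                    cfg$mci_to_ad_sojourn_mean_days[z]), 3 * se)
  }
})

test_that("ground-truth summary converges to the configured parameters and flags degenerate cases", {
  coh <- cached_cohort(1000, seed = 77)
  cfg <- coh$config
  smry <- ground_truth_summary(coh)
  expect_equal(sum(smry$n), 1000L)
  # subtype shares within 3 SE of the configured proportions
  for (z in 1:4) {
    p <- cfg$subtype_proportions[z]
    expect_lt(abs(smry$n[z] / 1000 - p), 3 * sqrt(p * (1 - p) / 1000))
  }
  # sds in the right ballpark (log-normal truncation shifts them slightly)
  expect_lt(abs(smry$mci_to_ad_sd[1] - 577) / 577, 0.2)

  one <- generate_cohort(generator_config(n_patients = 1, seed = 4))
  s1 <- ground_truth_summary(one)
  expect_equal(nrow(s1), 1L)
  expect_true(is.na(s1$mci_to_ad_sd))

  cens <- generate_cohort(generator_config(n_patients = 25,
                                           censoring_prob = 1, seed = 8))
  expect_true(all(is.na(cens$ground_truth$death_date)))
  expect_true(all(cens$ground_truth$censored))
  expect_equal(ground_truth_summary(cens)$censored_fraction, rep(1, 4))
})

test_that("emitted code frequencies follow the configured Bernoulli profiles", {
  # chi-square goodness of fit on per-window emission counts for a handful
  # of (subtype, state, code) cells at alpha = 0.01
  coh <- cached_cohort(1000, seed = 77)
  cfg <- coh$config
  vocab <- progphen:::synth_vocabulary(40, 24)
  profiles <- progphen:::default_profiles(4, vocab$diagnosis, 0.30, 0.85, 1)
  gt <- coh$ground_truth
  dx <- coh$diagnoses
  tl <- state_timelines(coh)
  anchor <- setNames(tl$first_record_date, tl$patient_id)
  # count windows and hits for subtype 2, state MCI, a signature and a
  # non-signature code
  pats <- gt$patient_id[gt$subtype == 2]
  n_win <- 0L
  hits <- c(0L, 0L)
  codes <- c(vocab$diagnosis[2], vocab$diagnosis[3])  # signature s2 vs s3
  all_dates <- rbind(coh$diagnoses[c("patient_id", "date")],
                     coh$drugs[c("patient_id", "date")],
                     coh$vitals[c("patient_id", "date")])
  for (pid in pats) {
    mci <- gt$first_mci_date[gt$patient_id == pid]
    ad <- gt$first_ad_date[gt$patient_id == pid]
    a <- anchor[pid]
    wins_mci <- seq(ceiling(as.numeric(mci - a) / 90),
                    floor(as.numeric(ad - a - 1) / 90))
    wins_mci <- wins_mci[wins_mci * 90 + a >= mci & wins_mci * 90 + a < ad]
    # emissions only happen in windows holding at least one encounter
    enc_wins <- unique(as.numeric(
      all_dates$date[all_dates$patient_id == pid] - a) %/% 90)
    wins_mci <- intersect(wins_mci, enc_wins)
    n_win <- n_win + length(wins_mci)
    pdx <- dx[dx$patient_id == pid, ]
    for (ci in 1:2) {
      dd <- pdx$date[pdx$code == codes[ci]]
      w <- as.numeric(dd - a) %/% 90
      hits[ci] <- hits[ci] + sum(w %in% wins_mci)
    }
  }
  for (ci in 1:2) {
    # marginal per-window emission rate = prevalence x documentation
    # recurrence (0.9); windows of one patient share the patient's realized
    # condition set, so the SE must be taken at the patient level
    q <- profiles[2, "MCI", codes[ci]] * 0.9
    rate <- hits[ci] / n_win
    se <- sqrt(q * (1 - q) / length(pats))   # conservative patient-level SE
    expect_lt(abs(rate - q), 3 * max(se, 0.02))
  }
})

test_that("separation = 0 makes the subtype profiles identical", {
  vocab <- progphen:::synth_vocabulary(12, 8)
  prof <- progphen:::default_profiles(4, vocab$diagnosis, 0.3, 0.45, 0)
  for (z in 2:4) expect_equal(prof[z, , ], prof[1, , ])
})
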