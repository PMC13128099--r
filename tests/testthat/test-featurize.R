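mk_dx <- function(pid, dates, codes) {
  data.frame(patient_id = pid, date = as.Date(dates), code = codes,
             code_system = "ICD10CM", stringsAsFactors = FALSE)
}

# a minimal eligible patient: MCI at day 400, AD at day 800, records padded
# a year on each side
eligible_dx <- function(pid = "P1", origin = as.Date("2015-01-01"),
                        mci_day = 400, ad_day = 800, last_day = 1300) {
  mk_dx(pid, origin + c(0, mci_day, ad_day, last_day),
        c("I10", "G31.84", "G30", "I10"))
}

test_that("cohort filters implement the study's inclusion rules at their boundaries", {
  origin <- as.Date("2015-01-01")
  demo <- function(pid, age_at_mci, mci_day = 400) data.frame(
    patient_id = pid,
    birth_date = origin + mci_day - round(age_at_mci * 365.25) - 1,
    sex = "F", race_ethnicity = "NH White", stringsAsFactors = FALSE)

  # age 49 excluded, age 50 retained
  coh <- manual_cohort(rbind(eligible_dx("P1"), eligible_dx("P2")),
                       demographics = rbind(demo("P1", 49), demo("P2", 50)))
  flt <- cohort_filter(coh)
  expect_false("P1" %in% flt$eligible)
  expect_true("P2" %in% flt$eligible)
  expect_equal(flt$ledger$excluded[flt$ledger$rule == "age_below_minimum"],
               1L)

  # AD code dated before the MCI code: excluded
  coh <- manual_cohort(rbind(
    mk_dx("P3", origin + c(0, 300, 400, 1300),
          c("I10", "G30", "G31.84", "I10")),
    eligible_dx("P4")),
    demographics = rbind(demo("P3", 70, 400), demo("P4", 70)))
  flt <- cohort_filter(coh)
  expect_false("P3" %in% flt$eligible)
  expect_true("P4" %in% flt$eligible)

  # conversion of exactly 180 days excluded; 181 retained
  coh <- manual_cohort(rbind(
    mk_dx("P5", origin + c(0, 400, 580, 1300),
          c("I10", "G31.84", "G30", "I10")),
    mk_dx("P6", origin + c(0, 400, 581, 1300),
          c("I10", "G31.84", "G30", "I10"))),
    demographics = rbind(demo("P5", 70), demo("P6", 70)))
  flt <- cohort_filter(coh)
  expect_false("P5" %in% flt$eligible)
  expect_true("P6" %in% flt$eligible)

  # less than a year of record before (or after) the index: excluded
  coh <- manual_cohort(rbind(
    mk_dx("P7", origin + c(100, 400, 800, 1300),
          c("I10", "G31.84", "G30", "I10")),   # 300 d before index
    mk_dx("P8", origin + c(0, 400, 700, 760),
          c("I10", "G31.84", "G30", "I10"))),  # 360 d after index
    demographics = rbind(demo("P7", 70), demo("P8", 70)))
  flt <- cohort_filter(coh)
  expect_length(flt$eligible, 0L)
  expect_warning(cohort_filter(coh), "no patients")
})

test_that("vital discretization matches the guideline cutoffs", {
  expect_equal(as.character(bmi_category(c(27, 18.5, 18.6, 24.9, 25, 30))),
               c("overweight", "underweight", "normal", "normal",
                 "overweight", "obesity"))
  expect_true(is.na(bmi_category(NA)))
  expect_error(bmi_category(-1), "negative")
  expect_equal(as.character(bp_category(c(110, 125, 135, 150, 185),
                                        c(70, 75, 70, 85, 95))),
               c("normal", "elevated", "stage1", "stage2", "crisis"))
  # crisis by diastolic alone; stage 2 by diastolic alone
  expect_equal(as.character(bp_category(c(120, 120), c(125, 95))),
               c("crisis", "stage2"))
  expect_true(is.na(bp_category(120, NA)))
})

test_that("windows are half-open, anchored at the first encounter, and labels follow the state machine", {
  origin <- as.Date("2015-01-01")
  # boundary event on day 90 belongs to window 2, not window 1
  dx <- mk_dx("P1", origin + c(0, 90, 400, 800, 1300),
              c("I10", "E11.9", "G31.84", "G30", "I10"))
  fe <- vectorize_cohort(manual_cohort(dx))
  X <- fe$X; w <- fe$windows
  expect_equal(w$window_start, origin + (w$window_index - 1L) * 90)
  expect_equal(unname(X[1, "phecode_401.1"]), 1L)   # I10 on day 0 -> window 1
  expect_equal(unname(X[1, "phecode_250.2"]), 0L)   # E11.9 on day 90 -> window 2
  expect_equal(unname(X[2, "phecode_250.2"]), 1L)
  # state: PreMCI until the first MCI code, then MCI, then AD, absorbing
  expect_equal(w$state[1], "PreMCI")
  expect_equal(w$state[w$window_start <= origin + 400 &
                         origin + 400 < w$window_start + 90], "MCI")
  expect_true(all(w$state[w$window_start > origin + 800] == "AD"))
  # labels are the next window's state; the final window is unlabeled
  expect_equal(w$label[-nrow(w)], w$state[-1])
  expect_true(is.na(w$label[nrow(w)]))
  # label sequence is monotone over PreMCI < MCI < AD
  ord <- match(w$state, c("PreMCI", "MCI", "AD"))
  expect_true(all(diff(ord) >= 0))
})

test_that("exactly one bit is set per demographic block and per present vital block", {
  coh <- cached_cohort(12, seed = 13)
  fe <- vectorize_cohort(coh)
  bl <- fe$feature_space$blocks
  for (b in c("age", "sex", "race")) {
    expect_true(all(rowSums(fe$X[, bl[[b]], drop = FALSE]) == 1L))
  }
  for (b in c("bmi", "bp", "smoking")) {
    expect_true(all(rowSums(fe$X[, bl[[b]], drop = FALSE]) <= 1L))
  }
  expect_true(all(fe$X %in% c(0L, 1L)))
})

test_that("uniform 5-year age bins set exactly one age bit", {
  expect_equal(progphen:::age_bin(c(49, 50, 54, 76, 89, 90, 101)),
               c("age_lt50", "age_50_54", "age_50_54", "age_75_79",
                 "age_85_89", "age_90plus", "age_90plus"))
})

test_that("no leakage: erasing data after a window changes no features up to it", {
  coh <- cached_cohort(6, seed = 17)
  fe <- vectorize_cohort(coh)
  cut_date <- as.Date("2016-06-01")
  truncate_tab <- function(df) df[df$date <= cut_date, , drop = FALSE]
  coh2 <- coh
  for (tab in c("diagnoses", "drugs", "vitals")) {
    coh2[[tab]] <- truncate_tab(coh2[[tab]])
  }
  keep <- vapply(unique(fe$windows$patient_id), function(p) {
    sum(fe$windows$patient_id == p & fe$windows$window_end <= cut_date)
  }, integer(1))
  ok <- names(keep)[keep >= 2]
  fe2 <- vectorize_cohort(coh2, patient_ids = ok)
  for (p in ok) {
    w1 <- which(fe$windows$patient_id == p &
                  fe$windows$window_end <= cut_date)
    w2 <- which(fe2$windows$patient_id == p &
                  fe2$windows$window_end <= cut_date)
    common <- intersect(fe$windows$window_index[w1],
                        fe2$windows$window_index[w2])
    r1 <- w1[match(common, fe$windows$window_index[w1])]
    r2 <- w2[match(common, fe2$windows$window_index[w2])]
    expect_gt(length(common), 0)
    expect_equal(fe2$X[r2, , drop = FALSE], fe$X[r1, , drop = FALSE])
  }
})

test_that("re-vectorizing the same cohort gives an identical feature space and matrix", {
  coh <- cached_cohort(6, seed = 17)
  a <- vectorize_cohort(coh)
  b <- vectorize_cohort(coh)
  expect_identical(a$feature_space$names, b$feature_space$names)
  expect_identical(a$X, b$X)
})

test_that("patients spanning fewer than two windows are dropped and reported", {
  origin <- as.Date("2015-01-01")
  dx <- rbind(mk_dx("P1", origin + c(0, 30), c("I10", "I10")),
              eligible_dx("P2"))
  fe <- vectorize_cohort(manual_cohort(dx))
  expect_equal(fe$dropped_patients, "P1")
  expect_false("P1" %in% fe$windows$patient_id)
})
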