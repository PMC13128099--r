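# Cohort filters and conversion of encounter streams into chronological
# sequences of binary "enhanced encounter" vectors on a 90-day grid, with
# next-window progression-state labels.
#
# State rule: a patient is Pre-MCI until the first MCI diagnosis code, MCI
# from that date, and AD from the first AD code onward. States are absorbing,
# so per-patient label sequences are monotone over PreMCI < MCI < AD.

STATE_LEVELS <- c("PreMCI", "MCI", "AD")

#' Observed state-transition timelines
#'
#' First/last record dates and first MCI / first AD diagnosis-code dates per
#' patient, computed from the observed code streams (not from any synthetic
#' ground truth).
#'
#' @param cohort an `ehr_cohort`
#' @param mci_codes,ad_codes ICD code lists defining the states
#' @return data frame with one row per patient
#' @export
state_timelines <- function(cohort, mci_codes = MCI_ICD_CODES,
                            ad_codes = AD_ICD_CODES) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  ids <- cohort$demographics$patient_id
  all_dates <- rbind(cohort$diagnoses[c("patient_id", "date")],
                     cohort$drugs[c("patient_id", "date")],
                     cohort$vitals[c("patient_id", "date")])
  min_by <- function(df) {
    if (nrow(df) == 0L) return(setNames(as.Date(character(0)), character(0)))
    agg <- stats::aggregate(date ~ patient_id, df, min)
    setNames(agg$date, agg$patient_id)
  }
  max_by <- function(df) {
    if (nrow(df) == 0L) return(setNames(as.Date(character(0)), character(0)))
    agg <- stats::aggregate(date ~ patient_id, df, max)
    setNames(agg$date, agg$patient_id)
  }
  firsts <- min_by(all_dates)
  lasts <- max_by(all_dates)
  mci <- min_by(cohort$diagnoses[cohort$diagnoses$code %in% mci_codes,
                                 c("patient_id", "date")])
  ad <- min_by(cohort$diagnoses[cohort$diagnoses$code %in% ad_codes,
                                c("patient_id", "date")])
  data.frame(
    patient_id = ids,
    first_record_date = as.Date(unname(firsts[ids]), origin = "1970-01-01"),
    last_record_date = as.Date(unname(lasts[ids]), origin = "1970-01-01"),
    first_mci_date = as.Date(unname(mci[ids]), origin = "1970-01-01"),
    first_ad_date = as.Date(unname(ad[ids]), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
}

#' Apply the study's cohort-inclusion filters
#'
#' Rules, applied in order (each counted over survivors of the previous
#' rules): (1) at least one MCI diagnosis code; (2) age 50 or older at the
#' first MCI diagnosis; (3) at least one AD diagnosis code (the cohort is the
#' MCI-to-AD converters); (4) no AD code on or before the first MCI code;
#' (5) at least 365 days of record before the index date (first MCI
#' diagnosis); (6) at least 365 days of record after the index date;
#' (7) conversion time strictly greater than 180 days ("more than six
#' months", read at day resolution).
#'
#' @param cohort an `ehr_cohort`
#' @param mci_codes,ad_codes ICD code lists defining the states
#' @param min_age minimum age at first MCI (years)
#' @param min_days_before,min_days_after required record span around the index
#' @param min_conversion_days conversion must exceed this many days
#' @return list with `eligible` (patient ids), `ledger` (exclusion counts per
#'   rule, in order) and `timelines` (the [state_timelines()] table)
#' @export
cohort_filter <- function(cohort, mci_codes = MCI_ICD_CODES,
                          ad_codes = AD_ICD_CODES, min_age = 50,
                          min_days_before = 365, min_days_after = 365,
                          min_conversion_days = 180) {
  tl <- state_timelines(cohort, mci_codes, ad_codes)
  demo <- cohort$demographics
  birth <- setNames(demo$birth_date, demo$patient_id)[tl$patient_id]
  age_at_mci <- floor(as.numeric(tl$first_mci_date - birth) / 365.25)
  conversion <- as.numeric(tl$first_ad_date - tl$first_mci_date)

  rules <- list(
    no_mci_code = is.na(tl$first_mci_date),
    age_below_minimum = !is.na(age_at_mci) & age_at_mci < min_age,
    no_ad_code = is.na(tl$first_ad_date),
    ad_before_mci = !is.na(conversion) & conversion <= 0,
    insufficient_record_before_index =
      as.numeric(tl$first_mci_date - tl$first_record_date) < min_days_before,
    insufficient_record_after_index =
      as.numeric(tl$last_record_date - tl$first_mci_date) < min_days_after,
    conversion_within_six_months =
      !is.na(conversion) & conversion > 0 & conversion <= min_conversion_days
  )
  alive <- rep(TRUE, nrow(tl))
  ledger <- integer(length(rules))
  names(ledger) <- names(rules)
  for (r in seq_along(rules)) {
    drop <- alive & rules[[r]] & !is.na(rules[[r]])
    ledger[r] <- sum(drop)
    alive <- alive & !drop
  }
  eligible <- tl$patient_id[alive]
  if (length(eligible) == 0L) warning("no patients remain after filtering")
  list(eligible = eligible,
       ledger = data.frame(rule = names(ledger), excluded = unname(ledger)),
       timelines = tl)
}

# ---- vital-sign discretization ----------------------------------------

#' Discretize body-mass index
#'
#' Categories: underweight (<= 18.5), normal weight (18.5-24.9), overweight
#' (25-29.9), obesity (>= 30). NA in, NA out.
#' @param bmi numeric, kg/m^2
#' @return factor with levels underweight/normal/overweight/obesity
#' @export
bmi_category <- function(bmi) {
  if (any(!is.na(bmi) & bmi < 0)) stop("negative bmi", call. = FALSE)
  lv <- c("underweight", "normal", "overweight", "obesity")
  out <- rep(NA_character_, length(bmi))
  out[!is.na(bmi) & bmi <= 18.5] <- "underweight"
  out[!is.na(bmi) & bmi > 18.5 & bmi < 25] <- "normal"
  out[!is.na(bmi) & bmi >= 25 & bmi < 30] <- "overweight"
  out[!is.na(bmi) & bmi >= 30] <- "obesity"
  factor(out, levels = lv)
}

#' Discretize blood pressure into the five guideline classes
#'
#' 2017 ACC/AHA cutoffs: normal (<120 and <80), elevated (120-129 and <80),
#' stage-1 hypertension (130-139 or 80-89), stage-2 hypertension (>= 140 or
#' >= 90), hypertensive crisis (> 180 or > 120). Both readings must be
#' present; otherwise NA.
#'
#' @param systolic,diastolic mmHg
#' @return factor with levels normal/elevated/stage1/stage2/crisis
#' @export
bp_category <- function(systolic, diastolic) {
  lv <- c("normal", "elevated", "stage1", "stage2", "crisis")
  out <- rep(NA_character_, length(systolic))
  ok <- !is.na(systolic) & !is.na(diastolic)
  out[ok] <- "normal"
  out[ok & systolic >= 120 & systolic < 130 & diastolic < 80] <- "elevated"
  out[ok & ((systolic >= 130 & systolic < 140) |
              (diastolic >= 80 & diastolic < 90))] <- "stage1"
  out[ok & (systolic >= 140 | diastolic >= 90)] <- "stage2"
  out[ok & (systolic > 180 | diastolic > 120)] <- "crisis"
  factor(out, levels = lv)
}

smoking_category <- function(x) {
  lv <- c("current", "former", "non-smoker", "others")
  out <- ifelse(is.na(x) | x == "", NA_character_,
                ifelse(x %in% lv, x, "others"))
  factor(out, levels = lv)
}

AGE_BIN_LABELS <- c("age_lt50", paste0("age_", seq(50, 85, 5), "_",
                                       seq(54, 89, 5)), "age_90plus")

age_bin <- function(age) {
  idx <- ifelse(age < 50, 1L, pmin(2L + (age - 50) %/% 5, 10L))
  AGE_BIN_LABELS[idx]
}

RACE_LEVELS <- c("NH White", "NH Black", "Hispanic", "Other", "Unknown")

# ---- feature space -----------------------------------------------------

#' Construct the shared binary feature space
#'
#' Ordered blocks: 5-year age bins (from 50, with an under-50 and a 90+ bin),
#' sex, race-ethnicity, Phecodes (plus an `unmapped` catch-all), ATC level-3
#' classes (plus `unmapped`), and discretized vitals (BMI, blood pressure,
#' smoking). The space is fixed by the code maps, so re-vectorizing the same
#' cohort yields an identical ordering.
#'
#' @param maps list with `diagnosis` and `drug` [load_code_map()] objects
#' @return object of class `feature_space` with `names` and `blocks`
#' @export
feature_space <- function(maps = default_code_maps()) {
  phe <- c(sort(unique(maps$diagnosis$mapping)), "unmapped")
  atc <- c(sort(unique(maps$drug$mapping)), "unmapped")
  blocks <- list(
    age = AGE_BIN_LABELS,
    sex = c("sex_F", "sex_M", "sex_other"),
    race = paste0("race_", gsub(" ", "_", RACE_LEVELS)),
    phecode = paste0("phecode_", phe),
    atc = paste0("atc_", atc),
    bmi = paste0("bmi_", levels(bmi_category(numeric(0)))),
    bp = paste0("bp_", levels(bp_category(numeric(0), numeric(0)))),
    smoking = paste0("smoking_", c("current", "former", "non_smoker",
                                   "others"))
  )
  nm <- unlist(blocks, use.names = FALSE)
  idx <- split(seq_along(nm), rep(names(blocks), lengths(blocks)))
  structure(list(names = nm, blocks = idx[names(blocks)],
                 phecode_levels = phe, atc_levels = atc),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d features: %s\n", length(x$names),
              paste(sprintf("%s=%d", names(x$blocks), lengths(x$blocks)),
                    collapse = ", ")))
  invisible(x)
}

# ---- windowing and vectorization --------------------------------------

#' Build enhanced encounter windows and binary feature vectors
#'
#' Tiles each patient's record with contiguous half-open windows
#' `[start, start + window_days)` anchored at the first encounter. A code
#' feature bit is 1 iff the mapped Phecode / ATC-3 category occurs at least
#' once in the window (an event dated exactly on a window boundary belongs to
#' the *next* window). Vitals use the latest measurement within the window;
#' demographic bits are re-evaluated every window (age at window start).
#' The window's progression state is the state attained by the window's last
#' day, and its supervised label is the state of the following window; the
#' final window has label NA (retained for sequence building, excluded from
#' training). Patients with fewer than two windows are dropped and reported.
#'
#' @param cohort an `ehr_cohort`
#' @param patient_ids patients to vectorize (e.g. [cohort_filter()]'s
#'   `eligible`); defaults to all
#' @param maps code maps from [default_code_maps()] or [load_code_map()]
#' @param window_days window width in days
#' @param mci_codes,ad_codes ICD code lists defining the states
#' @return object of class `encounter_features`: `feature_space`, binary
#'   matrix `X` (windows x features), window metadata `windows`
#'   (patient_id, window_index, window_start, window_end, state, label) and
#'   `dropped_patients`
#' @export
vectorize_cohort <- function(cohort, patient_ids = NULL,
                             maps = default_code_maps(), window_days = 90L,
                             mci_codes = MCI_ICD_CODES,
                             ad_codes = AD_ICD_CODES) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  fs <- feature_space(maps)
  tl <- state_timelines(cohort, mci_codes, ad_codes)
  ids <- patient_ids %||% cohort$demographics$patient_id
  tl <- tl[match(ids, tl$patient_id), , drop = FALSE]

  ok_span <- !is.na(tl$first_record_date) &
    as.numeric(tl$last_record_date - tl$first_record_date) >= window_days
  dropped <- ids[!ok_span]
  tl <- tl[ok_span, , drop = FALSE]
  ids <- tl$patient_id
  if (length(ids) == 0L) stop("no patients with at least two windows",
                              call. = FALSE)

  anchor <- setNames(tl$first_record_date, ids)
  n_win <- setNames(as.integer(as.numeric(tl$last_record_date - anchor) %/%
                                 window_days) + 1L, ids)
  row_start <- setNames(c(0L, cumsum(unname(n_win)))[seq_along(ids)], ids)
  n_rows <- sum(n_win)

  meta <- data.frame(
    patient_id = rep(ids, n_win),
    window_index = unlist(lapply(n_win, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)
  meta$window_start <- anchor[meta$patient_id] +
    (meta$window_index - 1L) * window_days
  meta$window_end <- meta$window_start + window_days

  X <- matrix(0L, n_rows, length(fs$names),
              dimnames = list(NULL, fs$names))
  col_of <- setNames(seq_along(fs$names), fs$names)

  set_bits <- function(pid, date, colname) {
    keep <- pid %in% ids & !is.na(colname)
    pid <- pid[keep]; date <- date[keep]; colname <- colname[keep]
    win <- as.integer(as.numeric(date - anchor[pid]) %/% window_days)
    keep2 <- win >= 0L & win < n_win[pid]
    rows <- row_start[pid[keep2]] + win[keep2] + 1L
    X[cbind(rows, col_of[colname[keep2]])] <<- 1L
  }

  dx <- cohort$diagnoses
  set_bits(dx$patient_id, dx$date,
           paste0("phecode_", apply_code_map(dx$code, maps$diagnosis)))
  rx <- cohort$drugs
  set_bits(rx$patient_id, rx$date,
           paste0("atc_", apply_code_map(rx$code, maps$drug)))

  # vitals: latest measurement per window wins; rows are date-sorted so a
  # later assignment to the same (row, col-block) pair overwrites nothing --
  # instead keep only the last non-NA measurement per window per block
  vt <- cohort$vitals[cohort$vitals$patient_id %in% ids, , drop = FALSE]
  if (nrow(vt) > 0L) {
    vt <- vt[order(vt$patient_id, vt$date), , drop = FALSE]
    vt$win <- as.integer(as.numeric(vt$date - anchor[vt$patient_id]) %/%
                           window_days)
    vt <- vt[vt$win >= 0L & vt$win < n_win[vt$patient_id], , drop = FALSE]
    key <- paste(vt$patient_id, vt$win)
    last_of <- function(values, cat_fun) {
      present <- !is.na(values)
      idx <- tapply(seq_len(nrow(vt))[present], key[present], max)
      idx
    }
    for (block in list(
      list(val = vt$bmi, cat = paste0("bmi_", bmi_category(vt$bmi))),
      list(val = ifelse(is.na(vt$systolic) | is.na(vt$diastolic), NA, 1),
           cat = paste0("bp_", bp_category(vt$systolic, vt$diastolic))),
      list(val = ifelse(is.na(smoking_category(vt$smoking)), NA, 1),
           cat = paste0("smoking_",
                        gsub("-", "_", smoking_category(vt$smoking)))))) {
      idx <- last_of(block$val)
      idx <- idx[!is.na(idx)]
      if (length(idx) > 0L) {
        rows <- row_start[vt$patient_id[idx]] + vt$win[idx] + 1L
        X[cbind(rows, col_of[block$cat[idx]])] <- 1L
      }
    }
  }

  # demographics, re-evaluated per window
  demo <- cohort$demographics
  birth <- setNames(demo$birth_date, demo$patient_id)[meta$patient_id]
  age <- floor(as.numeric(meta$window_start - birth) / 365.25)
  X[cbind(seq_len(n_rows), col_of[age_bin(age)])] <- 1L
  sex <- setNames(demo$sex, demo$patient_id)[meta$patient_id]
  sex_col <- ifelse(sex %in% c("F", "M"), paste0("sex_", sex), "sex_other")
  X[cbind(seq_len(n_rows), col_of[sex_col])] <- 1L
  race <- setNames(demo$race_ethnicity, demo$patient_id)[meta$patient_id]
  race[!(race %in% RACE_LEVELS)] <- "Unknown"
  X[cbind(seq_len(n_rows), col_of[paste0("race_", gsub(" ", "_", race))])] <- 1L

  # progression state (by the window's last day) and next-window label
  mci_d <- setNames(tl$first_mci_date, ids)[meta$patient_id]
  ad_d <- setNames(tl$first_ad_date, ids)[meta$patient_id]
  last_day <- meta$window_end - 1L
  state_num <- 1L +
    (!is.na(mci_d) & last_day >= mci_d) +
    (!is.na(ad_d) & last_day >= ad_d)
  meta$state <- STATE_LEVELS[state_num]
  is_last <- meta$window_index == n_win[meta$patient_id]
  meta$label <- c(meta$state[-1L], NA_character_)
  meta$label[is_last] <- NA_character_

  structure(list(feature_space = fs, X = X, windows = meta,
                 dropped_patients = dropped, window_days = window_days),
            class = "encounter_features")
}

#' @export
print.encounter_features <- function(x, ...) {
  cat(sprintf("<encounter_features> %d windows x %d features, %d patients\n",
              nrow(x$X), ncol(x$X), length(unique(x$windows$patient_id))))
  invisible(x)
}
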