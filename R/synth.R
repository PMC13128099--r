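# Seeded synthetic longitudinal EHR generator with planted progression
# subphenotypes. The generative model is a three-state semi-Markov process
# Pre-MCI -> MCI -> AD with log-normal sojourn times, subtype- and
# state-specific Bernoulli code-emission profiles on a 90-day grid, Poisson
# encounter arrivals, and post-AD death with optional right-censoring.

# ICD codes defining the MCI and AD states (the study's code lists).
MCI_ICD_CODES <- c("331.83", "294.9", "G31.84", "F06.7", "F09",
                   "R41.840", "R41.841", "R41.89", "R41.9")
AD_ICD_CODES <- c("331.0", "G30", "G30.0", "G30.1", "G30.8", "G30.9")

# Marker codes the generator emits to date the state transitions.
MCI_MARKER_CODE <- "G31.84"
AD_MARKER_CODE <- "G30.9"

synth_vocabulary <- function(n_dx, n_rx) {
  maps <- default_code_maps()
  dx_pool <- setdiff(names(maps$diagnosis$mapping),
                     c(MCI_ICD_CODES, AD_ICD_CODES))
  rx_pool <- names(maps$drug$mapping)
  if (n_dx > length(dx_pool) || n_rx > length(rx_pool)) {
    stop(sprintf(
      "code_vocabulary_sizes exceed the packaged vocabulary (max %d diagnosis, %d drug)",
      length(dx_pool), length(rx_pool)), call. = FALSE)
  }
  list(diagnosis = dx_pool[seq_len(n_dx)], drug = rx_pool[seq_len(n_rx)])
}

# Subtype x state x code Bernoulli emission probabilities. Profiles are a
# shared base prevalence (geometric decay so a few codes dominate, mirroring
# the long-tailed prevalence of real comorbidity tables), multiplied by a
# state severity factor, plus subtype-specific signature offsets scaled by
# `separation`: each subtype's signature codes are elevated for it and
# slightly suppressed for the others, so at separation = 1 the subtypes have
# clearly distinct comorbidity/medication profiles (the planted structure
# the pipeline is meant to recover) while separation = 0 collapses all
# subtypes onto the shared base.
default_profiles <- function(n_subtypes, codes, base0, offset, separation) {
  n_code <- length(codes)
  base <- pmax(base0 * 0.88^(seq_len(n_code) - 1L), 0.02)
  state_mult <- c(1, 1.3, 1.6)
  signature <- ((seq_len(n_code) - 1L) %% n_subtypes) + 1L
  arr <- array(0, dim = c(n_subtypes, 3L, n_code),
               dimnames = list(NULL, c("PreMCI", "MCI", "AD"), codes))
  for (z in seq_len(n_subtypes)) {
    for (s in 1:3) {
      p <- base * state_mult[s]
      p[signature == z] <- p[signature == z] + offset * separation
      p[signature != z] <- p[signature != z] * (1 - 0.85 * separation)
      arr[z, s, ] <- clamp(p, 0.01, 0.95)
    }
  }
  arr
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: four
#' subphenotypes with MCI-to-AD sojourn means (854, 1236, 952, 805) days and
#' standard deviations (577, 725, 628, 563); pre-MCI record durations equal to
#' the reported first-record-to-AD times minus the sojourns; a subtype mix
#' dominated by the largest reported subphenotype (0.51) with the remainder
#' split evenly; age at first MCI drawn Normal(76, 8.88) truncated at 50; and
#' demographics drawn from the reported cohort percentages.
#'
#' `separation` in [0, 1] is the single difficulty dial: it scales both the
#' subtype-specific emission-profile offsets and the spread of the subtype
#' timing parameters (sojourn, pre-MCI duration, survival) around their
#' common mean, so that at `separation = 0` the subtypes are fully
#' exchangeable and at `separation = 1` the configured per-subtype values
#' apply unchanged.
#'
#' @param n_patients cohort size
#' @param n_subtypes number of planted subphenotypes
#' @param subtype_proportions probability vector summing to 1
#' @param mci_to_ad_sojourn_mean_days,mci_to_ad_sojourn_sd_days per-subtype
#'   MCI-to-AD sojourn mean/sd (days)
#' @param pre_mci_duration_mean_days,pre_mci_duration_sd_days per-subtype
#'   length of record before first MCI (days)
#' @param post_ad_survival_mean_days,post_ad_survival_sd_days per-subtype
#'   survival after first AD (days)
#' @param encounter_rate_per_90days expected encounters per 90-day window
#' @param code_vocabulary_sizes named counts for `diagnosis` and `drug`
#'   concepts drawn from the packaged vocabulary
#' @param subtype_prevalence_profiles optional list with arrays `diagnosis`
#'   and `drug` of dim (subtype, state, code); built from `separation` when
#'   NULL
#' @param separation difficulty dial in [0, 1], see Details
#' @param censoring_prob probability a patient's death date is censored
#' @param seed integer RNG seed
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_patients = 300L,
                             n_subtypes = 4L,
                             subtype_proportions = c(0.51, 0.17, 0.16, 0.16),
                             mci_to_ad_sojourn_mean_days = c(854, 1236, 952, 805),
                             mci_to_ad_sojourn_sd_days = c(577, 725, 628, 563),
                             pre_mci_duration_mean_days = c(1541, 1703, 1591, 1560),
                             pre_mci_duration_sd_days = NULL,
                             post_ad_survival_mean_days = c(1460, 900, 950, 1500),
                             post_ad_survival_sd_days = NULL,
                             encounter_rate_per_90days = 3,
                             code_vocabulary_sizes = c(diagnosis = 40L, drug = 24L),
                             subtype_prevalence_profiles = NULL,
                             separation = 1,
                             censoring_prob = 0.2,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_subtypes = as.integer(n_subtypes),
    subtype_proportions = as.numeric(subtype_proportions),
    mci_to_ad_sojourn_mean_days = as.numeric(mci_to_ad_sojourn_mean_days),
    mci_to_ad_sojourn_sd_days = as.numeric(mci_to_ad_sojourn_sd_days),
    pre_mci_duration_mean_days = as.numeric(pre_mci_duration_mean_days),
    pre_mci_duration_sd_days =
      as.numeric(pre_mci_duration_sd_days %||%
                   (0.35 * pre_mci_duration_mean_days)),
    post_ad_survival_mean_days = as.numeric(post_ad_survival_mean_days),
    post_ad_survival_sd_days =
      as.numeric(post_ad_survival_sd_days %||%
                   (0.7 * post_ad_survival_mean_days)),
    encounter_rate_per_90days = as.numeric(encounter_rate_per_90days),
    code_vocabulary_sizes = code_vocabulary_sizes,
    subtype_prevalence_profiles = subtype_prevalence_profiles,
    separation = as.numeric(separation),
    censoring_prob = as.numeric(censoring_prob),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  k <- cfg$n_subtypes
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (length(cfg$subtype_proportions) != k ||
      any(cfg$subtype_proportions < 0) ||
      abs(sum(cfg$subtype_proportions) - 1) > 1e-8) {
    stop("subtype_proportions must be a length-n_subtypes vector summing to 1",
         call. = FALSE)
  }
  for (f in c("mci_to_ad_sojourn_mean_days", "mci_to_ad_sojourn_sd_days",
              "pre_mci_duration_mean_days", "pre_mci_duration_sd_days",
              "post_ad_survival_mean_days", "post_ad_survival_sd_days")) {
    if (length(cfg[[f]]) != k || any(cfg[[f]] <= 0)) {
      stop(sprintf("%s must be %d positive values", f, k), call. = FALSE)
    }
  }
  if (cfg$encounter_rate_per_90days <= 0) {
    stop("encounter_rate_per_90days must be positive", call. = FALSE)
  }
  if (cfg$separation < 0 || cfg$separation > 1) {
    stop("separation must be in [0, 1]", call. = FALSE)
  }
  if (cfg$censoring_prob < 0 || cfg$censoring_prob > 1) {
    stop("censoring_prob must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# Shrink per-subtype parameter vectors toward their proportion-weighted mean
# so separation = 0 makes subtypes exchangeable in timing as well as profile.
shrink_to_common <- function(x, w, separation) {
  m <- sum(x * w)
  m + separation * (x - m)
}

#' Generate a synthetic longitudinal EHR cohort
#'
#' Simulates `config$n_patients` patients through the three-state process
#' Pre-MCI -> MCI -> AD. All patients satisfy the downstream cohort-inclusion
#' rules by construction: age >= 50 at first MCI, conversion time > 180 days,
#' and at least 365 days of records before and after the index (first MCI)
#' date. Encounters arrive as a homogeneous Poisson process at
#' `encounter_rate_per_90days`. The subtype profiles are patient-level
#' prevalences: each patient's chronic condition/medication set is realized
#' once against the cumulative state-specific prevalence (so conditions
#' accumulate as the disease stage advances), and active conditions are then
#' documented in each 90-day window with recurrence probability 0.9, so the
#' per-window marginal emission rate for a code is 0.9 times its prevalence
#' in the current state. State-marker diagnoses are guaranteed on the
#' transition dates themselves. Same config and seed give a byte-identical
#' cohort.
#'
#' @param config a [generator_config()]
#' @return an `ehr_cohort` whose `ground_truth` element holds the per-patient
#'   subtype label and true state-change dates
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  k <- config$n_subtypes
  w <- config$subtype_proportions
  sep <- config$separation
  n <- config$n_patients
  vocab <- synth_vocabulary(config$code_vocabulary_sizes[["diagnosis"]],
                            config$code_vocabulary_sizes[["drug"]])
  profiles <- config$subtype_prevalence_profiles %||% list(
    diagnosis = default_profiles(k, vocab$diagnosis, 0.30, 0.85, sep),
    drug = default_profiles(k, vocab$drug, 0.22, 0.75, sep)
  )

  soj_mean <- shrink_to_common(config$mci_to_ad_sojourn_mean_days, w, sep)
  soj_sd <- shrink_to_common(config$mci_to_ad_sojourn_sd_days, w, sep)
  pre_mean <- shrink_to_common(config$pre_mci_duration_mean_days, w, sep)
  pre_sd <- shrink_to_common(config$pre_mci_duration_sd_days, w, sep)
  sur_mean <- shrink_to_common(config$post_ad_survival_mean_days, w, sep)
  sur_sd <- shrink_to_common(config$post_ad_survival_sd_days, w, sep)

  subtype <- sample.int(k, n, replace = TRUE, prob = w)
  age_mci <- rnorm_trunc(n, 76, 8.88, lower = 50)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.6166, 0.3834))
  race <- sample(c("NH White", "NH Black", "Hispanic", "Other", "Unknown"),
                 n, replace = TRUE,
                 prob = c(0.6483, 0.1648, 0.1085, 0.0253, 0.0531))
  mci_date <- as.Date("2015-01-01") + sample.int(1461L, n, replace = TRUE) - 1L
  # record length before first MCI (>= 366 d => one-year-before rule holds)
  pre_days <- round(vapply(seq_len(n), function(i) {
    rlnorm_meansd(1, pre_mean[subtype[i]], pre_sd[subtype[i]], lower = 366)
  }, numeric(1)))
  # conversion time (> 180 d rule holds by construction)
  soj_days <- round(vapply(seq_len(n), function(i) {
    rlnorm_meansd(1, soj_mean[subtype[i]], soj_sd[subtype[i]], lower = 181)
  }, numeric(1)))
  # post-AD survival; jointly with the sojourn it must leave >= 365 d of
  # record after the index date
  sur_days <- round(vapply(seq_len(n), function(i) {
    lo <- max(31, 367 - soj_days[i])
    rlnorm_meansd(1, sur_mean[subtype[i]], sur_sd[subtype[i]], lower = lo)
  }, numeric(1)))
  censored <- stats::runif(n) < config$censoring_prob
  # censoring time: uniform between the one-year-after-index floor and death
  cens_offset <- vapply(seq_len(n), function(i) {
    lo <- max(1, 366 - soj_days[i])
    round(stats::runif(1, lo, sur_days[i]))
  }, numeric(1))

  first_date <- mci_date - pre_days
  ad_date <- mci_date + soj_days
  death_date <- ad_date + sur_days
  end_date <- ifelse(censored, ad_date + cens_offset, death_date)
  end_date <- as.Date(end_date, origin = "1970-01-01")

  patient_id <- sprintf("P%05d", seq_len(n))
  smoking_status <- sample(c("current", "former", "non-smoker", "others"),
                           n, replace = TRUE,
                           prob = c(0.12, 0.30, 0.53, 0.05))

  dx_rows <- vector("list", n)
  rx_rows <- vector("list", n)
  vt_rows <- vector("list", n)
  rate <- config$encounter_rate_per_90days
  n_dx <- length(vocab$diagnosis)
  n_rx <- length(vocab$drug)

  for (i in seq_len(n)) {
    span <- as.integer(end_date[i] - first_date[i])
    mci_day <- as.integer(mci_date[i] - first_date[i])
    ad_day <- as.integer(ad_date[i] - first_date[i])
    nwin <- span %/% 90L + 1L
    counts <- stats::rpois(nwin, rate)
    days <- unlist(lapply(seq_len(nwin), function(wi) {
      if (counts[wi] == 0L) return(integer(0))
      lo <- (wi - 1L) * 90L
      hi <- min(lo + 89L, span)
      if (hi < lo) return(integer(0))
      lo + sample.int(hi - lo + 1L, counts[wi], replace = TRUE) - 1L
    }))
    days <- sort(unique(c(0L, mci_day, ad_day, span, days)))
    days <- days[days <= span]
    win_of <- days %/% 90L
    state_of_day <- function(d) 1L + (d >= mci_day) + (d >= ad_day)
    wins <- sort(unique(win_of))
    win_state <- state_of_day(wins * 90L)
    first_enc <- days[match(wins, win_of)]

    # comorbidity and drug emissions. The profiles are *patient-level*
    # prevalences (as in prevalence-based subphenotype characterization):
    # one uniform draw per patient per code decides, against the cumulative
    # state-specific prevalence, whether the condition is active in each
    # state -- conditions are chronic and accumulate as the prevalence
    # rises with disease stage. Active conditions are then documented in
    # each window with a fixed recurrence probability, attached to the
    # window's first encounter.
    z <- subtype[i]
    pd <- profiles$diagnosis[z, win_state, , drop = FALSE]
    dim(pd) <- c(length(wins), n_dx)
    u_dx <- stats::runif(n_dx)
    active_dx <- sweep(pd, 2L, u_dx, ">")
    dx_hit <- which(matrix(stats::runif(length(pd)) < 0.9, nrow(pd)) &
                      active_dx, arr.ind = TRUE)
    pr <- profiles$drug[z, win_state, , drop = FALSE]
    dim(pr) <- c(length(wins), n_rx)
    u_rx <- stats::runif(n_rx)
    active_rx <- sweep(pr, 2L, u_rx, ">")
    rx_hit <- which(matrix(stats::runif(length(pr)) < 0.9, nrow(pr)) &
                      active_rx, arr.ind = TRUE)

    dx_day <- first_enc[dx_hit[, 1L]]
    dx_code <- vocab$diagnosis[dx_hit[, 2L]]
    rx_day <- first_enc[rx_hit[, 1L]]
    rx_code <- vocab$drug[rx_hit[, 2L]]

    # state markers: guaranteed on the transition dates, recurrent afterwards
    mci_wins <- wins[win_state == 2L]
    mci_rep <- first_enc[match(mci_wins[stats::runif(length(mci_wins)) < 0.6],
                               wins)]
    ad_wins <- wins[win_state == 3L]
    ad_rep <- first_enc[match(ad_wins[stats::runif(length(ad_wins)) < 0.6],
                              wins)]
    mci_days_out <- unique(c(mci_day, mci_rep[mci_rep >= mci_day]))
    ad_days_out <- unique(c(ad_day, ad_rep[ad_rep >= ad_day]))

    dx_rows[[i]] <- data.frame(
      patient_id = patient_id[i],
      date = first_date[i] + c(dx_day, mci_days_out, ad_days_out),
      code = c(dx_code, rep(MCI_MARKER_CODE, length(mci_days_out)),
               rep(AD_MARKER_CODE, length(ad_days_out))),
      code_system = "ICD10CM", stringsAsFactors = FALSE)
    rx_rows[[i]] <- data.frame(
      patient_id = rep(patient_id[i], length(rx_day)),
      date = first_date[i] + rx_day,
      code = rx_code, code_system = rep("RXNORM", length(rx_day)),
      stringsAsFactors = FALSE)

    # one vitals measurement per window, at its first encounter; BMI drifts
    # down and systolic pressure varies mildly by subtype
    st <- win_state
    vt_rows[[i]] <- data.frame(
      patient_id = patient_id[i],
      date = first_date[i] + first_enc,
      bmi = round(pmax(stats::rnorm(length(wins), 27.5 - 1.0 * (st - 1L),
                                    4.2), 14), 1),
      systolic = round(pmax(stats::rnorm(
        length(wins),
        128 + sep * seq(8, -8, length.out = k)[z], 14), 80)),
      diastolic = round(pmax(stats::rnorm(length(wins), 78, 9), 40)),
      smoking = smoking_status[i], stringsAsFactors = FALSE)
  }

  demographics <- data.frame(
    patient_id = patient_id,
    birth_date = mci_date - round(age_mci * 365.25),
    sex = sex, race_ethnicity = race, stringsAsFactors = FALSE)
  ground_truth <- data.frame(
    patient_id = patient_id,
    subtype = subtype,
    first_mci_date = mci_date,
    first_ad_date = ad_date,
    death_date = as.Date(ifelse(censored, NA, death_date),
                         origin = "1970-01-01"),
    censored = censored,
    last_followup_date = end_date,
    age_at_first_mci = round(age_mci, 1),
    stringsAsFactors = FALSE)

  new_ehr_cohort(
    demographics = demographics,
    diagnoses = do.call(rbind, dx_rows),
    drugs = do.call(rbind, rx_rows),
    vitals = do.call(rbind, vt_rows),
    ground_truth = ground_truth,
    config = config)
}

#' Summarize the planted ground truth of a synthetic cohort
#'
#' Per-subtype empirical means/sds computed from the true state-change dates
#' (never from the emitted codes): MCI-to-AD sojourn, post-AD survival among
#' observed deaths, and the censoring fraction. A standard deviation over
#' fewer than two patients is reported as NA.
#'
#' @param cohort a synthetic `ehr_cohort` (must carry `ground_truth`)
#' @return data frame with one row per subtype
#' @export
ground_truth_summary <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  gt <- cohort$ground_truth
  if (is.null(gt)) stop("cohort has no ground truth (not synthetic?)",
                        call. = FALSE)
  soj <- as.numeric(gt$first_ad_date - gt$first_mci_date)
  surv <- as.numeric(gt$death_date - gt$first_ad_date)
  sd_or_na <- function(x) if (sum(!is.na(x)) >= 2L) stats::sd(x, na.rm = TRUE)
    else NA_real_
  out <- lapply(sort(unique(gt$subtype)), function(z) {
    idx <- gt$subtype == z
    data.frame(
      subtype = z,
      n = sum(idx),
      mci_to_ad_mean = mean(soj[idx], na.rm = TRUE),
      mci_to_ad_sd = sd_or_na(soj[idx]),
      survival_mean = if (any(idx & !gt$censored))
        mean(surv[idx], na.rm = TRUE) else NA_real_,
      survival_sd = sd_or_na(surv[idx]),
      censored_fraction = mean(gt$censored[idx]))
  })
  do.call(rbind, out)
}
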