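# Clinical characterization of fitted subphenotypes: Kaplan-Meier curves
# with right-censoring, log-rank comparisons, transition-time statistics and
# prevalence contrasts between clusters.

#' Kaplan-Meier estimator with Greenwood confidence intervals
#'
#' Product-limit survival estimate with 95% confidence intervals computed by
#' the Greenwood formula on the log(-log) scale (the `survival` package's
#' "log-log" type). With no censoring the curve equals the empirical
#' survival function. If every subject is censored the curve is constant at
#' 1 and flagged.
#'
#' @param time follow-up durations in days (>= 0)
#' @param event 1 = event observed, 0 = right-censored
#' @param conf_level confidence level
#' @return object of class `km_fit`: step-function table (`time`, `n_risk`,
#'   `n_event`, `survival`, `lower`, `upper`), `all_censored` flag, and the
#'   underlying `survfit`
#' @export
km_estimator <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(time >= 0), all(event %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, survival = sf$surv,
                    lower = sf$lower, upper = sf$upper)
  structure(list(table = tab, all_censored = sum(event) == 0L,
                 n = length(time), survfit = sf),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n=%d, %d event times%s\n", x$n,
              sum(x$table$n_event > 0),
              if (x$all_censored) " (all censored; curve degenerate at 1)"
              else ""))
  invisible(x)
}

#' Survival at given times from a KM fit
#' @param km a `km_fit`
#' @param times evaluation times
#' @return survival probabilities (right-continuous step function)
#' @export
km_survival_at <- function(km, times) {
  st <- c(0, km$table$time)
  sv <- c(1, km$table$survival)
  idx <- findInterval(times, st)
  sv[idx]
}

#' Kaplan-Meier curves per cluster, as a tidy table
#' @param time,event as in [km_estimator()]
#' @param group cluster labels
#' @return data frame (cluster, time, survival, lower, upper, n_risk)
#' @export
km_by_group <- function(time, event, group) {
  out <- lapply(sort(unique(group)), function(g) {
    km <- km_estimator(time[group == g], event[group == g])
    cbind(cluster = g, km$table)
  })
  do.call(rbind, out)
}

#' K-sample log-rank test
#'
#' Compares survival across groups with the log-rank chi-square statistic on
#' K - 1 degrees of freedom. Undefined (flagged, not zero) when no events
#' occurred.
#'
#' @param time,event as in [km_estimator()]
#' @param group group labels (>= 2 distinct)
#' @return list(statistic, df, p_value, n_events)
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(unique(group)) >= 2L)
  if (sum(event) == 0L) {
    return(list(statistic = NA_real_, df = length(unique(group)) - 1L,
                p_value = NA_real_, n_events = 0L,
                note = "no events: log-rank undefined"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(unique(group)) - 1L
  list(statistic = sd_$chisq, df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       n_events = sum(event))
}

#' Per-cluster transition-time statistics
#'
#' Mean and sd of the MCI-to-AD sojourn and of the first-record-to-AD time,
#' per cluster. Non-converters (no AD date) are excluded from the means and
#' counted separately; a singleton cluster reports its mean with sd NA.
#'
#' @param assignments named cluster labels (names = patient ids)
#' @param timelines data frame with columns patient_id, first_record_date,
#'   first_mci_date, first_ad_date (e.g. from [state_timelines()] or a
#'   synthetic cohort's ground truth)
#' @return data frame with one row per cluster
#' @export
transition_stats <- function(assignments, timelines) {
  ids <- names(assignments)
  stopifnot(!is.null(ids), all(ids %in% timelines$patient_id))
  tl <- timelines[match(ids, timelines$patient_id), , drop = FALSE]
  mci_ad <- as.numeric(tl$first_ad_date - tl$first_mci_date)
  first_col <- if ("first_record_date" %in% names(tl)) "first_record_date"
               else NULL
  rec_ad <- if (!is.null(first_col))
    as.numeric(tl$first_ad_date - tl[[first_col]]) else rep(NA_real_,
                                                            nrow(tl))
  sd_or_na <- function(x) if (sum(!is.na(x)) >= 2L)
    stats::sd(x, na.rm = TRUE) else NA_real_
  out <- lapply(sort(unique(assignments)), function(k) {
    idx <- assignments == k
    data.frame(cluster = k, n = sum(idx),
               n_nonconverters = sum(idx & is.na(tl$first_ad_date)),
               mci_to_ad_mean = mean(mci_ad[idx], na.rm = TRUE),
               mci_to_ad_sd = sd_or_na(mci_ad[idx]),
               record_to_ad_mean = mean(rec_ad[idx], na.rm = TRUE),
               record_to_ad_sd = sd_or_na(rec_ad[idx]))
  })
  do.call(rbind, out)
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-5, 1e-4, 1e-3, 1e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Prevalence contrasts between subphenotypes
#'
#' For patient-level binary feature indicators ("ever present in the
#' record"), computes the per-cluster prevalence matrix, per-feature 2x2
#' chi-square tests between every pair of clusters (switching to Fisher's
#' exact test when an expected cell count drops below 5, noted per cell),
#' significance tiers (* p<0.01, ** p<0.001, *** p<0.0001, **** p<0.00001),
#' and pairwise Pearson correlations between the cluster prevalence
#' profiles. No multiple-testing correction is applied; tiers are reported
#' raw.
#'
#' @param assignments named cluster labels (names = patient ids)
#' @param features binary matrix, patients x features (rownames = patient
#'   ids)
#' @return list with `prevalence` (clusters x features), `tests` (long data
#'   frame: feature, cluster_a, cluster_b, p_value, tier, method) and
#'   `profile_correlation` (clusters x clusters)
#' @export
prevalence_tests <- function(assignments, features) {
  features <- as.matrix(features)
  ids <- names(assignments)
  stopifnot(!is.null(ids), !is.null(rownames(features)),
            all(ids %in% rownames(features)))
  features <- features[ids, , drop = FALSE]
  ks <- sort(unique(assignments))
  prev <- t(vapply(ks, function(k) {
    colMeans(features[assignments == k, , drop = FALSE])
  }, numeric(ncol(features))))
  rownames(prev) <- ks

  pairs <- utils::combn(ks, 2L, simplify = FALSE)
  tests <- lapply(colnames(features), function(f) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- features[assignments == pr[1], f]
      b <- features[assignments == pr[2], f]
      tab <- rbind(c(sum(a), length(a) - sum(a)),
                   c(sum(b), length(b) - sum(b)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        method <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        method <- "chisq"
      }
      data.frame(feature = f, cluster_a = pr[1], cluster_b = pr[2],
                 p_value = p, tier = as.character(significance_tier(p)),
                 method = method, stringsAsFactors = FALSE)
    }))
  })
  corr <- stats::cor(t(prev))
  list(prevalence = prev, tests = do.call(rbind, tests),
       profile_correlation = corr)
}

#' Ever-present binary feature indicators per patient
#'
#' Collapses window-level feature bits to the patient level by OR over all
#' windows (code blocks only; demographic bits are taken from the last
#' window).
#'
#' @param features an `encounter_features`
#' @return binary matrix, patients x features
#' @export
patient_feature_indicators <- function(features) {
  stopifnot(inherits(features, "encounter_features"))
  pid <- features$windows$patient_id
  agg <- rowsum(features$X, pid)
  out <- (agg > 0) * 1L
  rownames(out) <- rownames(agg)
  out
}
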