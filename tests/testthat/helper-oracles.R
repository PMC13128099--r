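# Independent oracles and small fixture builders used across the suite.

# Exhaustive DTW: recursively enumerate every admissible warping path
# (boundary, monotone, steps (1,0)/(0,1)/(1,1)) and take the minimum
# cumulative Euclidean cost. Exponential; only for tiny sequences.
dtw_bruteforce <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1L)
  n <- nrow(a); m <- nrow(b)
  d <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    if (i == n && j == m) return(0)
    best <- Inf
    if (i < n) best <- min(best, d(i + 1, j) + rec(i + 1, j))
    if (j < m) best <- min(best, d(i, j + 1) + rec(i, j + 1))
    if (i < n && j < m) best <- min(best, d(i + 1, j + 1) + rec(i + 1, j + 1))
    best
  }
  d(1, 1) + rec(1, 1)
}

# Brute-force assignment: all permutations (for checking the Hungarian
# solver on small matrices).
assignment_bruteforce <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) { best_cost <- cst; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# Straight-line Davies-Bouldin reimplementation over arbitrary dist calls.
dbi_bruteforce <- function(seqs, centroids, assignments) {
  K <- length(centroids)
  sig <- sapply(seq_len(K), function(k) {
    m <- seqs[assignments == k]
    mean(sapply(m, function(s) dtw_distance(s, centroids[[k]])))
  })
  mean(sapply(seq_len(K), function(i) {
    max(sapply(setdiff(seq_len(K), i), function(j) {
      (sig[i] + sig[j]) / dtw_distance(centroids[[i]], centroids[[j]])
    }))
  }))
}

# Random chronology-respecting directed graph shaped like a DPG (node order
# equals date order, so src < dst guarantees the invariants).
random_digraph <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  dates <- as.Date("2015-01-01") +
    sort(sample.int(1500L, n, replace = TRUE))
  nodes <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      window_index = 1L, window_start = dates,
                      node_id = seq_len(n), stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
  e <- pairs[keep, , drop = FALSE]
  edges <- data.frame(src = e[, 1L], dst = e[, 2L],
                      elapsed_days = as.integer(dates[e[, 2L]] -
                                                  dates[e[, 1L]]),
                      type = "similarity", origin = e[, 1L])
  structure(list(nodes = nodes, edges = edges, X = NULL, k = n - 1L),
            class = "progression_graph")
}

# Small synthetic cohort cached per test session (generation is seeded, so
# regenerating is deterministic; caching just saves time).
local_cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n_patients, seed, separation = 1) {
  key <- paste(n_patients, seed, separation, sep = "_")
  if (is.null(local_cohort_cache[[key]])) {
    local_cohort_cache[[key]] <- generate_cohort(generator_config(
      n_patients = n_patients, seed = seed, separation = separation))
  }
  local_cohort_cache[[key]]
}

# Tiny hand-built cohort for boundary tests: one patient, explicit events.
manual_cohort <- function(diagnoses, drugs = NULL, vitals = NULL,
                          demographics = NULL) {
  empty_events <- data.frame(patient_id = character(0),
                             date = as.Date(character(0)),
                             code = character(0), code_system = character(0),
                             stringsAsFactors = FALSE)
  empty_vitals <- data.frame(patient_id = character(0),
                             date = as.Date(character(0)), bmi = numeric(0),
                             systolic = numeric(0), diastolic = numeric(0),
                             smoking = character(0), stringsAsFactors = FALSE)
  ids <- unique(c(diagnoses$patient_id, drugs$patient_id,
                  vitals$patient_id, demographics$patient_id))
  demo <- demographics %||% data.frame(
    patient_id = ids, birth_date = as.Date("1940-01-01"), sex = "F",
    race_ethnicity = "NH White", stringsAsFactors = FALSE)
  progphen:::new_ehr_cohort(demographics = demo, diagnoses = diagnoses,
                            drugs = drugs %||% empty_events,
                            vitals = vitals %||% empty_vitals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
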