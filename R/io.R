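# Reading/writing the tabular EHR dialect and code-mapping tables.
#
# The on-disk dialect is four RFC-4180 CSV tables with ISO-8601 dates:
#   demographics.csv  patient_id, birth_date, sex, race_ethnicity
#   diagnoses.csv     patient_id, date, code, code_system
#   drugs.csv         patient_id, date, code, code_system
#   vitals.csv        patient_id, date, bmi, systolic, diastolic, smoking
# Dates are day-resolution; elapsed time downstream is integer days.

COHORT_TABLES <- list(
  demographics = c("patient_id", "birth_date", "sex", "race_ethnicity"),
  diagnoses    = c("patient_id", "date", "code", "code_system"),
  drugs        = c("patient_id", "date", "code", "code_system"),
  vitals       = c("patient_id", "date", "bmi", "systolic", "diastolic",
                   "smoking")
)

parse_date_column <- function(x, file, column) {
  parsed <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(parsed))
  if (length(bad) > 0L) {
    stop(sprintf("%s: unparseable date in column '%s' at row %d (value '%s')",
                 file, column, bad[1], x[bad[1]]), call. = FALSE)
  }
  parsed
}

read_table_checked <- function(path, name) {
  if (!file.exists(path)) stop(sprintf("missing cohort table: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- COHORT_TABLES[[name]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column '%s'", path, missing[1]),
         call. = FALSE)
  }
  df
}

#' Read an EHR cohort from its four CSV tables
#'
#' Reads `demographics.csv`, `diagnoses.csv`, `drugs.csv` and `vitals.csv`
#' from `dir` (or explicit `paths`), validates headers and dates, and returns
#' the cohort in canonical in-memory form: long event tables sorted by
#' (patient, date), with duplicate (patient, date, code) rows collapsed so the
#' per-day code sets are true sets. Reading is order-insensitive: permuting
#' input rows yields an identical cohort.
#'
#' @param dir directory containing the four tables
#' @param paths optional named list/vector overriding individual table paths
#'   (names among demographics, diagnoses, drugs, vitals)
#' @return an object of class `ehr_cohort` with elements `demographics`,
#'   `diagnoses`, `drugs`, `vitals` (data frames) and `ground_truth` (NULL;
#'   populated for synthetic cohorts)
#' @seealso [write_cohort()], [encounter_records()]
#' @export
read_cohort <- function(dir = NULL, paths = NULL) {
  resolve <- function(name) {
    if (!is.null(paths) && !is.null(paths[[name]])) return(paths[[name]])
    file.path(dir, paste0(name, ".csv"))
  }
  demo <- read_table_checked(resolve("demographics"), "demographics")
  demo$birth_date <- parse_date_column(demo$birth_date,
                                       resolve("demographics"), "birth_date")
  dx <- read_table_checked(resolve("diagnoses"), "diagnoses")
  dx$date <- parse_date_column(dx$date, resolve("diagnoses"), "date")
  rx <- read_table_checked(resolve("drugs"), "drugs")
  rx$date <- parse_date_column(rx$date, resolve("drugs"), "date")
  vt <- read_table_checked(resolve("vitals"), "vitals")
  vt$date <- parse_date_column(vt$date, resolve("vitals"), "date")
  for (col in c("bmi", "systolic", "diastolic")) {
    vt[[col]] <- suppressWarnings(as.numeric(vt[[col]]))
  }
  if (any(!is.na(vt$bmi) & vt$bmi <= 0)) {
    stop(sprintf("%s: non-positive bmi at row %d", resolve("vitals"),
                 which(!is.na(vt$bmi) & vt$bmi <= 0)[1]), call. = FALSE)
  }
  gt_path <- if (!is.null(dir)) file.path(dir, "ground_truth.csv") else NULL
  gt <- NULL
  if (!is.null(gt_path) && file.exists(gt_path)) {
    gt <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
    for (col in intersect(c("first_mci_date", "first_ad_date", "death_date",
                            "last_followup_date"), names(gt))) {
      gt[[col]] <- as.Date(gt[[col]])
    }
  }
  new_ehr_cohort(demographics = demo, diagnoses = dx, drugs = rx, vitals = vt,
                 ground_truth = gt)
}

new_ehr_cohort <- function(demographics, diagnoses, drugs, vitals,
                           ground_truth = NULL, config = NULL) {
  canon_events <- function(df) {
    df <- df[!duplicated(df[c("patient_id", "date", "code")]), , drop = FALSE]
    df <- df[order(df$patient_id, df$date, df$code), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  diagnoses <- canon_events(diagnoses)
  drugs <- canon_events(drugs)
  vitals <- vitals[order(vitals$patient_id, vitals$date), , drop = FALSE]
  vitals <- vitals[!duplicated(vitals[c("patient_id", "date")]), , drop = FALSE]
  rownames(vitals) <- NULL
  demographics <- demographics[order(demographics$patient_id), , drop = FALSE]
  rownames(demographics) <- NULL
  structure(list(demographics = demographics, diagnoses = diagnoses,
                 drugs = drugs, vitals = vitals, ground_truth = ground_truth,
                 config = config),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients, %d diagnosis rows, %d drug rows, %d vital rows\n",
              nrow(x$demographics), nrow(x$diagnoses), nrow(x$drugs),
              nrow(x$vitals)))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  synthetic ground truth present (%d subtypes)\n",
                length(unique(x$ground_truth$subtype))))
  }
  invisible(x)
}

#' Write an EHR cohort to CSV tables
#'
#' Inverse of [read_cohort()]; a write/read round trip is the identity on the
#' record set. Synthetic cohorts additionally emit `ground_truth.csv`.
#'
#' @param cohort an `ehr_cohort`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(COHORT_TABLES)) {
    utils::write.csv(cohort[[name]], file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(cohort$ground_truth)) {
    utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Per-patient encounter streams
#'
#' Collapses the long event tables into one record per (patient, date):
#' the day's diagnosis-code set, drug-code set, vitals (if measured that day)
#' and demographics. Records are sorted ascending by date; duplicate rows for
#' the same day are merged by set union, so two rows with codes {A} and {B}
#' become one record with {A, B}.
#'
#' @param cohort an `ehr_cohort`
#' @param patient_ids optional subset of patients
#' @return named list (by patient id) of data frames with list-columns
#'   `diagnosis_codes` and `drug_codes`
#' @export
encounter_records <- function(cohort, patient_ids = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  ids <- patient_ids %||% cohort$demographics$patient_id
  dx_split <- split(cohort$diagnoses, cohort$diagnoses$patient_id)
  rx_split <- split(cohort$drugs, cohort$drugs$patient_id)
  vt_split <- split(cohort$vitals, cohort$vitals$patient_id)
  out <- lapply(ids, function(pid) {
    dx <- dx_split[[pid]]
    rx <- rx_split[[pid]]
    vt <- vt_split[[pid]]
    dates <- sort(unique(c(dx$date, rx$date, vt$date)))
    if (length(dates) == 0L) {
      return(data.frame(date = as.Date(character(0))))
    }
    rec <- data.frame(date = dates)
    rec$diagnosis_codes <- I(lapply(dates, function(d) {
      sort(unique(dx$code[dx$date == d]))
    }))
    rec$drug_codes <- I(lapply(dates, function(d) {
      sort(unique(rx$code[rx$date == d]))
    }))
    idx <- match(dates, vt$date)
    rec$bmi <- vt$bmi[idx]
    rec$systolic <- vt$systolic[idx]
    rec$diastolic <- vt$diastolic[idx]
    rec$smoking <- vt$smoking[idx]
    rec
  })
  names(out) <- ids
  out
}

# ---- code maps ---------------------------------------------------------

#' Load a two-column code-mapping table
#'
#' Reads a CSV with columns `source_code,target` mapping raw EHR codes to an
#' aggregation target (Phecode for diagnoses, ATC level 3 for drugs). The
#' mapping must be many-to-one: a source code listed twice with conflicting
#' targets is an error. When `target_format = "atc3"` every target must be a
#' third-level ATC class (letter, two digits, letter, e.g. "N06D"); deeper or
#' shallower ATC levels are rejected.
#'
#' @param path CSV path
#' @param target_format one of "none", "atc3"
#' @return a `code_map` object
#' @export
load_code_map <- function(path, target_format = c("none", "atc3")) {
  target_format <- match.arg(target_format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("source_code", "target") %in% names(df))) {
    stop(sprintf("%s: code map needs columns source_code,target", path),
         call. = FALSE)
  }
  df <- unique(df[c("source_code", "target")])
  dup <- df$source_code[duplicated(df$source_code)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: source code '%s' mapped to conflicting targets",
                 path, dup[1]), call. = FALSE)
  }
  if (target_format == "atc3" &&
      !all(grepl("^[A-Z][0-9]{2}[A-Z]$", df$target))) {
    bad <- df$target[!grepl("^[A-Z][0-9]{2}[A-Z]$", df$target)][1]
    stop(sprintf("%s: target '%s' is not a third-level ATC class", path, bad),
         call. = FALSE)
  }
  mapping <- df$target
  names(mapping) <- df$source_code
  structure(list(mapping = mapping, path = path,
                 target_format = target_format),
            class = "code_map")
}

#' @export
print.code_map <- function(x, ...) {
  cat(sprintf("<code_map> %d source codes -> %d targets\n",
              length(x$mapping), length(unique(x$mapping))))
  invisible(x)
}

#' Apply a code map, routing unmapped codes to a catch-all bucket
#'
#' Unmapped codes are never dropped: they map to the single category
#' `"unmapped"` so the downstream feature dimension is stable, and are counted
#' in the coverage report.
#'
#' @param codes character vector of source codes
#' @param map a `code_map`
#' @return character vector of targets, same length as `codes`
#' @export
apply_code_map <- function(codes, map) {
  stopifnot(inherits(map, "code_map"))
  out <- unname(map$mapping[codes])
  out[is.na(out)] <- "unmapped"
  out
}

#' Coverage of a code map over observed codes
#' @param map a `code_map`
#' @param codes observed source codes
#' @return list(fraction_mapped, n_unmapped, unmapped_codes)
#' @export
map_coverage <- function(map, codes) {
  mapped <- codes %in% names(map$mapping)
  list(fraction_mapped = if (length(codes)) mean(mapped) else NA_real_,
       n_unmapped = sum(!mapped),
       unmapped_codes = sort(unique(codes[!mapped])))
}

#' Packaged diagnosis and drug code maps
#'
#' Small packaged subsets of the ICD-to-Phecode and drug-to-ATC-3 crosswalks,
#' sufficient for the bundled synthetic vocabulary. Real deployments should
#' supply full crosswalks via [load_code_map()].
#'
#' @return list(diagnosis = code_map, drug = code_map)
#' @export
default_code_maps <- function() {
  list(
    diagnosis = load_code_map(system.file("extdata",
                                          "icd_phecode_subset.csv",
                                          package = "progphen")),
    drug = load_code_map(system.file("extdata", "drug_atc_subset.csv",
                                     package = "progphen"),
                         target_format = "atc3")
  )
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys are [generator_config()] arguments
#' @return a `generator_config`
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(generator_config, vals)
}
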