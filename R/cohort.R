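#' Clinical item vocabularies
#'
#' Closed code lists for the three set-valued clinical fields of a syncope
#' cohort: electrocardiographic abnormalities, precipitating/predisposing
#' factors of the syncopal episode, and prodromal symptoms. Unknown codes are
#' rejected at parse time.
#'
#' @return A character vector of valid codes.
#' @examples
#' ecg_finding_codes()
#' @export
ecg_finding_codes <- function() {
  c("bradycardia_lt_40", "st_change_gt_1mm", "qt_prolongation_440ms",
    "ventricular_tachycardia", "av_block_2_or_3", "sick_sinus",
    "ventricular_or_rapid_svt", "sinus_pause", "pacemaker_malfunction")
}

#' @rdname ecg_finding_codes
#' @export
precipitating_factor_codes <- function() {
  c("warm_place", "crowded_place", "prolonged_standing", "overtiring",
    "postprandial", "neck_turning", "syncope_sitting", "syncope_supine",
    "syncope_upright", "syncope_during_effort", "syncope_after_effort")
}

#' @rdname ecg_finding_codes
#' @export
prodrome_codes <- function() {
  c("blurred_vision", "lightheadedness", "diaphoresis", "palpitations",
    "nausea", "vomiting", "abdominal_discomfort", "weakness", "feeling_cold",
    "feeling_warm", "tremors", "yawn", "pallor", "redness", "cyanosis")
}

# Canonical column order of the cohort file; also the in-memory layout.
cohort_columns <- function() {
  c("patient_id", "age", "ecg_findings", "cardiopathy",
    "palpitations_or_dyspnea", "syncope_during_effort", "syncope_supine",
    "precipitating_factors", "prodromes", "autonomic_prodromes",
    "neurovegetative_recovery_signs", "diagnosis")
}

cohort_bool_columns <- function() {
  c("cardiopathy", "palpitations_or_dyspnea", "syncope_during_effort",
    "syncope_supine", "autonomic_prodromes", "neurovegetative_recovery_signs")
}

# Split a semicolon-joined set cell into a code vector ("" -> empty set).
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_codes <- function(codes) paste(codes, collapse = ";")

parse_bool <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes")] <- TRUE
  out[v %in% c("0", "false", "f", "no")] <- FALSE
  out
}

#' Assemble a syncope cohort from per-patient fields
#'
#' Builds and validates the canonical cohort `data.frame`: one row per
#' patient, set-valued fields stored as semicolon-joined code strings,
#' logical indicator fields, and an adjudicated `diagnosis` of
#' `"cardiac"`, `"noncardiac"` or `"unknown"`.
#'
#' When the standalone effort/supine indicators are `NA` they are
#' synchronised from the precipitating-factor set (codes
#' `syncope_during_effort`, `syncope_supine`); when both representations are
#' populated the standalone indicators are authoritative for scoring.
#'
#' @param patient_id Character vector of opaque identifiers.
#' @param age Integer ages in years (>= 0).
#' @param ecg_findings,precipitating_factors,prodromes Either character
#'   vectors of semicolon-joined codes or lists of code vectors. See
#'   [ecg_finding_codes()] for the valid vocabularies.
#' @param cardiopathy,palpitations_or_dyspnea,syncope_during_effort,syncope_supine,autonomic_prodromes,neurovegetative_recovery_signs
#'   Logical indicators.
#' @param diagnosis `"cardiac"`, `"noncardiac"` or `"unknown"`
#'   (case-insensitive).
#' @return A validated `egsys_cohort` data frame.
#' @seealso [read_cohort()], [validate_cohort()]
#' @export
new_cohort <- function(patient_id, age, ecg_findings = "", cardiopathy = FALSE,
                       palpitations_or_dyspnea = FALSE,
                       syncope_during_effort = NA, syncope_supine = NA,
                       precipitating_factors = "", prodromes = "",
                       autonomic_prodromes = FALSE,
                       neurovegetative_recovery_signs = FALSE,
                       diagnosis = "unknown") {
  as_cell <- function(x) {
    if (is.list(x)) vapply(x, join_codes, character(1)) else as.character(x)
  }
  df <- data.frame(
    patient_id = as.character(patient_id),
    age = as.integer(age),
    ecg_findings = as_cell(ecg_findings),
    cardiopathy = as.logical(cardiopathy),
    palpitations_or_dyspnea = as.logical(palpitations_or_dyspnea),
    syncope_during_effort = as.logical(syncope_during_effort),
    syncope_supine = as.logical(syncope_supine),
    precipitating_factors = as_cell(precipitating_factors),
    prodromes = as_cell(prodromes),
    autonomic_prodromes = as.logical(autonomic_prodromes),
    neurovegetative_recovery_signs = as.logical(neurovegetative_recovery_signs),
    diagnosis = tolower(as.character(diagnosis)),
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
}

#' Validate a cohort data frame
#'
#' Checks the schema, the closed code vocabularies, and the structural
#' invariants: autonomic prodromes require a non-empty prodrome set, ages are
#' non-negative, and `diagnosis` is one of cardiac/noncardiac/unknown.
#' `NA` effort/supine indicators are filled in from the
#' precipitating-factor set. Errors name the offending column and row.
#'
#' @param cohort A data frame with the columns of `cohort_columns()`.
#' @return The normalised cohort, classed `egsys_cohort`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- as.data.frame(cohort)[cohort_columns()]

  cohort$patient_id <- as.character(cohort$patient_id)
  cohort$age <- as.integer(cohort$age)
  if (anyNA(cohort$age) || any(cohort$age < 0)) {
    bad <- which(is.na(cohort$age) | cohort$age < 0)
    stop("invalid age at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  na_ok <- c("syncope_during_effort", "syncope_supine")
  for (col in cohort_bool_columns()) {
    v <- cohort[[col]]
    if (!is.logical(v)) {
      blank <- is.na(v) | !nzchar(trimws(as.character(v)))
      parsed <- parse_bool(v)
      bad <- which(is.na(parsed) & !blank)
      if (length(bad)) {
        stop("unparseable boolean in column '", col, "' at row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      v <- parsed
    }
    if (!(col %in% na_ok) && anyNA(v)) {
      stop("missing boolean in column '", col, "' at row(s): ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    cohort[[col]] <- v
  }

  check_codes <- function(col, valid) {
    cells <- as.character(cohort[[col]])
    cells[is.na(cells)] <- ""
    parts <- strsplit(cells, ";", fixed = TRUE)
    flat <- unlist(parts, use.names = FALSE)
    if (length(flat) && !all(flat %in% valid)) {
      row_of <- rep(seq_along(parts), lengths(parts))
      bad <- !flat %in% valid
      i <- row_of[bad][1]
      stop("unknown ", col, " code(s) at row ", i, ": ",
           paste(unique(flat[bad][row_of[bad] == i]), collapse = ", "),
           call. = FALSE)
    }
    # normalise: dedupe, vocabulary order
    vapply(parts, function(codes) join_codes(valid[valid %in% codes]),
           character(1), USE.NAMES = FALSE)
  }
  cohort$ecg_findings <- check_codes("ecg_findings", ecg_finding_codes())
  cohort$precipitating_factors <-
    check_codes("precipitating_factors", precipitating_factor_codes())
  cohort$prodromes <- check_codes("prodromes", prodrome_codes())

  # standalone effort/supine indicators: authoritative when present,
  # synchronised from the factor set when NA; cells are normalised so a
  # fixed-string match cannot hit a substring of another code
  has_factor <- function(code) {
    grepl(code, cohort$precipitating_factors, fixed = TRUE)
  }
  fill <- is.na(cohort$syncope_during_effort)
  cohort$syncope_during_effort[fill] <- has_factor("syncope_during_effort")[fill]
  fill <- is.na(cohort$syncope_supine)
  cohort$syncope_supine[fill] <- has_factor("syncope_supine")[fill]

  no_prodrome <- !nzchar(cohort$prodromes)
  bad <- which(no_prodrome & cohort$autonomic_prodromes)
  if (length(bad)) {
    stop("autonomic_prodromes is true but the prodrome set is empty at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  cohort$diagnosis <- tolower(trimws(as.character(cohort$diagnosis)))
  bad <- which(!cohort$diagnosis %in% c("cardiac", "noncardiac", "unknown"))
  if (length(bad)) {
    stop("diagnosis must be cardiac/noncardiac/unknown; invalid at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  rownames(cohort) <- NULL
  class(cohort) <- c("egsys_cohort", "data.frame")
  cohort
}

#' Read a syncope cohort from a CSV file
#'
#' The file dialect is UTF-8 comma-separated with a required header,
#' booleans as 0/1 (true/false also accepted), and set-valued cells as
#' semicolon-joined codes. Malformed codes and booleans are reported with
#' their row numbers; a missing column is a schema error naming the column.
#'
#' @param path Path to the cohort CSV.
#' @return A validated `egsys_cohort` data frame.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw)) {
    for (col in cohort_bool_columns()) {
      v <- trimws(raw[[col]])
      parsed <- parse_bool(v)
      blank <- !nzchar(v) | is.na(v)
      if (col %in% c("syncope_during_effort", "syncope_supine")) {
        bad <- which(is.na(parsed) & !blank)
      } else {
        bad <- which(is.na(parsed))
      }
      if (length(bad)) {
        stop("unparseable boolean in column '", col, "' at row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      raw[[col]] <- parsed
    }
  } else {
    for (col in cohort_bool_columns()) raw[[col]] <- logical(0)
  }
  validate_cohort(raw)
}

#' Write a syncope cohort to a CSV file
#'
#' Serialisation is deterministic: canonical column order, booleans as 0/1,
#' set cells as semicolon-joined codes in vocabulary order. Reading a file
#' and writing it again is byte-idempotent after the first normalisation
#' pass.
#'
#' @param cohort A validated cohort (see [validate_cohort()]).
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- as.data.frame(cohort)
  for (col in cohort_bool_columns()) out[[col]] <- as.integer(out[[col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' ECG abnormality indicator
#'
#' A patient's ECG is abnormal if one or more findings from the closed list
#' (bradycardia below 40/min, ST changes over 1 mm, QT prolongation,
#' ventricular tachycardia, second/third-degree AV block, sick sinus,
#' ventricular or rapid supraventricular arrhythmia, sinus pause, pacemaker
#' malfunction) is present.
#'
#' @param cohort A validated cohort.
#' @return Logical vector, one element per patient.
#' @export
ecg_abnormal <- function(cohort) {
  nzchar(as.character(cohort$ecg_findings))
}

#' @export
print.egsys_cohort <- function(x, ...) {
  dx <- table(factor(x$diagnosis, c("cardiac", "noncardiac", "unknown")))
  cat("EGSYS cohort: ", nrow(x), " patients (",
      dx[["cardiac"]], " cardiac, ", dx[["noncardiac"]], " noncardiac, ",
      dx[["unknown"]], " unknown origin)\n", sep = "")
  NextMethod()
}
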