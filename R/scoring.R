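#' EGSYS item weights and cut-off
#'
#' The two fixed additive weight tables of the rule and the decision
#' threshold. EGSYS-U (univariate-derived weights) scores ten items and
#' spans \[-6, 11\]; EGSYS-M (multivariate-derived weights) scores six items
#' and spans \[-2, 12\]. A total score of at least `cutoff` (3) flags the
#' patient as at risk of a cardiac cause.
#'
#' The two "absence" items of EGSYS-U (`no_precipitating`, `no_prodromes`)
#' contribute +1 when the corresponding presence indicator is false.
#'
#' @return A list with integer vectors `univariate` and `multivariate`
#'   (named by item) and the integer `cutoff`.
#' @export
egsys_weights <- function() {
  list(
    univariate = c(
      abnormal_ecg_or_cardiopathy = 3L,
      palpitations_or_dyspnea = 3L,
      supine_or_effort = 2L,
      age_gt_64 = 1L,
      no_precipitating = 1L,
      no_prodromes = 1L,
      blurred_vision = -1L,
      neurovegetative_recovery = -1L,
      precipitating_present = -2L,
      autonomic_prodromes = -2L
    ),
    multivariate = c(
      abnormal_ecg_or_cardiopathy = 3L,
      palpitations_or_dyspnea = 4L,
      effort = 3L,
      supine = 2L,
      autonomic_prodromes = -1L,
      precipitating_present = -1L
    ),
    cutoff = 3L
  )
}

#' Derive the boolean EGSYS items from patient records
#'
#' Maps raw clinical fields to the indicator set both score variants are
#' built from: combined abnormal-ECG-or-cardiopathy item, palpitations or
#' dyspnea preceding the faint, effort and supine syncope (and their union,
#' the combined univariate item), age strictly over 64 years, presence of
#' any precipitating/predisposing factor, presence of any prodrome, blurred
#' vision among the prodromes, autonomic (vasovagal-type) prodromes, and
#' neurovegetative signs during recovery.
#'
#' @param cohort A validated cohort (see [validate_cohort()]).
#' @return A data frame of logical item columns, one row per patient,
#'   classed `egsys_items`.
#' @export
derive_items <- function(cohort) {
  if (!inherits(cohort, "egsys_cohort")) cohort <- validate_cohort(cohort)
  blurred <- grepl("blurred_vision", cohort$prodromes, fixed = TRUE)
  items <- data.frame(
    abnormal_ecg_or_cardiopathy = ecg_abnormal(cohort) | cohort$cardiopathy,
    palpitations_or_dyspnea = cohort$palpitations_or_dyspnea,
    effort = cohort$syncope_during_effort,
    supine = cohort$syncope_supine,
    supine_or_effort = cohort$syncope_during_effort | cohort$syncope_supine,
    age_gt_64 = cohort$age > 64L,
    precipitating_present = nzchar(cohort$precipitating_factors),
    any_prodrome = nzchar(cohort$prodromes),
    blurred_vision = blurred,
    autonomic_prodromes = cohort$autonomic_prodromes,
    neurovegetative_recovery = cohort$neurovegetative_recovery_signs
  )
  class(items) <- c("egsys_items", "data.frame")
  items
}

item_columns <- function() {
  c("abnormal_ecg_or_cardiopathy", "palpitations_or_dyspnea", "effort",
    "supine", "supine_or_effort", "age_gt_64", "precipitating_present",
    "any_prodrome", "blurred_vision", "autonomic_prodromes",
    "neurovegetative_recovery")
}

validate_items <- function(items) {
  missing_cols <- setdiff(item_columns(), names(items))
  if (length(missing_cols)) {
    stop("items are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in item_columns()) {
    if (!is.logical(items[[col]]) || anyNA(items[[col]])) {
      stop("item column '", col, "' must be logical without NA", call. = FALSE)
    }
  }
  if (any(items$supine_or_effort != (items$effort | items$supine))) {
    stop("supine_or_effort must equal effort | supine", call. = FALSE)
  }
  if (any((items$blurred_vision | items$autonomic_prodromes) &
            !items$any_prodrome)) {
    stop("blurred_vision/autonomic_prodromes require any_prodrome",
         call. = FALSE)
  }
  items
}

#' Compute the EGSYS scores
#'
#' `score_univariate()` and `score_multivariate()` sum the fixed item
#' weights over the true indicators (see [egsys_weights()]); the univariate
#' variant additionally awards +1 for the absence of precipitating factors
#' and +1 for the absence of prodromes. `classify()` applies the at-risk
#' threshold: a score of at least `cutoff` flags a probable cardiac cause.
#'
#' @param items An item data frame from [derive_items()] (or any data frame
#'   with the same logical columns).
#' @return Integer score vector; for `classify()`, a factor with levels
#'   `at_risk`, `low_risk`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 5, seed = 1))
#' items <- derive_items(cohort)
#' score_univariate(items)
#' classify(score_multivariate(items))
#' @export
score_univariate <- function(items) {
  items <- validate_items(items)
  w <- egsys_weights()$univariate
  as.integer(
    w[["abnormal_ecg_or_cardiopathy"]] * items$abnormal_ecg_or_cardiopathy +
      w[["palpitations_or_dyspnea"]] * items$palpitations_or_dyspnea +
      w[["supine_or_effort"]] * items$supine_or_effort +
      w[["age_gt_64"]] * items$age_gt_64 +
      w[["no_precipitating"]] * (!items$precipitating_present) +
      w[["no_prodromes"]] * (!items$any_prodrome) +
      w[["blurred_vision"]] * items$blurred_vision +
      w[["neurovegetative_recovery"]] * items$neurovegetative_recovery +
      w[["precipitating_present"]] * items$precipitating_present +
      w[["autonomic_prodromes"]] * items$autonomic_prodromes
  )
}

#' @rdname score_univariate
#' @export
score_multivariate <- function(items) {
  items <- validate_items(items)
  w <- egsys_weights()$multivariate
  as.integer(
    w[["abnormal_ecg_or_cardiopathy"]] * items$abnormal_ecg_or_cardiopathy +
      w[["palpitations_or_dyspnea"]] * items$palpitations_or_dyspnea +
      w[["effort"]] * items$effort +
      w[["supine"]] * items$supine +
      w[["autonomic_prodromes"]] * items$autonomic_prodromes +
      w[["precipitating_present"]] * items$precipitating_present
  )
}

#' @rdname score_univariate
#' @param score Integer score vector.
#' @param cutoff At-risk threshold (default 3; the boundary is inclusive).
#' @export
classify <- function(score, cutoff = egsys_weights()$cutoff) {
  factor(ifelse(score >= cutoff, "at_risk", "low_risk"),
         levels = c("at_risk", "low_risk"))
}

#' Score every patient in a cohort
#'
#' Appends per-patient columns `egsys_u`, `egsys_m`, `at_risk_u`,
#' `at_risk_m` to the cohort. Patients with unknown diagnosis are scored
#' like any other; they are only excluded later, from accuracy statistics.
#'
#' @inheritParams derive_items
#' @param cutoff At-risk threshold (default 3).
#' @return The cohort with four score/classification columns appended.
#' @export
score_cohort <- function(cohort, cutoff = egsys_weights()$cutoff) {
  if (!inherits(cohort, "egsys_cohort")) cohort <- validate_cohort(cohort)
  items <- derive_items(cohort)
  cohort$egsys_u <- score_univariate(items)
  cohort$egsys_m <- score_multivariate(items)
  cohort$at_risk_u <- as.integer(cohort$egsys_u >= cutoff)
  cohort$at_risk_m <- as.integer(cohort$egsys_m >= cutoff)
  cohort
}
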