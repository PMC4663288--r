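#' Synthetic cohort configuration
#'
#' Parameters of the two-class generative model behind [simulate_cohort()]:
#' cohort size, cardiac prevalence, and class-conditional probabilities for
#' each scored risk factor. Items are drawn independently given the
#' diagnosis class, with two structural couplings: effort and supine
#' syncope are mutually exclusive (one event has one position/activity),
#' and the prodrome state is a single categorical draw whose categories fix
#' the joint distribution of "no prodromes", blurred vision and autonomic
#' prodromes.
#'
#' The defaults reproduce the class-conditional frequencies of a 198-patient
#' emergency-department validation cohort with 115 cardiac and 83 noncardiac
#' cases (e.g. palpitations/dyspnea 51/115 vs 8/83; abnormal
#' ECG/cardiopathy 101/115 vs 32/83; age over 64 in 67/115 vs 20/83).
#'
#' @param n Cohort size (integer >= 1).
#' @param prevalence_cardiac Probability that a patient's adjudicated
#'   diagnosis is cardiac. Default 115/198.
#' @param p_cardiac,p_noncardiac Class-conditional parameter lists with
#'   Bernoulli probabilities `abnormal_ecg_or_cardiopathy`,
#'   `palpitations_or_dyspnea`, `effort`, `supine`, `age_gt_64`,
#'   `precipitating_present`, `neurovegetative_recovery`, and a
#'   `prodrome_pattern` probability vector over
#'   `none`, `blurred_only`, `autonomic_only`, `blurred_autonomic`, `other`
#'   summing to 1.
#' @param seed Integer seed making generation fully reproducible; `NULL`
#'   uses (and advances) the current RNG state.
#' @return A validated `egsys_cohort_config` object.
#' @export
cohort_config <- function(n = 198L,
                          prevalence_cardiac = 115 / 198,
                          p_cardiac = list(
                            abnormal_ecg_or_cardiopathy = 101 / 115,
                            palpitations_or_dyspnea = 51 / 115,
                            effort = 29 / 115,
                            supine = 7 / 115,
                            age_gt_64 = 67 / 115,
                            precipitating_present = 41 / 115,
                            neurovegetative_recovery = 31 / 115,
                            prodrome_pattern = c(none = 37, blurred_only = 11,
                                                 autonomic_only = 18,
                                                 blurred_autonomic = 0,
                                                 other = 49) / 115
                          ),
                          p_noncardiac = list(
                            abnormal_ecg_or_cardiopathy = 32 / 83,
                            palpitations_or_dyspnea = 8 / 83,
                            effort = 22 / 83,
                            supine = 2 / 83,
                            age_gt_64 = 20 / 83,
                            precipitating_present = 26 / 83,
                            neurovegetative_recovery = 37 / 83,
                            prodrome_pattern = c(none = 9, blurred_only = 25,
                                                 autonomic_only = 45,
                                                 blurred_autonomic = 4,
                                                 other = 0) / 83
                          ),
                          seed = NULL) {
  cfg <- structure(
    list(n = n, prevalence_cardiac = prevalence_cardiac,
         p_cardiac = p_cardiac, p_noncardiac = p_noncardiac, seed = seed),
    class = "egsys_cohort_config"
  )
  validate_config(cfg)
}

config_bernoulli_items <- function() {
  c("abnormal_ecg_or_cardiopathy", "palpitations_or_dyspnea", "effort",
    "supine", "age_gt_64", "precipitating_present",
    "neurovegetative_recovery")
}

prodrome_pattern_levels <- function() {
  c("none", "blurred_only", "autonomic_only", "blurred_autonomic", "other")
}

validate_config <- function(config) {
  if (!inherits(config, "egsys_cohort_config")) {
    stop("expected an egsys_cohort_config", call. = FALSE)
  }
  n <- config$n
  if (length(n) != 1 || is.na(n) || n < 1 || n != as.integer(n)) {
    stop("cohort size n must be an integer >= 1", call. = FALSE)
  }
  config$n <- as.integer(n)
  pr <- config$prevalence_cardiac
  if (length(pr) != 1 || is.na(pr) || pr < 0 || pr > 1) {
    stop("prevalence_cardiac must be a probability in [0, 1]", call. = FALSE)
  }
  for (cls in c("p_cardiac", "p_noncardiac")) {
    p <- config[[cls]]
    for (item in config_bernoulli_items()) {
      v <- p[[item]]
      if (is.null(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
        stop(cls, "$", item, " must be a probability in [0, 1]", call. = FALSE)
      }
    }
    if (p$effort + p$supine > 1 + 1e-12) {
      stop(cls, ": effort + supine probabilities exceed 1 ",
           "(the two positions are mutually exclusive)", call. = FALSE)
    }
    pp <- p$prodrome_pattern
    if (!all(prodrome_pattern_levels() %in% names(pp))) {
      stop(cls, "$prodrome_pattern must name categories ",
           paste(prodrome_pattern_levels(), collapse = ", "), call. = FALSE)
    }
    pp <- pp[prodrome_pattern_levels()]
    if (any(is.na(pp)) || any(pp < 0) || abs(sum(pp) - 1) > 1e-8) {
      stop(cls, "$prodrome_pattern must be non-negative and sum to 1",
           call. = FALSE)
    }
    config[[cls]]$prodrome_pattern <- pp
  }
  if (!is.null(config$seed)) {
    if (length(config$seed) != 1 || is.na(config$seed)) {
      stop("seed must be a single integer or NULL", call. = FALSE)
    }
    config$seed <- as.integer(config$seed)
  }
  config
}

#' @export
print.egsys_cohort_config <- function(x, ...) {
  cat("EGSYS synthetic cohort configuration\n")
  cat("  n = ", x$n, ", cardiac prevalence = ",
      format(x$prevalence_cardiac, digits = 4),
      if (is.null(x$seed)) ", no seed" else paste0(", seed = ", x$seed),
      "\n", sep = "")
  tab <- rbind(
    cardiac = unlist(x$p_cardiac[config_bernoulli_items()]),
    noncardiac = unlist(x$p_noncardiac[config_bernoulli_items()])
  )
  print(round(tab, 3))
  cat("prodrome pattern:\n")
  print(round(rbind(cardiac = x$p_cardiac$prodrome_pattern,
                    noncardiac = x$p_noncardiac$prodrome_pattern), 3))
  invisible(x)
}

# Run expr under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# prodrome codes the generator treats as autonomic/vasovagal-type vs not;
# the autonomic_prodromes flag, not the codes, drives scoring
autonomic_pool <- function() c("nausea", "diaphoresis", "lightheadedness",
                               "vomiting", "pallor", "feeling_warm")
nonautonomic_pool <- function() c("weakness", "palpitations", "tremors",
                                  "yawn", "feeling_cold")
generic_factor_pool <- function() c("warm_place", "crowded_place",
                                    "prolonged_standing", "overtiring",
                                    "postprandial", "neck_turning",
                                    "syncope_sitting", "syncope_upright")

#' Generate a synthetic syncope cohort
#'
#' Draws `config$n` patients: the diagnosis class from
#' `Bernoulli(prevalence_cardiac)`, then every risk factor from its
#' class-conditional distribution (see [cohort_config()]). Ages are drawn
#' uniformly within the band implied by the age-over-64 indicator
#' (18–64 or 65–95). The combined abnormal-ECG/cardiopathy item is realised
#' as one randomly chosen ECG finding; set-valued fields receive concrete
#' codes consistent with the drawn indicators. Generation is fully
#' reproducible from `config$seed` and leaves the caller's RNG stream
#' untouched when a seed is given.
#'
#' @param config An [cohort_config()] object.
#' @return A validated `egsys_cohort` data frame with `config$n` rows.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 20, seed = 42))
#' table(cohort$diagnosis)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_config(config)
  with_seed(config$seed, {
    n <- config$n
    cardiac <- stats::runif(n) < config$prevalence_cardiac
    draw <- function(item) {
      p <- ifelse(cardiac, config$p_cardiac[[item]],
                  config$p_noncardiac[[item]])
      stats::runif(n) < p
    }
    ecg_item <- draw("abnormal_ecg_or_cardiopathy")
    palp <- draw("palpitations_or_dyspnea")
    age64 <- draw("age_gt_64")
    precip <- draw("precipitating_present")
    neuro <- draw("neurovegetative_recovery")

    # mutually exclusive effort/supine: one categorical draw per patient
    u <- stats::runif(n)
    p_eff <- ifelse(cardiac, config$p_cardiac$effort,
                    config$p_noncardiac$effort)
    p_sup <- ifelse(cardiac, config$p_cardiac$supine,
                    config$p_noncardiac$supine)
    effort <- u < p_eff
    supine <- !effort & u < p_eff + p_sup

    # prodrome state: one categorical draw fixes none/blurred/autonomic
    lv <- prodrome_pattern_levels()
    pat <- character(n)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(cardiac == cls)
      if (!length(idx)) next
      probs <- if (cls) config$p_cardiac$prodrome_pattern else
        config$p_noncardiac$prodrome_pattern
      pat[idx] <- sample(lv, length(idx), replace = TRUE, prob = probs)
    }

    age <- integer(n)
    age[age64] <- sample(65:95, sum(age64), replace = TRUE)
    age[!age64] <- sample(18:64, sum(!age64), replace = TRUE)

    ecg <- character(n)
    ecg[ecg_item] <- sample(ecg_finding_codes(), sum(ecg_item),
                            replace = TRUE)

    factors <- character(n)
    k <- sum(precip)
    if (k) factors[precip] <- sample(generic_factor_pool(), k, replace = TRUE)

    prodromes <- character(n)
    fill_from <- function(which_pat, pool, prefix = NULL) {
      idx <- which(pat == which_pat)
      if (!length(idx)) return()
      codes <- sample(pool, length(idx), replace = TRUE)
      if (!is.null(prefix)) codes <- paste(prefix, codes, sep = ";")
      prodromes[idx] <<- codes
    }
    prodromes[pat == "blurred_only"] <- "blurred_vision"
    fill_from("autonomic_only", autonomic_pool())
    fill_from("blurred_autonomic", autonomic_pool(), prefix = "blurred_vision")
    fill_from("other", nonautonomic_pool())
    autonomic <- pat %in% c("autonomic_only", "blurred_autonomic")

    new_cohort(
      patient_id = sprintf("S%05d", seq_len(n)),
      age = age,
      ecg_findings = ecg,
      cardiopathy = FALSE,
      palpitations_or_dyspnea = palp,
      syncope_during_effort = effort,
      syncope_supine = supine,
      precipitating_factors = factors,
      prodromes = prodromes,
      autonomic_prodromes = autonomic,
      neurovegetative_recovery_signs = neuro,
      diagnosis = ifelse(cardiac, "cardiac", "noncardiac")
    )
  })
}

# class-conditional probability of a scored item under a config
item_probability <- function(config, item, class = c("cardiac", "noncardiac")) {
  class <- match.arg(class)
  p <- if (class == "cardiac") config$p_cardiac else config$p_noncardiac
  pp <- p$prodrome_pattern
  switch(item,
         supine_or_effort = p$effort + p$supine,
         any_prodrome = 1 - pp[["none"]],
         no_prodromes = pp[["none"]],
         blurred_vision = pp[["blurred_only"]] + pp[["blurred_autonomic"]],
         autonomic_prodromes = pp[["autonomic_only"]] + pp[["blurred_autonomic"]],
         no_precipitating = 1 - p$precipitating_present,
         {
           if (!item %in% config_bernoulli_items()) {
             stop("unknown item: ", item, call. = FALSE)
           }
           p[[item]]
         })
}

#' Plug-in odds ratio implied by a generator configuration
#'
#' The cardiac-vs-noncardiac odds ratio
#' \eqn{[p_c/(1-p_c)] / [p_n/(1-p_n)]} implied by an item's
#' class-conditional probabilities. On default settings this reproduces the
#' 2x2 odds ratios computable from the calibration counts (e.g.
#' palpitations/dyspnea: (51/64)/(8/75) = 7.47).
#'
#' @param config An [cohort_config()] object.
#' @param item Item name: one of the Bernoulli items of the config, or a
#'   derived item (`supine_or_effort`, `any_prodrome`, `no_prodromes`,
#'   `no_precipitating`, `blurred_vision`, `autonomic_prodromes`).
#' @return The odds ratio (cardiac over noncardiac).
#' @export
plug_in_odds_ratio <- function(config, item) {
  config <- validate_config(config)
  p_c <- item_probability(config, item, "cardiac")
  p_n <- item_probability(config, item, "noncardiac")
  if (p_c <= 0 || p_c >= 1 || p_n <= 0 || p_n >= 1) {
    stop("odds ratio undefined: class probability for '", item,
         "' is 0 or 1", call. = FALSE)
  }
  unname((p_c / (1 - p_c)) / (p_n / (1 - p_n)))
}
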