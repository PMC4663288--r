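# Builders shared across test files. Fixtures are generated in code; no
# data files are read.

make_record <- function(patient_id = "P1", age = 50, ecg_findings = "",
                        cardiopathy = FALSE, palpitations_or_dyspnea = FALSE,
                        syncope_during_effort = FALSE, syncope_supine = FALSE,
                        precipitating_factors = "", prodromes = "",
                        autonomic_prodromes = FALSE,
                        neurovegetative_recovery_signs = FALSE,
                        diagnosis = "noncardiac") {
  new_cohort(patient_id = patient_id, age = age, ecg_findings = ecg_findings,
             cardiopathy = cardiopathy,
             palpitations_or_dyspnea = palpitations_or_dyspnea,
             syncope_during_effort = syncope_during_effort,
             syncope_supine = syncope_supine,
             precipitating_factors = precipitating_factors,
             prodromes = prodromes,
             autonomic_prodromes = autonomic_prodromes,
             neurovegetative_recovery_signs = neurovegetative_recovery_signs,
             diagnosis = diagnosis)
}

# Items data frame from explicit indicator values (defaults all FALSE).
make_items <- function(abnormal_ecg_or_cardiopathy = FALSE,
                       palpitations_or_dyspnea = FALSE,
                       effort = FALSE, supine = FALSE,
                       age_gt_64 = FALSE, precipitating_present = FALSE,
                       any_prodrome = FALSE, blurred_vision = FALSE,
                       autonomic_prodromes = FALSE,
                       neurovegetative_recovery = FALSE) {
  data.frame(
    abnormal_ecg_or_cardiopathy = abnormal_ecg_or_cardiopathy,
    palpitations_or_dyspnea = palpitations_or_dyspnea,
    effort = effort, supine = supine,
    supine_or_effort = effort | supine,
    age_gt_64 = age_gt_64,
    precipitating_present = precipitating_present,
    any_prodrome = any_prodrome | blurred_vision | autonomic_prodromes,
    blurred_vision = blurred_vision,
    autonomic_prodromes = autonomic_prodromes,
    neurovegetative_recovery = neurovegetative_recovery
  )
}

# Every reachable indicator pattern: 7 free booleans x 5 prodrome states.
all_item_patterns <- function() {
  g <- expand.grid(abn = c(FALSE, TRUE), palp = c(FALSE, TRUE),
                   eff = c(FALSE, TRUE), sup = c(FALSE, TRUE),
                   age = c(FALSE, TRUE), precip = c(FALSE, TRUE),
                   neuro = c(FALSE, TRUE),
                   prod = c("none", "other", "blurred", "autonomic",
                            "blurred_autonomic"),
                   stringsAsFactors = FALSE)
  data.frame(
    abnormal_ecg_or_cardiopathy = g$abn,
    palpitations_or_dyspnea = g$palp,
    effort = g$eff, supine = g$sup,
    supine_or_effort = g$eff | g$sup,
    age_gt_64 = g$age,
    precipitating_present = g$precip,
    any_prodrome = g$prod != "none",
    blurred_vision = g$prod %in% c("blurred", "blurred_autonomic"),
    autonomic_prodromes = g$prod %in% c("autonomic", "blurred_autonomic"),
    neurovegetative_recovery = g$neuro
  )
}

# A small random cohort of integer scores and labels for ROC tests.
random_scored_cohort <- function(n, seed, shift = 2) {
  set.seed(seed)
  labels <- ifelse(runif(n) < 0.5, "cardiac", "noncardiac")
  scores <- ifelse(labels == "cardiac",
                   sample(-2:10, n, replace = TRUE),
                   sample((-2:10) - shift, n, replace = TRUE))
  list(scores = scores, labels = labels)
}

# O(n^2) Mann-Whitney concordance: P(diseased score > non-diseased) + ties/2.
concordance_auc <- function(scores, labels) {
  x <- scores[labels == "cardiac"]
  y <- scores[labels == "noncardiac"]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}
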