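test_that("code vocabularies cover the defined clinical term lists", {
  # transcribed independently from the clinical definitions
  ecg_terms <- c("bradycardia_lt_40", "st_change_gt_1mm",
                 "qt_prolongation_440ms", "ventricular_tachycardia",
                 "av_block_2_or_3", "sick_sinus", "ventricular_or_rapid_svt",
                 "sinus_pause", "pacemaker_malfunction")
  factor_terms <- c("warm_place", "crowded_place", "prolonged_standing",
                    "overtiring", "postprandial", "neck_turning",
                    "syncope_sitting", "syncope_supine", "syncope_upright",
                    "syncope_during_effort", "syncope_after_effort")
  prodrome_terms <- c("blurred_vision", "lightheadedness", "diaphoresis",
                      "palpitations", "nausea", "vomiting",
                      "abdominal_discomfort", "weakness", "feeling_cold",
                      "feeling_warm", "tremors", "yawn", "pallor", "redness",
                      "cyanosis")
  expect_setequal(ecg_finding_codes(), ecg_terms)
  expect_setequal(precipitating_factor_codes(), factor_terms)
  expect_setequal(prodrome_codes(), prodrome_terms)
})

test_that("ecg_abnormal is true iff at least one finding is present", {
  expect_false(ecg_abnormal(make_record(ecg_findings = "")))
  expect_true(ecg_abnormal(make_record(ecg_findings = "st_change_gt_1mm")))
  expect_true(ecg_abnormal(
    make_record(ecg_findings = "bradycardia_lt_40;sinus_pause")))
  # monotone: adding any finding to any subset never flips true -> false
  codes <- ecg_finding_codes()
  for (k in 1:3) {
    set.seed(k)
    base <- sample(codes, k)
    extra <- sample(setdiff(codes, base), 1)
    before <- ecg_abnormal(make_record(ecg_findings = paste(base, collapse = ";")))
    after <- ecg_abnormal(
      make_record(ecg_findings = paste(c(base, extra), collapse = ";")))
    expect_true(!before || after)
  }
})

test_that("cohort CSV round-trip preserves every field and is idempotent", {
  cohort <- simulate_cohort(cohort_config(n = 198, seed = 404))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(cohort, f1)
  back <- read_cohort(f1)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
  write_cohort(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a small hand-written file parses field by field", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("patient_id", "age", "ecg_findings", "cardiopathy",
            "palpitations_or_dyspnea", "syncope_during_effort",
            "syncope_supine", "precipitating_factors", "prodromes",
            "autonomic_prodromes", "neurovegetative_recovery_signs",
            "diagnosis"), collapse = ","),
    "A,70,bradycardia_lt_40;sinus_pause,0,1,0,0,,blurred_vision,0,0,Cardiac",
    "B,30,,0,0,1,0,warm_place,nausea,1,1,NONCARDIAC",
    "C,45,,1,0,0,0,,,0,0,unknown"
  ), path)
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$diagnosis, c("cardiac", "noncardiac", "unknown"))
  expect_equal(cohort$ecg_findings[1], "bradycardia_lt_40;sinus_pause")
  expect_true(cohort$cardiopathy[3])
  expect_true(cohort$autonomic_prodromes[2])
  expect_equal(cohort$age, c(70L, 30L, 45L))
})

test_that("serialisation rules: empty cohort, 0/1 booleans, joined sets", {
  path <- tempfile(fileext = ".csv")
  empty <- validate_cohort(utils::read.csv(text = paste(
    c("patient_id", "age", "ecg_findings", "cardiopathy",
      "palpitations_or_dyspnea", "syncope_during_effort", "syncope_supine",
      "precipitating_factors", "prodromes", "autonomic_prodromes",
      "neurovegetative_recovery_signs", "diagnosis"), collapse = ","),
    colClasses = c(age = "integer")))
  write_cohort(empty, path)
  expect_equal(length(readLines(path)), 1) # header only
  rec <- make_record(ecg_findings = "sinus_pause;bradycardia_lt_40")
  write_cohort(rec, path)
  lines <- readLines(path)
  # set cells are vocabulary-ordered and semicolon-joined
  expect_match(lines[2], "bradycardia_lt_40;sinus_pause")
  expect_match(lines[2], ",0,0,0,0,", fixed = TRUE)
})

test_that("schema and row-level validation errors are specific", {
  base <- make_record()
  # missing column
  broken <- as.data.frame(base)
  broken$age <- NULL
  expect_error(validate_cohort(broken), "age")
  # unknown enum code, reported with row number
  two <- rbind(as.data.frame(make_record(patient_id = "A")),
               as.data.frame(make_record(patient_id = "B")))
  two$prodromes[2] <- "dizzyness"
  expect_error(validate_cohort(two), "row 2")
  # autonomic prodromes without any prodrome
  expect_error(make_record(prodromes = "", autonomic_prodromes = TRUE),
               "autonomic")
  # unparseable boolean in a file
  path <- tempfile(fileext = ".csv")
  df <- as.data.frame(make_record())
  df$cardiopathy <- "maybe"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "cardiopathy.*row")
  # invalid diagnosis
  expect_error(make_record(diagnosis = "cardiogenic"), "diagnosis")
})

test_that("effort/supine indicators sync from the factor set when absent", {
  df <- as.data.frame(make_record(precipitating_factors =
                                    "syncope_during_effort;warm_place"))
  df$syncope_during_effort <- NA
  df$syncope_supine <- NA
  cohort <- validate_cohort(df)
  expect_true(cohort$syncope_during_effort)
  expect_false(cohort$syncope_supine)
  # but an explicit indicator is authoritative
  df$syncope_during_effort <- FALSE
  expect_false(validate_cohort(df)$syncope_during_effort)
})
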