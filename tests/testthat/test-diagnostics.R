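test_that("confusion_at_cutoff counts with an inclusive boundary", {
  cm <- confusion_at_cutoff(3L, "cardiac", 3L)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]), c(tp = 1, fn = 0, fp = 0, tn = 0))
  cm <- confusion_at_cutoff(2L, "cardiac", 3L)
  expect_equal(cm$fn, 1L)
  # six patients counted by hand
  scores <- c(5, 2, 3, -1, 4, 3)
  labels <- c("cardiac", "cardiac", "noncardiac", "noncardiac", "cardiac",
              "cardiac")
  cm <- confusion_at_cutoff(scores, labels, 3)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 3, fn = 1, fp = 1, tn = 1))
  expect_error(confusion_at_cutoff(integer(0), character(0), 3), "empty")
  expect_error(confusion_at_cutoff(1:2, c("cardiac", "benign"), 3), "benign")
})

test_that("screening proportions match hand arithmetic on reconstructed matrices", {
  # matrices implied by 86.08%/68.29% and 91.30%/57.32% with 115/82 patients
  u <- confusion(tp = 99, fn = 16, fp = 26, tn = 56)
  m <- confusion(tp = 105, fn = 10, fp = 35, tn = 47)
  expect_equal(sensitivity(u), 99 / 115)
  expect_equal(specificity(u), 56 / 82)
  expect_equal(ppv(u), 0.792)
  expect_equal(npv(u), 56 / 72)
  expect_equal(sensitivity(m), 105 / 115)
  expect_equal(npv(m), 47 / 57)
  expect_equal(ppv(m), 0.75)
  z <- confusion(tp = 0, fn = 5, fp = 0, tn = 5)
  expect_equal(sensitivity(z), 0)
  expect_error(ppv(z), "zero denominator")
  expect_error(sensitivity(confusion(0, 0, 3, 4)), "zero denominator")
})

test_that("likelihood ratios: standard and posttest-odds conventions", {
  u <- confusion(tp = 99, fn = 16, fp = 26, tn = 56)
  lr <- likelihood_ratios(u)
  expect_equal(lr$lr_pos, (99 / 115) / (26 / 82), tolerance = 1e-12)
  expect_equal(lr$lr_pos, 2.715, tolerance = 1e-3)
  expect_equal(lr$odds_pos, 0.792 / 0.208, tolerance = 1e-12)
  expect_equal(lr$odds_neg, (16 / 72) / (56 / 72), tolerance = 1e-12)
  # sens = spec = 0.5 gives LR+ = 1
  lr <- likelihood_ratios(confusion(5, 5, 5, 5))
  expect_equal(lr$lr_pos, 1)
  expect_equal(lr$lr_neg, 1)
  expect_error(likelihood_ratios(confusion(5, 0, 5, 0)), "zero denominator")
})

test_that("Bayes consistency: ppv from counts equals ppv from (sens, spec, prevalence)", {
  set.seed(31)
  for (i in 1:25) {
    cm <- confusion(tp = sample(1:50, 1), fn = sample(1:50, 1),
                    fp = sample(1:50, 1), tn = sample(1:50, 1))
    prev <- (cm$tp + cm$fn) / (cm$tp + cm$fn + cm$fp + cm$tn)
    se <- sensitivity(cm)
    sp <- specificity(cm)
    expect_equal(ppv(cm),
                 se * prev / (se * prev + (1 - sp) * (1 - prev)),
                 tolerance = 1e-12)
    expect_equal(npv(cm),
                 sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev),
                 tolerance = 1e-12)
  }
})

test_that("Wilson interval solves the score-test inequality (uniroot oracle)", {
  # independent oracle: the Wilson bounds are the roots p of
  # (phat - p)^2 = z^2 p(1-p)/n
  z <- qnorm(0.975)
  for (case in list(c(99, 115), c(5, 10), c(1, 20), c(110, 115))) {
    x <- case[1]; n <- case[2]; phat <- x / n
    f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
    lo <- uniroot(f, c(1e-12, phat), tol = 1e-12)$root
    hi <- uniroot(f, c(phat, 1 - 1e-12), tol = 1e-12)$root
    ci <- proportion_ci(x, n, 0.95, "wilson")
    expect_equal(ci[1], lo, tolerance = 1e-8)
    expect_equal(ci[2], hi, tolerance = 1e-8)
  }
  # frozen value for the sensitivity numerator of the reconstructed matrix
  expect_equal(proportion_ci(99, 115, 0.95, "wilson"),
               c(0.7858988, 0.9125107), tolerance = 1e-6)
  expect_equal(proportion_ci(0, 10, 0.95, "wilson")[1], 0)
})

test_that("Clopper-Pearson matches binom.test and is symmetric at 5/10", {
  for (case in list(c(0, 10), c(5, 10), c(99, 115), c(20, 20))) {
    ci <- proportion_ci(case[1], case[2], 0.95, "clopper_pearson")
    ref <- binom.test(case[1], case[2])$conf.int
    expect_equal(ci, as.numeric(ref), tolerance = 1e-9)
  }
  ci <- proportion_ci(5, 10, 0.95, "clopper_pearson")
  expect_equal(ci[1], 1 - ci[2], tolerance = 1e-9)
})

test_that("proportion_ci validates its inputs", {
  expect_error(proportion_ci(5, 0), "n > 0")
  expect_error(proportion_ci(11, 10), "successes")
  expect_error(proportion_ci(5, 10, level = 1.5), "level")
  wald <- proportion_ci(5, 10, 0.95, "wald")
  expect_equal(wald, 0.5 + c(-1, 1) * qnorm(0.975) * sqrt(0.25 / 10))
})

test_that("2x2 odds ratios follow the cross-product and Woolf interval", {
  o <- odds_ratio_2x2(51, 8, 64, 75)
  expect_equal(o$or, 3825 / 512, tolerance = 1e-12)
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$or, 1)
  expect_equal(odds_ratio_2x2(10, 1, 105, 82)$or, 820 / 105, tolerance = 1e-12)
  # Woolf CI is log-symmetric about the estimate
  expect_equal(o$or^2, o$ci_low * o$ci_high, tolerance = 1e-9)
  se <- sqrt(1 / 51 + 1 / 8 + 1 / 64 + 1 / 75)
  expect_equal(o$ci_high, o$or * exp(qnorm(0.975) * se), tolerance = 1e-12)
  expect_error(odds_ratio_2x2(0, 1, 1, 1), "continuity")
  oc <- odds_ratio_2x2(0, 1, 1, 1, continuity = TRUE)
  expect_equal(oc$or, (0.5 * 1.5) / (1.5 * 1.5), tolerance = 1e-12)
  expect_error(odds_ratio_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("2x2 association test matches the chi-square formula and Fisher", {
  # balanced independent table
  expect_equal(chi2_2x2(20, 20, 20, 20), 1)
  expect_lt(chi2_2x2(51, 8, 64, 75), 0.001)
  # independent arithmetic oracle for the Pearson statistic
  a <- 12; b <- 5; c_ <- 7; d <- 20
  n <- a + b + c_ + d
  stat <- n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(chi2_2x2(a, b, c_, d), pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # Fisher flag delegates to the exact test
  expect_equal(chi2_2x2(3, 1, 1, 3, method = "fisher"),
               fisher.test(rbind(c(3, 1), c(1, 3)))$p.value)
  expect_error(chi2_2x2(0, 0, 0, 0), "all-zero")
})

test_that("sample-size formula reproduces the planning numbers", {
  expect_equal(sample_size_for_sensitivity(0.90, 0.05, 0.95), 138L)
  expect_equal(sample_size_for_sensitivity(0.50, 0.05, 0.95), 384L)
  expect_equal(sample_size_for_sensitivity(0.90, 0.05, 0.95, mode = "ceiling"),
               139L)
  # coarser precision needs fewer patients
  expect_lt(sample_size_for_sensitivity(0.90, 0.10),
            sample_size_for_sensitivity(0.90, 0.05))
  expect_error(sample_size_for_sensitivity(1, 0.05), "strictly")
  expect_error(sample_size_for_sensitivity(0.9, 0), "positive")
})

test_that("proportions are invariant under patient reordering", {
  set.seed(8)
  scores <- sample(-2:10, 40, replace = TRUE)
  labels <- sample(c("cardiac", "noncardiac"), 40, replace = TRUE,
                   prob = c(0.6, 0.4))
  perm <- sample(40)
  a <- confusion_at_cutoff(scores, labels, 3)
  b <- confusion_at_cutoff(scores[perm], labels[perm], 3)
  expect_identical(a, b)
})

test_that("accuracy_report bundles estimates with intervals", {
  rep <- accuracy_report(confusion(99, 16, 26, 56))
  expect_equal(rep$sensitivity$estimate, 99 / 115)
  expect_equal(c(rep$sensitivity$low, rep$sensitivity$high),
               proportion_ci(99, 115))
  expect_equal(rep$posttest_odds_pos, 0.792 / 0.208, tolerance = 1e-12)
  expect_true(rep$lr_pos$low < rep$lr_pos$estimate &
                rep$lr_pos$estimate < rep$lr_pos$high)
  # degenerate matrix: proportions survive, ratios are NA
  perfect <- accuracy_report(confusion(10, 0, 0, 10))
  expect_equal(perfect$sensitivity$estimate, 1)
  expect_equal(perfect$specificity$estimate, 1)
  expect_true(is.na(perfect$lr_pos$estimate))
})

test_that("Welch mean-score comparison", {
  r <- mean_score_comparison(c(5, 5, 1, 1),
                             c("cardiac", "cardiac", "noncardiac", "noncardiac"))
  expect_equal(r$mean_cardiac - r$mean_noncardiac, 4)
  expect_error(mean_score_comparison(1:3, rep("cardiac", 3)), "both")
  r <- mean_score_comparison(c(5, 1), c("cardiac", "noncardiac"))
  expect_true(is.na(r$p_value))
  # agrees with t.test
  set.seed(4)
  s <- rnorm(30)
  l <- rep(c("cardiac", "noncardiac"), 15)
  r <- mean_score_comparison(s, l)
  expect_equal(r$p_value, t.test(s[l == "cardiac"], s[l == "noncardiac"])$p.value)
})
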