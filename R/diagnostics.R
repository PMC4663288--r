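#' Confusion matrix at a score cut-off
#'
#' Cross-tabulates an integer score against a binary diagnosis with the
#' rule "positive iff score >= cutoff" (the cut-off boundary is inclusive).
#' `confusion()` builds the same object from raw counts.
#'
#' @param scores Integer score vector.
#' @param labels Diagnosis labels, `"cardiac"` (diseased) or
#'   `"noncardiac"`.
#' @param cutoff Positivity threshold.
#' @return An `egsys_confusion` object with integer fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @examples
#' cm <- confusion(tp = 99, fn = 16, fp = 26, tn = 56)
#' sensitivity(cm)
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("cardiac", "noncardiac"))
  if (length(bad)) {
    stop("labels must be cardiac/noncardiac; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pos <- scores >= cutoff
  dis <- labels == "cardiac"
  confusion(tp = sum(pos & dis), fn = sum(!pos & dis),
            fp = sum(pos & !dis), tn = sum(!pos & !dis))
}

#' @rdname confusion_at_cutoff
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @export
confusion <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != as.integer(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "egsys_confusion")
}

#' @export
print.egsys_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              diagnosis = c("cardiac", "noncardiac")))
  print(m)
  invisible(x)
}

ratio_or_stop <- function(num, den, what) {
  if (den == 0) {
    stop(what, " undefined: zero denominator", call. = FALSE)
  }
  num / den
}

#' Screening proportions of a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp) and negative predictive value tn/(tn+fn). A zero
#' denominator is an error, never silently 0.
#'
#' @param cm An `egsys_confusion` object.
#' @return A proportion in \[0, 1\].
#' @export
sensitivity <- function(cm) ratio_or_stop(cm$tp, cm$tp + cm$fn, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(cm) ratio_or_stop(cm$tn, cm$tn + cm$fp, "specificity")

#' @rdname sensitivity
#' @export
ppv <- function(cm) ratio_or_stop(cm$tp, cm$tp + cm$fp, "ppv")

#' @rdname sensitivity
#' @export
npv <- function(cm) ratio_or_stop(cm$tn, cm$tn + cm$fn, "npv")

#' Likelihood ratios, standard and posttest-odds forms
#'
#' The standard forms are `lr_pos = sens/(1-spec)` and
#' `lr_neg = (1-sens)/spec`. The posttest-odds forms,
#' `odds_pos = ppv/(1-ppv)` and `odds_neg = (1-npv)/npv`, are the
#' prevalence-dependent quantities some validation reports print under the
#' "likelihood ratio" heading; both are returned, clearly labelled, so
#' either convention can be reproduced.
#'
#' @param cm An `egsys_confusion` object.
#' @return A list with `lr_pos`, `lr_neg`, `odds_pos`, `odds_neg`.
#' @export
likelihood_ratios <- function(cm) {
  sens <- sensitivity(cm)
  spec <- specificity(cm)
  pv_pos <- ppv(cm)
  pv_neg <- npv(cm)
  list(
    lr_pos = ratio_or_stop(sens, 1 - spec, "positive likelihood ratio"),
    lr_neg = ratio_or_stop(1 - sens, spec, "negative likelihood ratio"),
    odds_pos = ratio_or_stop(pv_pos, 1 - pv_pos, "positive posttest odds"),
    odds_neg = ratio_or_stop(1 - pv_neg, pv_neg, "negative posttest odds")
  )
}

#' Binomial confidence interval for a proportion
#'
#' Two-sided interval for `successes/n` by the Wilson score method
#' (default), the exact Clopper-Pearson method (beta quantiles), or the
#' Wald normal approximation.
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level in (0, 1).
#' @param method `"wilson"`, `"clopper_pearson"` or `"wald"`.
#' @return Numeric `c(low, high)`, clamped to \[0, 1\].
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("wilson", "clopper_pearson", "wald")) {
  method <- match.arg(method)
  if (n <= 0 || successes < 0 || successes > n) {
    stop("require 0 <= successes <= n with n > 0", call. = FALSE)
  }
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    stop("confidence level must lie in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - level
  p <- successes / n
  ci <- switch(method,
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      den <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / den
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(centre - half, centre + half)
    },
    clopper_pearson = {
      low <- if (successes == 0) 0 else
        stats::qbeta(alpha / 2, successes, n - successes + 1)
      high <- if (successes == n) 1 else
        stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
      c(low, high)
    },
    wald = {
      z <- stats::qnorm(1 - alpha / 2)
      p + c(-1, 1) * z * sqrt(p * (1 - p) / n)
    }
  )
  pmin(pmax(ci, 0), 1)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' For counts arranged as (a = exposed diseased, b = exposed non-diseased,
#' c = unexposed diseased, d = unexposed non-diseased) the odds ratio is
#' `ad / bc`; the interval is the Woolf logit method,
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell makes
#' both undefined unless `continuity = TRUE`, which adds the Haldane 0.5 to
#' every cell.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param level Confidence level.
#' @param continuity Apply the Haldane-Anscombe 0.5 correction when any
#'   cell is zero.
#' @return A list with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, level = 0.95, continuity = FALSE) {
  counts <- as.numeric(c(a, b, c, d)) # avoid integer overflow in products
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(counts == 0)) {
    if (!continuity) {
      stop("odds ratio undefined with a zero cell; ",
           "set continuity = TRUE for the Haldane correction", call. = FALSE)
    }
    counts <- counts + 0.5
  }
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / counts))
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

#' Association test for a 2x2 table
#'
#' Pearson chi-square without continuity correction (1 df) by default, or
#' Fisher's exact test. Counts are arranged as in [odds_ratio_2x2()].
#'
#' @inheritParams odds_ratio_2x2
#' @param method `"pearson"` or `"fisher"`.
#' @return The two-sided p-value.
#' @export
chi2_2x2 <- function(a, b, c, d, method = c("pearson", "fisher")) {
  method <- match.arg(method)
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero table", call. = FALSE)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (method == "pearson") {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  } else {
    stats::fisher.test(tab)$p.value
  }
}

#' Accuracy report for a confusion matrix
#'
#' Bundles the four screening proportions with binomial confidence
#' intervals, the standard likelihood ratios with log-method (Simel)
#' intervals, and the posttest-odds variants.
#'
#' @param cm An `egsys_confusion` object.
#' @param level Confidence level for all intervals.
#' @param ci_method Proportion CI method, see [proportion_ci()].
#' @return An `egsys_accuracy` object: a list of `estimate`/`low`/`high`
#'   triples plus the posttest odds.
#' @export
accuracy_report <- function(cm, level = 0.95, ci_method = "wilson") {
  sens <- sensitivity(cm)
  spec <- specificity(cm)
  # degenerate matrices (perfect separation, empty prediction arms) leave
  # the affected ratio undefined; the report carries NA there
  lr <- tryCatch(likelihood_ratios(cm),
                 error = function(e) list(lr_pos = NA_real_,
                                          lr_neg = NA_real_,
                                          odds_pos = NA_real_,
                                          odds_neg = NA_real_))
  prop <- function(x, n) {
    ci <- proportion_ci(x, n, level, ci_method)
    list(estimate = x / n, low = ci[1], high = ci[2])
  }
  # Simel log-method CI for the standard likelihood ratios
  z <- stats::qnorm(1 - (1 - level) / 2)
  lr_ci <- function(lr_val, se) {
    if (is.na(lr_val) || !is.finite(se)) {
      return(list(estimate = lr_val, low = NA_real_, high = NA_real_))
    }
    list(estimate = lr_val, low = lr_val * exp(-z * se),
         high = lr_val * exp(z * se))
  }
  n_dis <- cm$tp + cm$fn
  n_non <- cm$fp + cm$tn
  se_pos <- sqrt((1 - sens) / (sens * n_dis) + spec / ((1 - spec) * n_non))
  se_neg <- sqrt(sens / ((1 - sens) * n_dis) + (1 - spec) / (spec * n_non))
  structure(list(
    confusion = cm,
    sensitivity = prop(cm$tp, n_dis),
    specificity = prop(cm$tn, n_non),
    ppv = prop(cm$tp, cm$tp + cm$fp),
    npv = prop(cm$tn, cm$tn + cm$fn),
    lr_pos = lr_ci(lr$lr_pos, se_pos),
    lr_neg = lr_ci(lr$lr_neg, se_neg),
    posttest_odds_pos = lr$odds_pos,
    posttest_odds_neg = lr$odds_neg,
    level = level, ci_method = ci_method
  ), class = "egsys_accuracy")
}

#' @export
print.egsys_accuracy <- function(x, digits = 2, ...) {
  pct <- function(e) sprintf("%.*f (%.*f-%.*f)", digits, 100 * e$estimate,
                             digits, 100 * e$low, digits, 100 * e$high)
  rat <- function(e) sprintf("%.*f (%.*f-%.*f)", digits, e$estimate,
                             digits, e$low, digits, e$high)
  cat(sprintf("%-28s %s\n", "Sensitivity (%)", pct(x$sensitivity)))
  cat(sprintf("%-28s %s\n", "Specificity (%)", pct(x$specificity)))
  cat(sprintf("%-28s %s\n", "Positive predictive value (%)", pct(x$ppv)))
  cat(sprintf("%-28s %s\n", "Negative predictive value (%)", pct(x$npv)))
  cat(sprintf("%-28s %s\n", "LR+ [sens/(1-spec)]", rat(x$lr_pos)))
  cat(sprintf("%-28s %s\n", "LR- [(1-sens)/spec]", rat(x$lr_neg)))
  cat(sprintf("%-28s %.*f\n", "Posttest odds, positive",
              digits, x$posttest_odds_pos))
  cat(sprintf("%-28s %.*f\n", "Posttest odds, negative",
              digits, x$posttest_odds_neg))
  invisible(x)
}

#' Sample size for estimating a sensitivity
#'
#' The normal-approximation precision formula
#' `n = z^2 * p * (1 - p) / d^2` for estimating a proportion `p` to
#' half-width `d` at the given confidence level; with 90% expected
#' sensitivity, 5% precision and 95% confidence it gives 138 (truncated).
#'
#' @param expected_sens Anticipated sensitivity, in (0, 1).
#' @param precision Desired half-width of the confidence interval, > 0.
#' @param level Confidence level.
#' @param mode `"truncate"` (drop the fraction) or `"ceiling"`.
#' @return Integer number of diseased subjects required.
#' @export
sample_size_for_sensitivity <- function(expected_sens, precision,
                                        level = 0.95,
                                        mode = c("truncate", "ceiling")) {
  mode <- match.arg(mode)
  if (expected_sens <= 0 || expected_sens >= 1) {
    stop("expected_sens must lie strictly in (0, 1)", call. = FALSE)
  }
  if (precision <= 0) stop("precision must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  n <- z^2 * expected_sens * (1 - expected_sens) / precision^2
  as.integer(if (mode == "truncate") floor(n) else ceiling(n))
}

#' Welch comparison of mean scores between diagnosis classes
#'
#' Group means and standard deviations of a score in the cardiac and
#' noncardiac classes, with the Welch two-sample t-test p-value.
#'
#' @param scores Numeric score vector.
#' @param labels `"cardiac"`/`"noncardiac"` labels.
#' @return A list with `mean_cardiac`, `sd_cardiac`, `mean_noncardiac`,
#'   `sd_noncardiac`, `p_value` (`NA` when either class has fewer than two
#'   members).
#' @export
mean_score_comparison <- function(scores, labels) {
  labels <- as.character(labels)
  x <- scores[labels == "cardiac"]
  y <- scores[labels == "noncardiac"]
  if (!length(x) || !length(y)) {
    stop("both diagnosis classes must be present", call. = FALSE)
  }
  p <- if (length(x) < 2 || length(y) < 2) NA_real_ else
    tryCatch(stats::t.test(x, y)$p.value,
             error = function(e) NA_real_) # degenerate: zero variance
  list(mean_cardiac = mean(x), sd_cardiac = stats::sd(x),
       mean_noncardiac = mean(y), sd_noncardiac = stats::sd(y),
       p_value = p)
}
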