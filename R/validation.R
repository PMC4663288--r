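#' Validate the EGSYS rule on a cohort
#'
#' The package's central entry point. Scores every patient with both EGSYS
#' variants, excludes patients of unknown diagnostic origin from all
#' accuracy denominators (their count and score summary are logged), and
#' computes the full diagnostic-validation battery: per-item frequency /
#' odds-ratio / p-value table, accuracy reports for EGSYS-U and EGSYS-M at
#' the cut-off, ROC curves with DeLong confidence intervals and the paired
#' DeLong comparison, Youden-optimal cut-offs, and Welch comparisons of
#' mean scores between diagnosis classes.
#'
#' @param cohort A validated cohort (see [read_cohort()],
#'   [simulate_cohort()]).
#' @param cutoff At-risk threshold, default 3 (boundary inclusive).
#' @param ci_method Binomial CI method for proportions, see
#'   [proportion_ci()].
#' @param level Confidence level for all intervals.
#' @return An `egsys_validation` object with `print`, `summary`, `plot`,
#'   `coef` and `predict` methods; persist it with [write_validation()].
#' @examples
#' fit <- egsys_validation(simulate_cohort(cohort_config(seed = 11)))
#' fit
#' coef(fit)
#' @export
egsys_validation <- function(cohort, cutoff = egsys_weights()$cutoff,
                             ci_method = "wilson", level = 0.95) {
  scored <- score_cohort(cohort, cutoff = cutoff)
  known <- scored[scored$diagnosis != "unknown", , drop = FALSE]
  excluded <- scored[scored$diagnosis == "unknown", , drop = FALSE]
  if (!nrow(known)) {
    stop("cohort contains no patients with known diagnosis", call. = FALSE)
  }
  if (length(unique(known$diagnosis)) < 2) {
    stop("cohort is single-class after excluding unknown diagnoses; ",
         "accuracy statistics are undefined", call. = FALSE)
  }
  labels <- known$diagnosis

  items <- derive_items(known)
  item_table <- item_frequency_table(items, labels, level = level)

  cm_u <- confusion_at_cutoff(known$egsys_u, labels, cutoff)
  cm_m <- confusion_at_cutoff(known$egsys_m, labels, cutoff)
  roc_u <- roc_curve(known$egsys_u, labels)
  roc_m <- roc_curve(known$egsys_m, labels)

  structure(list(
    cutoff = cutoff,
    level = level,
    ci_method = ci_method,
    n_total = nrow(scored),
    n_analysed = nrow(known),
    n_excluded = nrow(excluded),
    excluded_scores = excluded[, c("patient_id", "egsys_u", "egsys_m")],
    scores = scored,
    item_table = item_table,
    accuracy_u = accuracy_report(cm_u, level = level, ci_method = ci_method),
    accuracy_m = accuracy_report(cm_m, level = level, ci_method = ci_method),
    roc_u = roc_u,
    roc_m = roc_m,
    auc_u = auc_ci_delong(known$egsys_u, labels, level),
    auc_m = auc_ci_delong(known$egsys_m, labels, level),
    delong = delong_test(known$egsys_u, known$egsys_m, labels),
    youden_u = youden_best_cutoff(roc_u),
    youden_m = youden_best_cutoff(roc_m),
    means_u = mean_score_comparison(known$egsys_u, labels),
    means_m = mean_score_comparison(known$egsys_m, labels)
  ), class = "egsys_validation")
}

# Per-item frequency, cardiac-vs-noncardiac odds ratio (Woolf CI, Haldane
# continuity on zero cells) and Pearson chi-square p-value.
item_frequency_table <- function(items, labels, level = 0.95) {
  dis <- labels == "cardiac"
  rows <- c("abnormal_ecg_or_cardiopathy", "palpitations_or_dyspnea",
            "supine_or_effort", "effort", "supine", "age_gt_64",
            "no_precipitating", "no_prodromes", "blurred_vision",
            "neurovegetative_recovery", "precipitating_present",
            "autonomic_prodromes")
  out <- do.call(rbind, lapply(rows, function(item) {
    v <- switch(item,
                no_precipitating = !items$precipitating_present,
                no_prodromes = !items$any_prodrome,
                items[[item]])
    a <- sum(v & dis)
    b <- sum(v & !dis)
    c_ <- sum(!v & dis)
    d <- sum(!v & !dis)
    or <- tryCatch(odds_ratio_2x2(a, b, c_, d, level = level,
                                  continuity = TRUE),
                   error = function(e) list(or = NA_real_, ci_low = NA_real_,
                                            ci_high = NA_real_))
    p <- tryCatch(chi2_2x2(a, b, c_, d), error = function(e) NA_real_)
    data.frame(item = item, n = a + b,
               pct = 100 * (a + b) / length(labels),
               n_cardiac = a, n_noncardiac = b,
               odds_ratio = or$or, or_low = or$ci_low, or_high = or$ci_high,
               p_value = p)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.egsys_validation <- function(x, ...) {
  cat("EGSYS diagnostic validation (cut-off >=", x$cutoff, ")\n", sep = "")
  cat("  ", x$n_analysed, " patients analysed (",
      x$n_excluded, " excluded, unknown origin)\n", sep = "")
  cat(sprintf("  AUC: EGSYS-U %.3f (%.2f-%.2f), EGSYS-M %.3f (%.2f-%.2f), DeLong p = %.2f\n",
              x$auc_u[["auc"]], x$auc_u[["low"]], x$auc_u[["high"]],
              x$auc_m[["auc"]], x$auc_m[["low"]], x$auc_m[["high"]],
              x$delong$p.value))
  cat(sprintf("  Youden-optimal cut-off: EGSYS-U >=%g, EGSYS-M >=%g\n",
              x$youden_u, x$youden_m))
  cat(sprintf("  Sensitivity/specificity at cut-off: U %.1f%%/%.1f%%, M %.1f%%/%.1f%%\n",
              100 * x$accuracy_u$sensitivity$estimate,
              100 * x$accuracy_u$specificity$estimate,
              100 * x$accuracy_m$sensitivity$estimate,
              100 * x$accuracy_m$specificity$estimate))
  invisible(x)
}

#' @export
summary.egsys_validation <- function(object, digits = 2, ...) {
  x <- object
  print(x)
  cat("\nScreening performance, EGSYS-U:\n")
  print(x$accuracy_u, digits = digits)
  cat("\nScreening performance, EGSYS-M:\n")
  print(x$accuracy_m, digits = digits)
  cat("\nMean scores (cardiac vs noncardiac):\n")
  cat(sprintf("  EGSYS-U: %.2f +/- %.2f vs %.2f +/- %.2f (Welch p = %.2g)\n",
              x$means_u$mean_cardiac, x$means_u$sd_cardiac,
              x$means_u$mean_noncardiac, x$means_u$sd_noncardiac,
              x$means_u$p_value))
  cat(sprintf("  EGSYS-M: %.2f +/- %.2f vs %.2f +/- %.2f (Welch p = %.2g)\n",
              x$means_m$mean_cardiac, x$means_m$sd_cardiac,
              x$means_m$mean_noncardiac, x$means_m$sd_noncardiac,
              x$means_m$p_value))
  cat("\nItem table:\n")
  tab <- x$item_table
  tab$pct <- round(tab$pct, 1)
  tab$odds_ratio <- round(tab$odds_ratio, 2)
  tab$or_low <- round(tab$or_low, 2)
  tab$or_high <- round(tab$or_high, 2)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.egsys_validation <- function(object, ...) {
  w <- egsys_weights()
  all_items <- union(names(w$univariate), names(w$multivariate))
  out <- matrix(NA_integer_, length(all_items), 2,
                dimnames = list(all_items, c("EGSYS-U", "EGSYS-M")))
  out[names(w$univariate), 1] <- w$univariate
  out[names(w$multivariate), 2] <- w$multivariate
  out
}

#' @export
predict.egsys_validation <- function(object, newdata, ...) {
  scored <- score_cohort(newdata, cutoff = object$cutoff)
  scored[, c("patient_id", "egsys_u", "egsys_m", "at_risk_u", "at_risk_m")]
}

#' @export
plot.egsys_validation <- function(x, ...) {
  plot(x$roc_u, col = "black",
       main = "EGSYS-U vs EGSYS-M", ...)
  plot(x$roc_m, add = TRUE, col = "red")
  graphics::legend("bottomright", lwd = 2, col = c("black", "red"),
                   legend = c(sprintf("EGSYS-U (AUC %.3f)", x$auc_u[["auc"]]),
                              sprintf("EGSYS-M (AUC %.3f)", x$auc_m[["auc"]])))
  invisible(x)
}

fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

#' Write a validation report bundle
#'
#' Persists an [egsys_validation()] result as a deterministic set of plain
#' files: per-patient scores (`patient_scores.csv`), the item table
#' (`item_table.csv`), accuracy reports for both variants
#' (`accuracy.json`), the ROC points (`roc_points.csv`), AUCs / DeLong /
#' Youden / mean-score summaries (`summary.json`), and a run log
#' (`run_log.txt`) recording counts and exclusions. Re-running the same
#' validation writes byte-identical files.
#'
#' @param x An `egsys_validation` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_validation <- function(x, dir) {
  stopifnot(inherits(x, "egsys_validation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wfile <- function(name) {
    p <- file.path(dir, name)
    paths <<- c(paths, p)
    p
  }
  write_csv_lf <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  }

  scores <- x$scores
  for (col in cohort_bool_columns()) scores[[col]] <- as.integer(scores[[col]])
  write_csv_lf(as.data.frame(scores), wfile("patient_scores.csv"))
  write_csv_lf(x$item_table, wfile("item_table.csv"))

  acc <- function(a) {
    tripl <- function(e) list(estimate = e$estimate, low = e$low, high = e$high)
    list(confusion = a$confusion[c("tp", "fn", "fp", "tn")],
         sensitivity = tripl(a$sensitivity), specificity = tripl(a$specificity),
         ppv = tripl(a$ppv), npv = tripl(a$npv),
         lr_pos = tripl(a$lr_pos), lr_neg = tripl(a$lr_neg),
         posttest_odds_pos = a$posttest_odds_pos,
         posttest_odds_neg = a$posttest_odds_neg)
  }
  jsonlite::write_json(list(cutoff = x$cutoff, level = x$level,
                            ci_method = x$ci_method,
                            egsys_u = acc(x$accuracy_u),
                            egsys_m = acc(x$accuracy_m)),
                       wfile("accuracy.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  roc <- rbind(cbind(score = "egsys_u", as.data.frame(x$roc_u)),
               cbind(score = "egsys_m", as.data.frame(x$roc_m)))
  write_csv_lf(roc, wfile("roc_points.csv"))

  jsonlite::write_json(list(
    auc_u = as.list(x$auc_u), auc_m = as.list(x$auc_m),
    delong = list(z = unname(x$delong$statistic), p_value = x$delong$p.value),
    youden_cutoff = list(egsys_u = x$youden_u, egsys_m = x$youden_m),
    mean_scores = list(egsys_u = x$means_u, egsys_m = x$means_m)
  ), wfile("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    "EGSYS validation run",
    paste0("cutoff: >=", x$cutoff),
    paste0("ci_method: ", x$ci_method, " (level ", x$level, ")"),
    paste0("patients total: ", x$n_total),
    paste0("patients analysed: ", x$n_analysed),
    paste0("patients excluded (unknown origin): ", x$n_excluded),
    if (x$n_excluded > 0) {
      paste0("excluded EGSYS-M scores: ",
             paste(sort(x$excluded_scores$egsys_m), collapse = ", "),
             " (max ", max(x$excluded_scores$egsys_m), ")")
    },
    paste0("cardiac: ", x$accuracy_u$confusion$tp + x$accuracy_u$confusion$fn,
           ", noncardiac: ",
           x$accuracy_u$confusion$fp + x$accuracy_u$confusion$tn)
  )
  writeLines(log_lines, con = wfile("run_log.txt"), sep = "\n")
  invisible(paths)
}
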