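#' ROC curve of an integer score
#'
#' Sweeps every observed score as a positivity threshold (rule: positive
#' iff score >= threshold), plus sentinel thresholds giving the (1, 1) and
#' (0, 0) endpoints. True- and false-positive rates are non-increasing in
#' the threshold.
#'
#' @param scores Numeric score vector.
#' @param labels `"cardiac"` (diseased) / `"noncardiac"` labels.
#' @return An `egsys_roc` data frame with columns `threshold`, `tpr`,
#'   `fpr`, ordered by increasing threshold, with the diseased and
#'   non-diseased counts as attributes.
#' @examples
#' cohort <- score_cohort(simulate_cohort(cohort_config(n = 100, seed = 7)))
#' r <- roc_curve(cohort$egsys_m, cohort$diagnosis)
#' auc(r)
#' youden_best_cutoff(r)
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.character(labels)
  dis <- labels == "cardiac"
  non <- labels == "noncardiac"
  if (any(!dis & !non)) {
    stop("labels must be cardiac/noncardiac", call. = FALSE)
  }
  n1 <- sum(dis)
  n0 <- sum(non)
  if (n1 == 0 || n0 == 0) {
    stop("ROC curve requires both diagnosis classes", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) sum(scores[dis] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[non] >= t) / n0, numeric(1))
  out <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  attr(out, "n_diseased") <- n1
  attr(out, "n_nondiseased") <- n0
  class(out) <- c("egsys_roc", "data.frame")
  out
}

#' Area under an ROC curve
#'
#' Trapezoidal area over the (fpr, tpr) points. For a score this equals
#' the Mann-Whitney concordance probability: the chance that a random
#' diseased patient outscores a random non-diseased one, ties counting
#' one half.
#'
#' @param curve An `egsys_roc` object from [roc_curve()].
#' @return The area, in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "egsys_roc"))
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]
  y <- curve$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-optimal cut-off of an ROC curve
#'
#' The finite threshold maximising the Youden index J = tpr - fpr;
#' ties are broken toward the higher (more specific) threshold.
#'
#' @param curve An `egsys_roc` object.
#' @return The selected threshold.
#' @export
youden_best_cutoff <- function(curve) {
  stopifnot(inherits(curve, "egsys_roc"))
  fin <- is.finite(curve$threshold)
  if (!any(fin)) stop("degenerate ROC curve", call. = FALSE)
  j <- curve$tpr[fin] - curve$fpr[fin]
  thr <- curve$threshold[fin]
  best <- max(j)
  max(thr[j >= best - 1e-12])
}

#' @export
print.egsys_roc <- function(x, ...) {
  cat("ROC curve: ", attr(x, "n_diseased"), " diseased vs ",
      attr(x, "n_nondiseased"), " non-diseased; AUC = ",
      format(auc(x), digits = 4), "\n", sep = "")
  NextMethod()
}

#' @export
plot.egsys_roc <- function(x, add = FALSE, col = "black", lwd = 2, ...) {
  o <- order(x$fpr, x$tpr)
  if (!add) {
    graphics::plot(x$fpr[o], x$tpr[o], type = "l", col = col, lwd = lwd,
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$fpr[o], x$tpr[o], col = col, lwd = lwd, ...)
  }
  invisible(x)
}

# midrank placements: for each diseased score, the fraction of
# non-diseased scores it beats (ties half), and vice versa
delong_placements <- function(x1, x0) {
  n1 <- length(x1)
  n0 <- length(x0)
  v10 <- vapply(x1, function(s) (sum(s > x0) + 0.5 * sum(s == x0)) / n0,
                numeric(1))
  v01 <- vapply(x0, function(s) (sum(x1 > s) + 0.5 * sum(x1 == s)) / n1,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same patients using the
#' DeLong placement-based covariance estimate and a two-sided normal test
#' on the AUC difference.
#'
#' @param scores_a,scores_b Paired score vectors on identical patients.
#' @param labels `"cardiac"`/`"noncardiac"` labels.
#' @return An object of class `htest` with the z statistic, the two
#'   AUC estimates, and the p-value. The variance of the difference is
#'   attached as `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
        length(scores_a) != length(labels)) {
    stop("paired scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.character(labels)
  dis <- labels == "cardiac"
  non <- labels == "noncardiac"
  if (any(!dis & !non)) stop("labels must be cardiac/noncardiac", call. = FALSE)
  n1 <- sum(dis)
  n0 <- sum(non)
  if (n1 < 2 || n0 < 2) {
    stop("DeLong test needs at least two patients per class", call. = FALSE)
  }
  pa <- delong_placements(scores_a[dis], scores_a[non])
  pb <- delong_placements(scores_b[dis], scores_b[non])
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(
    statistic = c(z = z),
    p.value = p,
    estimate = c(auc_a = pa$auc, auc_b = pb$auc),
    var_diff = var_diff,
    alternative = "two.sided",
    method = "DeLong test for two correlated ROC curves",
    data.name = "paired scores"
  ), class = "htest")
}

# DeLong variance of a single AUC; used for AUC confidence intervals
auc_ci_delong <- function(scores, labels, level = 0.95) {
  labels <- as.character(labels)
  p <- delong_placements(scores[labels == "cardiac"],
                         scores[labels == "noncardiac"])
  v <- stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = p$auc,
    low = max(0, p$auc - z * sqrt(v)),
    high = min(1, p$auc + z * sqrt(v)))
}
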