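# Diagnostic-test evaluation: ROC/AUROC, sensitivity-anchored operating
# points, exact Clopper-Pearson intervals, confusion metrics, serial
# combination with a confirmatory reader, and transmission-reduction
# arithmetic. A case is predicted positive iff its score is >= the
# operating threshold (closed lower bound, which fixes tie behavior).

#' Bundle scores and binary labels for evaluation
#'
#' @param scores numeric vector of classifier scores.
#' @param labels logical (or 0/1) vector, TRUE = condition present.
#' @param record_ids optional identifiers.
#' @return object of class `scored_cohort`.
#' @export
scored_cohort <- function(scores, labels, record_ids = NULL) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stopf("scores/labels must not be NA")
  structure(list(scores = as.numeric(scores), labels = labels,
                 record_ids = record_ids %||%
                   sprintf("case%05d", seq_along(scores))),
            class = "scored_cohort")
}

check_both_classes <- function(cohort) {
  if (!any(cohort$labels) || all(cohort$labels))
    stopf("cohort must contain both classes")
}

#' ROC curve points
#'
#' One point per distinct score used as cut-off (positive iff score >=
#' threshold), plus the degenerate all-positive (threshold -Inf) and
#' all-negative (threshold +Inf) endpoints.
#'
#' @param cohort a [scored_cohort()].
#' @return data.frame with columns threshold, sensitivity, specificity,
#'   ordered by increasing threshold (sensitivity non-increasing).
#' @export
roc_points <- function(cohort) {
  check_both_classes(cohort)
  thr <- c(-Inf, sort(unique(cohort$scores)), Inf)
  npos <- sum(cohort$labels)
  nneg <- sum(!cohort$labels)
  sens <- vapply(thr, function(t) sum(cohort$scores >= t & cohort$labels) / npos, 0)
  spec <- vapply(thr, function(t) sum(cohort$scores < t & !cohort$labels) / nneg, 0)
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Area under the ROC curve
#'
#' Computed as the pair-counting (Mann-Whitney) statistic: the fraction of
#' positive-negative pairs in which the positive scores higher, ties
#' counted 1/2 — identical to the trapezoidal area under the ROC curve.
#'
#' @param cohort a [scored_cohort()].
#' @return AUROC in [0, 1].
#' @export
auroc <- function(cohort) {
  check_both_classes(cohort)
  r <- rank(cohort$scores, ties.method = "average")
  npos <- sum(cohort$labels)
  nneg <- sum(!cohort$labels)
  (sum(r[cohort$labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Stratified bootstrap percentile interval for the AUROC
#'
#' Positives and negatives are resampled separately (so every resample
#' retains both classes), the AUROC recomputed `n_boot` times, and the
#' percentile interval returned, widened if needed to contain the point
#' estimate.
#'
#' @param cohort a [scored_cohort()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return numeric c(lower, upper).
#' @export
auroc_ci <- function(cohort, n_boot = 2000, seed = 1L, level = 0.95) {
  check_both_classes(cohort)
  if (n_boot < 100) stopf("'n_boot' must be >= 100")
  set.seed(seed)
  pos <- cohort$scores[cohort$labels]
  neg <- cohort$scores[!cohort$labels]
  est <- auroc(cohort)
  boots <- vapply(seq_len(n_boot), function(b) {
    p <- sample(pos, replace = TRUE)
    q <- sample(neg, replace = TRUE)
    auroc(scored_cohort(c(p, q), c(rep(TRUE, length(p)), rep(FALSE, length(q)))))
  }, 0)
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  c(min(ci[1], est), max(ci[2], est))
}

#' Operating threshold anchored at a target sensitivity
#'
#' Returns the largest threshold whose sensitivity is >= the target — i.e.
#' the threshold maximizing specificity subject to the sensitivity
#' constraint. A target of 1 is always achievable (threshold at or below
#' the minimum positive score).
#'
#' @param cohort a [scored_cohort()].
#' @param target_sens required sensitivity in (0, 1].
#' @return list with `threshold`, `achieved_sensitivity`, `specificity`.
#' @export
threshold_at_sensitivity <- function(cohort, target_sens = 0.95) {
  if (target_sens <= 0 || target_sens > 1)
    stopf("'target_sens' must be in (0, 1]")
  if (!any(cohort$labels)) stopf("no positive cases in cohort")
  rp <- roc_points(cohort)
  ok <- rp[rp$sensitivity >= target_sens, ]
  best <- ok[which.max(ok$threshold), ]
  list(threshold = best$threshold,
       achieved_sensitivity = best$sensitivity,
       specificity = best$specificity)
}

#' Confusion counts at a threshold
#'
#' @param cohort a [scored_cohort()].
#' @param threshold operating cut-off; positive iff score >= threshold.
#' @return list of class `confusion_counts`: tp, fp, tn, fn.
#' @export
confusion_counts <- function(cohort, threshold) {
  pred <- cohort$scores >= threshold
  structure(list(
    tp = sum(pred & cohort$labels),
    fp = sum(pred & !cohort$labels),
    tn = sum(!pred & !cohort$labels),
    fn = sum(!pred & cohort$labels)
  ), class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts binomial tail probabilities through beta quantiles:
#' lower = qbeta(alpha/2; k, n-k+1), upper = qbeta(1-alpha/2; k+1, n-k),
#' with lower = 0 at k = 0 and upper = 1 at k = n.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric c(lower, upper).
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stopf("need integers 0 <= k <= n with n >= 1")
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

prop_with_ci <- function(k, n, level) {
  if (n == 0) {
    warnf("zero denominator; metric undefined")
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                k = k, n = n))
  }
  ci <- clopper_pearson(k, n, level)
  list(estimate = k / n, lower = unname(ci[1]), upper = unname(ci[2]),
       k = k, n = n)
}

#' Sensitivity, specificity, PPV and NPV with exact intervals
#'
#' All four proportions carry exact Clopper-Pearson intervals. A metric
#' with a zero denominator is reported as NA with a warning.
#'
#' @param counts a [confusion_counts()] object.
#' @param level confidence level (default 0.95).
#' @return named list of four `prop` entries (estimate, lower, upper, k, n).
#' @export
diagnostic_metrics <- function(counts, level = 0.95) {
  with(counts, list(
    sens = prop_with_ci(tp, tp + fn, level),
    spec = prop_with_ci(tn, tn + fp, level),
    ppv  = prop_with_ci(tp, tp + fp, level),
    npv  = prop_with_ci(tn, tn + fn, level)
  ))
}

#' Serial combination of a screening and a confirmatory reader
#'
#' Combined positive iff the screen AND the confirmatory reader are both
#' positive: screen-negative cases are never transmitted, hence negative.
#'
#' @param screen_flags,confirm_flags logical vectors of equal length.
#' @return logical vector of combined calls.
#' @export
serial_combine <- function(screen_flags, confirm_flags) {
  if (length(screen_flags) != length(confirm_flags))
    stopf("flag vectors must have equal length")
  screen_flags & confirm_flags
}

#' Fraction of ECGs withheld from transmission
#'
#' 1 - flagged/total: the share of records a screen-negative triage would
#' keep from the confirmatory reader.
#'
#' @param screen_flags logical vector of screen calls.
#' @return list with `fraction` and `percent` (nearest integer).
#' @export
transmission_reduction <- function(screen_flags) {
  if (!length(screen_flags)) stopf("empty input")
  frac <- 1 - sum(screen_flags) / length(screen_flags)
  list(fraction = frac, percent = round(100 * frac))
}

#' Full diagnostic report of a scored cohort
#'
#' Confusion counts and the four predictive metrics at the operating
#' threshold, AUROC with bootstrap CI, and the transmission-reduction
#' fraction implied by screening at that threshold.
#'
#' @param cohort a [scored_cohort()].
#' @param threshold operating cut-off.
#' @param level confidence level.
#' @param n_boot AUROC bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return object of class `diagnostic_report`.
#' @export
diagnostic_report <- function(cohort, threshold, level = 0.95,
                              n_boot = 2000, seed = 1L) {
  counts <- confusion_counts(cohort, threshold)
  structure(list(
    n = length(cohort$scores),
    threshold = threshold,
    counts = counts,
    metrics = diagnostic_metrics(counts, level),
    auroc = auroc(cohort),
    auroc_ci = auroc_ci(cohort, n_boot = n_boot, seed = seed, level = level),
    reduction = transmission_reduction(cohort$scores >= threshold),
    level = level
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(p) if (is.na(p$estimate)) "undefined" else
    sprintf("%.2f (%.2f-%.2f)", p$estimate, p$lower, p$upper)
  cat(sprintf("Diagnostic report (n = %d, threshold = %.4f)\n", x$n, x$threshold))
  cat(sprintf("  counts: TP %d, FP %d, TN %d, FN %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  m <- x$metrics
  cat(sprintf("  Sens %s  Spec %s\n", fmt(m$sens), fmt(m$spec)))
  cat(sprintf("  PPV  %s  NPV  %s\n", fmt(m$ppv), fmt(m$npv)))
  cat(sprintf("  AUROC %.3f (%.3f-%.3f)\n", x$auroc, x$auroc_ci[1], x$auroc_ci[2]))
  cat(sprintf("  transmission reduction: %d%% of ECGs withheld\n",
              x$reduction$percent))
  invisible(x)
}

#' Write a diagnostic report as JSON and a flat CSV summary
#'
#' @param report a [diagnostic_report()].
#' @param json_path,csv_path output files (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      n = report$n, threshold = report$threshold,
      counts = unclass(report$counts),
      metrics = report$metrics,
      auroc = report$auroc,
      auroc_ci = list(lower = report$auroc_ci[1], upper = report$auroc_ci[2]),
      reduction = report$reduction, level = report$level
    )
    jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(csv_path)) {
    m <- report$metrics
    df <- data.frame(
      metric = c("sens", "spec", "ppv", "npv", "auroc"),
      estimate = c(m$sens$estimate, m$spec$estimate, m$ppv$estimate,
                   m$npv$estimate, report$auroc),
      lower = c(m$sens$lower, m$spec$lower, m$ppv$lower, m$npv$lower,
                report$auroc_ci[1]),
      upper = c(m$sens$upper, m$spec$upper, m$ppv$upper, m$npv$upper,
                report$auroc_ci[2])
    )
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}
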