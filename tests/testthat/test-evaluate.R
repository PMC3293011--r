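# ROC/AUROC, operating points, exact binomial intervals, confusion metrics,
# serial combination and transmission reduction.

test_that("ROC points agree with brute-force confusion tables", {
  for (seed in c(1, 2)) {
    ch <- random_cohort(40, seed = seed, ties = seed == 2)
    rp <- roc_points(ch)
    expect_true(all(diff(rp$sensitivity) <= 1e-12))
    for (k in seq_len(nrow(rp))) {
      thr <- rp$threshold[k]
      pred <- ch$scores >= thr
      expect_equal(rp$sensitivity[k],
                   sum(pred & ch$labels) / sum(ch$labels))
      expect_equal(rp$specificity[k],
                   sum(!pred & !ch$labels) / sum(!ch$labels))
    }
  }

  # perfect separation passes through (sens 1, spec 1)
  perf <- scored_cohort(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  rp <- roc_points(perf)
  expect_true(any(rp$sensitivity == 1 & rp$specificity == 1))

  # all-tied scores admit only the degenerate operating points
  tied <- scored_cohort(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  rpt <- roc_points(tied)
  expect_setequal(paste(rpt$sensitivity, rpt$specificity),
                  c("1 0", "0 1"))

  expect_error(roc_points(scored_cohort(1:3 / 4, c(TRUE, TRUE, TRUE))),
               "both classes")
})

test_that("AUROC equals the all-pairs statistic and behaves at the extremes", {
  expect_equal(auroc(scored_cohort(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE))), 1)

  set.seed(3)
  null <- scored_cohort(runif(4000), runif(4000) < 0.5)
  expect_lt(abs(auroc(null) - 0.5), 0.03)

  for (seed in 1:5) {
    ch <- random_cohort(25, seed = seed, ties = seed %% 2 == 0)
    expect_equal(auroc(ch), pairs_auroc(ch$scores, ch$labels))
  }
})

test_that("AUROC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:3) {
    ch <- random_cohort(60, seed = seed)
    ref <- as.numeric(pROC::auc(pROC::roc(ch$labels, ch$scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(auroc(ch), ref, tolerance = 1e-12)
  }
})

test_that("the bootstrap AUROC interval is sane and shrinks with n", {
  perf <- scored_cohort(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(auroc_ci(perf, n_boot = 200, seed = 1), c(1, 1))

  gen <- function(n, seed) {
    set.seed(seed)
    npos <- n %/% 4
    scored_cohort(c(rnorm(npos, 1), rnorm(n - npos)),
                  rep(c(TRUE, FALSE), c(npos, n - npos)))
  }
  w_small <- diff(auroc_ci(gen(100, 5), n_boot = 400, seed = 2))
  w_large <- diff(auroc_ci(gen(2000, 6), n_boot = 400, seed = 2))
  expect_lt(w_large, w_small)

  # interval always contains the point estimate
  for (seed in 1:5) {
    ch <- random_cohort(30, seed = seed)
    ci <- auroc_ci(ch, n_boot = 200, seed = seed)
    a <- auroc(ch)
    expect_gte(a, ci[1]); expect_lte(a, ci[2])
  }
})

test_that("the bootstrap interval covers the true AUROC at nominal rate", {
  mu <- 1.2
  true_auc <- pnorm(mu / sqrt(2))
  R <- 200
  cover <- 0
  for (r in seq_len(R)) {
    set.seed(5000 + r)
    ch <- scored_cohort(c(rnorm(40, mu), rnorm(120)),
                        rep(c(TRUE, FALSE), c(40, 120)))
    ci <- auroc_ci(ch, n_boot = 300, seed = r)
    if (ci[1] <= true_auc && true_auc <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / R, 0.95 - 0.04)
  expect_lte(cover / R, 1)
})

test_that("sensitivity-anchored thresholds maximize specificity under the constraint", {
  set.seed(7)
  ch <- scored_cohort(c(rnorm(38, 1.2), rnorm(522)),
                      rep(c(TRUE, FALSE), c(38, 522)))

  op <- threshold_at_sensitivity(ch, 1.0)
  expect_equal(op$achieved_sensitivity, 1)

  op95 <- threshold_at_sensitivity(ch, 0.95)
  expect_gte(op95$achieved_sensitivity, 36 / 38)

  # exhaustive scan: no threshold meeting the constraint does better
  rp <- roc_points(ch)
  feasible <- rp[rp$sensitivity >= 0.95, ]
  expect_equal(op95$specificity, max(feasible$specificity))

  # a stricter target can only cost specificity
  spec_at <- function(t) threshold_at_sensitivity(ch, t)$specificity
  targets <- c(0.5, 0.7, 0.9, 0.95, 1.0)
  expect_true(all(diff(vapply(targets, spec_at, 0)) <= 1e-12))
})

test_that("confusion counts recount correctly at any threshold", {
  ch <- random_cohort(50, seed = 9)
  hi <- confusion_counts(ch, max(ch$scores) + 1)
  expect_equal(hi$tp + hi$fp, 0)
  lo <- confusion_counts(ch, min(ch$scores))
  expect_equal(lo$tn + lo$fn, 0)
  for (thr in c(0.2, 0.5, 0.8)) {
    cc <- confusion_counts(ch, thr)
    expect_equal(cc$tp, sum(ch$scores >= thr & ch$labels))
    expect_equal(cc$fn, sum(ch$scores < thr & ch$labels))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 50)
  }
})

test_that("Clopper-Pearson intervals are exact and contain the estimate", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(-1, 4), "k <= n")

  # independent oracle: stats::binom.test's exact interval
  for (n in c(10, 38, 100)) {
    for (k in unique(round(c(0, n / 4, n / 2, n)))) {
      ci <- clopper_pearson(k, n)
      ref <- binom.test(k, n)$conf.int
      expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-12)
      expect_lte(ci[["lower"]], k / n)
      expect_gte(ci[["upper"]], k / n)
    }
  }
})

test_that("metric formulas with intervals match hand recomputation", {
  cc <- structure(list(tp = 17, fp = 9, tn = 61, fn = 3),
                  class = "confusion_counts")
  m <- diagnostic_metrics(cc)
  expect_equal(m$sens$estimate, 17 / 20)
  expect_equal(m$spec$estimate, 61 / 70)
  expect_equal(m$ppv$estimate, 17 / 26)
  expect_equal(m$npv$estimate, 61 / 64)
  expect_equal(c(m$sens$lower, m$sens$upper),
               unname(clopper_pearson(17, 20)))

  cc0 <- structure(list(tp = 0, fp = 0, tn = 12, fn = 3),
                   class = "confusion_counts")
  expect_warning(m0 <- diagnostic_metrics(cc0), "undefined")
  expect_equal(m0$spec$estimate, 1)
  expect_true(is.na(m0$ppv$estimate))
})

test_that("serial combination is AND-logic with its dominance inequalities", {
  confirm <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(serial_combine(rep(TRUE, 4), confirm), confirm)
  expect_equal(serial_combine(rep(FALSE, 4), confirm), rep(FALSE, 4))
  expect_error(serial_combine(c(TRUE, FALSE), confirm), "equal length")

  set.seed(11)
  for (r in 1:10) {
    truth <- runif(80) < 0.3
    screen <- truth & runif(80) < 0.9 | runif(80) < 0.2
    confirm <- truth & runif(80) < 0.8 | runif(80) < 0.1
    comb <- serial_combine(screen, confirm)
    sens <- function(f) sum(f & truth) / sum(truth)
    spec <- function(f) sum(!f & !truth) / sum(!truth)
    expect_lte(sens(comb), min(sens(screen), sens(confirm)))
    expect_gte(spec(comb), max(spec(screen), spec(confirm)))
  }
})

test_that("transmission reduction is the withheld fraction", {
  flags <- rep(c(TRUE, FALSE), c(204, 356))
  tr <- transmission_reduction(flags)
  expect_equal(tr$percent, 64)
  expect_equal(transmission_reduction(rep(TRUE, 9))$percent, 0)
  expect_equal(transmission_reduction(rep(FALSE, 9))$percent, 100)
  expect_error(transmission_reduction(logical(0)), "empty")
})

test_that("diagnostic reports assemble and serialize coherently", {
  set.seed(13)
  ch <- scored_cohort(c(rnorm(20, 1.5), rnorm(80)),
                      rep(c(TRUE, FALSE), c(20, 80)))
  op <- threshold_at_sensitivity(ch, 0.95)
  rep_ <- diagnostic_report(ch, op$threshold, n_boot = 200, seed = 3)
  m <- rep_$metrics
  for (p in m) {
    if (is.na(p$estimate)) next
    expect_gte(p$estimate, p$lower)
    expect_lte(p$estimate, p$upper)
  }
  expect_equal(with(rep_$counts, tp + fp + tn + fn), 100)

  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_report(rep_, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$auroc, rep_$auroc)
  df <- read.csv(cp)
  expect_equal(df$metric, c("sens", "spec", "ppv", "npv", "auroc"))
})
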