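# End-to-end experiment orchestration: synthesize -> extract -> reduce ->
# train -> evaluate, with one global seed from which every stage seed is
# derived. The reducer and the ensemble are fitted on the training cohort
# only; the operating threshold is calibrated on the cohort named by
# `calibration` (training cohort by default, so the test evaluation stays
# leakage-free).

#' Configuration of a full screening experiment
#'
#' @param train_n,train_prevalence training-cohort size and STEMI
#'   prevalence (defaults 3000 and 0.2).
#' @param test_n,test_prevalence test-cohort size and STEMI prevalence
#'   (defaults 560 and 38/560, the ambulance-cohort composition).
#' @param noise_sd,baseline_wander generator noise settings shared by both
#'   cohorts (see [synth_config()]).
#' @param p_pci_given_stemi,p_pci_given_nonstemi conditional probabilities
#'   of the needs-acute-PCI label, shared by both cohorts.
#' @param n_components retained principal components (default 20).
#' @param train a [train_config()]; its seed is derived from `seed`.
#' @param target_sensitivity sensitivity anchor for the operating point.
#' @param outcome `"stemi"` or `"needs_acute_pci"`.
#' @param calibration `"train"` (default) calibrates the threshold on the
#'   training cohort's own predictions; `"test"` calibrates on the test
#'   cohort (the apparent-performance mode).
#' @param level confidence level; `n_boot` AUROC bootstrap replicates.
#' @param do_cv run [cross_validate()] before training and adopt the
#'   selected (lambda, n_hidden).
#' @param seed global integer seed; train/test cohort seeds and all
#'   downstream seeds are derived from it (and are distinct).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(train_n = 3000, train_prevalence = 0.2,
                              test_n = 560, test_prevalence = 38 / 560,
                              noise_sd = 0.02, baseline_wander = c(0.05, 0.3),
                              p_pci_given_stemi = 0.9,
                              p_pci_given_nonstemi = 0.01,
                              n_components = 20,
                              train = train_config(),
                              target_sensitivity = 0.95,
                              outcome = c("stemi", "needs_acute_pci"),
                              calibration = c("train", "test"),
                              level = 0.95, n_boot = 2000,
                              do_cv = FALSE, seed = 1L) {
  outcome <- match.arg(outcome)
  calibration <- match.arg(calibration)
  assert_fraction(target_sensitivity, "target_sensitivity")
  train$seed <- mix_seed(seed, 3)
  structure(list(
    train_synth = synth_config(n_cases = train_n,
                               stemi_prevalence = train_prevalence,
                               p_pci_given_stemi = p_pci_given_stemi,
                               p_pci_given_nonstemi = p_pci_given_nonstemi,
                               noise_sd = noise_sd,
                               baseline_wander = baseline_wander,
                               seed = mix_seed(seed, 1)),
    test_synth = synth_config(n_cases = test_n,
                              stemi_prevalence = test_prevalence,
                              p_pci_given_stemi = p_pci_given_stemi,
                              p_pci_given_nonstemi = p_pci_given_nonstemi,
                              noise_sd = noise_sd,
                              baseline_wander = baseline_wander,
                              seed = mix_seed(seed, 2)),
    n_components = n_components,
    train = train,
    target_sensitivity = target_sensitivity,
    outcome = outcome,
    calibration = calibration,
    level = level,
    n_boot = n_boot,
    do_cv = do_cv,
    seed = as.integer(seed)
  ), class = "experiment_config")
}

# Generate a cohort case by case and extract features immediately, so the
# waveforms of a 3000-record cohort never sit in memory together.
synth_features <- function(synth_cfg) {
  X <- matrix(NA_real_, synth_cfg$n_cases, 156)
  stemi <- logical(synth_cfg$n_cases)
  pci <- logical(synth_cfg$n_cases)
  ids <- character(synth_cfg$n_cases)
  for (i in seq_len(synth_cfg$n_cases)) {
    case <- generate_case(synth_cfg, i)
    f <- extract_features(case$record)
    X[i, ] <- f
    if (i == 1) colnames(X) <- names(f)
    stemi[i] <- case$label$stemi
    pci[i] <- case$label$needs_acute_pci
    ids[i] <- case$record$record_id
  }
  rownames(X) <- ids
  list(features = X,
       labels = data.frame(record_id = ids, stemi = stemi,
                           needs_acute_pci = pci))
}

#' Run the full screening experiment
#'
#' Generates independent training and test cohorts, fits the reducer and
#' the bagged ensemble on the training cohort only, places the operating
#' threshold at the configured sensitivity anchor, and evaluates on the
#' test cohort. Fully reproducible for a fixed config.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for artifacts (report.json,
#'   report.csv, reducer.json, ensemble.json, run_log.json).
#' @param verbose print stage progress.
#' @return object of class `experiment_result`: the `report`
#'   ([diagnostic_report()]), fitted `reducer` and `ensemble`, the
#'   `operating` point, test `scores` and `labels`, and the `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  say("synthesizing training cohort (n = %d)", config$train_synth$n_cases)
  train <- synth_features(config$train_synth)
  y_train <- train$labels[[config$outcome]]
  if (length(unique(y_train)) < 2)
    stopf("stage train: training cohort has a single %s class", config$outcome)

  say("fitting reducer (156 -> %d)", config$n_components)
  reducer <- fit_reducer(train$features, config$n_components)
  s_train <- apply_reducer(reducer, train$features)

  tc <- config$train
  if (config$do_cv) {
    say("cross-validating hyperparameters")
    sel <- cross_validate(s_train, y_train, tc)
    tc$lambda <- sel$lambda
    tc$n_hidden <- sel$n_hidden
    say("selected lambda = %g, n_hidden = %d", sel$lambda, sel$n_hidden)
  }

  say("training %d-member ensemble", tc$n_members)
  ensemble <- train_ensemble(s_train, y_train, tc)

  say("synthesizing test cohort (n = %d)", config$test_synth$n_cases)
  test <- synth_features(config$test_synth)
  y_test <- test$labels[[config$outcome]]
  scores_test <- predict(ensemble, apply_reducer(reducer, test$features))
  test_cohort <- scored_cohort(scores_test, y_test, test$labels$record_id)

  say("calibrating threshold at sensitivity %.2f on the %s cohort",
      config$target_sensitivity, config$calibration)
  cal_cohort <- if (config$calibration == "train") {
    scored_cohort(predict(ensemble, s_train), y_train)
  } else {
    test_cohort
  }
  operating <- threshold_at_sensitivity(cal_cohort, config$target_sensitivity)

  say("evaluating on the test cohort")
  report <- diagnostic_report(test_cohort, operating$threshold,
                              level = config$level, n_boot = config$n_boot,
                              seed = mix_seed(config$seed, 4))

  result <- structure(list(report = report, reducer = reducer,
                           ensemble = ensemble, operating = operating,
                           scores = scores_test, labels = test$labels,
                           config = config),
                      class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"),
                 file.path(out_dir, "report.csv"))
    write_reducer(reducer, file.path(out_dir, "reducer.json"))
    write_ensemble(ensemble, file.path(out_dir, "ensemble.json"))
    log <- list(
      seed = config$seed,
      train_seed = config$train_synth$seed,
      test_seed = config$test_synth$seed,
      train_config = unclass(tc),
      n_components = config$n_components,
      outcome = config$outcome,
      calibration = config$calibration,
      target_sensitivity = config$target_sensitivity,
      operating = operating,
      train_n = config$train_synth$n_cases,
      test_n = config$test_synth$n_cases
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Screening experiment (outcome: %s)\n", x$config$outcome))
  cat(sprintf("  train n = %d, test n = %d, %d components, %d members\n",
              x$config$train_synth$n_cases, x$config$test_synth$n_cases,
              x$config$n_components, length(x$ensemble$members)))
  print(x$report)
  invisible(x)
}
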