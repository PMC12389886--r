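#' Reference per-subject classification performance tables
#'
#' Published per-subject test metrics (percent) of the seven-subject
#' robot-assisted cohort for the cost-sensitive SVM and the random
#' forest, shipped as package data. They are the inputs for the cohort
#' aggregation ("Mean +/- std" rows) and for the paired SVM-vs-RF
#' comparisons.
#'
#' @return A list with data frames `svm` and `rf`, columns `subject`,
#'   `accuracy`, `precision`, `recall`, `f1` (percent).
#' @export
reference_performance <- function() {
  rd <- function(f) read.csv(system.file("extdata", f,
                                         package = "painflex"))
  list(svm = rd("experiment2_svm_performance.csv"),
       rf = rd("experiment2_rf_performance.csv"))
}

#' Run the full robot-training evaluation on a cohort
#'
#' End-to-end orchestration of the pipeline on an Experiment-II-style
#' cohort: zero-phase filtering, sliding-window feature extraction,
#' double-cross-validated fitting of one or both classifiers per subject,
#' pseudo-online decision streams on each subject's held-out test trials
#' (each trial scored by the outer-fold model that never saw it),
#' majority-vote smoothing, maxAP estimation, and cohort aggregation.
#'
#' @param cohort a [synth_cohort()] result, or any list of subjects with
#'   `subject` and `trials` fields (trials must carry angle traces for
#'   the maxAP stage).
#' @param classifiers character vector among `"csvm"`, `"rf"`.
#' @param spec a [classifier_spec()].
#' @param feature_cfg a [feature_config()].
#' @param smooth_width odd majority-vote width.
#' @param seed master seed; every number in the report is reproducible
#'   from `(cohort, seed)`.
#' @param filter apply [bandpass_notch()] before feature extraction.
#' @return A list of class `painflex_report`: per classifier, the
#'   per-subject fits, the per-subject metrics table with its cohort
#'   mean/sd row, the [bias_summary()], and (when both classifiers ran)
#'   the paired per-metric comparisons.
#' @export
run_experiment2 <- function(cohort, classifiers = c("csvm", "rf"),
                            spec = classifier_spec(),
                            feature_cfg = feature_config(),
                            smooth_width = 5L, seed = 1L, filter = TRUE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  seeds <- derive_seeds(seed, length(cohort))
  subjects <- lapply(seq_along(cohort), function(s) {
    subj <- cohort[[s]]
    trials <- if (filter) lapply(subj$trials, bandpass_notch)
    else subj$trials
    features <- build_feature_table(trials, feature_cfg)
    out <- list(subject = subj$subject, trials = trials,
                features = features)
    for (cl in classifiers) {
      fit <- painflex(features, classifier = cl, spec = spec,
                      seed = seeds[s])
      est <- lapply(fit$fold_trials, function(ids) {
        fold <- which(vapply(fit$folds, function(f)
          setequal(f$test_trials, ids), TRUE))[1L]
        lapply(ids, function(id) {
          tf <- features[features$trial_id == id, , drop = FALSE]
          stream <- predict_stream(fit$folds[[fold]]$model, tf)
          stream <- smooth_decisions(stream, width = smooth_width)
          tr <- trials[[which(vapply(trials, function(t) t$trial_id,
                                     0L) == id)[1L]]]
          estimate_maxap(stream, tr)
        })
      })
      out[[cl]] <- list(fit = fit, estimates = unlist(est,
                                                      recursive = FALSE))
    }
    out
  })
  report <- list(classifiers = classifiers, seed = seed,
                 subjects = subjects)
  for (cl in classifiers) {
    tab <- do.call(rbind, lapply(subjects, function(su) {
      mm <- su[[cl]]$fit$mean_metrics
      data.frame(subject = su$subject, accuracy = 100 * mm["acc"],
                 precision = 100 * mm["pre"], recall = 100 * mm["rec"],
                 f1 = 100 * mm["f1"], row.names = NULL)
    }))
    agg <- aggregate_subjects(tab[, -1L])
    ests <- unlist(lapply(subjects, function(su) su[[cl]]$estimates),
                   recursive = FALSE)
    subj_of <- rep(vapply(subjects, function(su) su$subject, 0L),
                   vapply(subjects, function(su)
                     length(su[[cl]]$estimates), 0L))
    report[[cl]] <- list(per_subject = tab, cohort = agg,
                         bias = bias_summary(ests, subj_of))
  }
  if (all(c("csvm", "rf") %in% classifiers)) {
    report$comparison <- lapply(
      stats::setNames(nm = c("accuracy", "precision", "recall", "f1")),
      function(m) paired_t(report$csvm$per_subject[[m]],
                           report$rf$per_subject[[m]], name = m))
  }
  class(report) <- "painflex_report"
  report
}

#' @export
print.painflex_report <- function(x, ...) {
  cat(sprintf("<painflex_report> %d subjects, classifiers: %s\n",
              length(x$subjects),
              paste(toupper(x$classifiers), collapse = ", ")))
  for (cl in x$classifiers) {
    co <- x[[cl]]$cohort
    b <- x[[cl]]$bias
    cat(sprintf(
      paste0("  %s: Acc %.2f +/- %.2f%%, Pre %.2f%%, Rec %.2f%%, F1 ",
             "%.2f%%\n       maxAP bias %.2f +/- %.2f deg, early fraction ",
             "%.1f%% (%d early / %d delayed / %d none)\n"),
      toupper(cl), co["mean", "accuracy"], co["sd", "accuracy"],
      co["mean", "precision"], co["mean", "recall"], co["mean", "f1"],
      b$mean_bias, b$sd_bias, 100 * b$early_fraction,
      b$n_early, b$n_delayed, b$n_none))
  }
  if (!is.null(x$comparison)) {
    cat("  SVM vs RF (paired):\n")
    for (cmp in x$comparison)
      cat(sprintf("    %-9s t(%d) = %.4f, p = %.4f %s\n",
                  cmp$name, cmp$df, cmp$t, cmp$p, cmp$stars))
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits the per-subject metric tables (with the mean/sd row) as CSV and
#' the bias and comparison summaries as JSON.
#'
#' @param report a [run_experiment2()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in report$classifiers) {
    tab <- report[[cl]]$per_subject
    agg <- report[[cl]]$cohort
    tail <- data.frame(subject = c("mean", "sd"),
                       accuracy = agg$accuracy,
                       precision = agg$precision,
                       recall = agg$recall, f1 = agg$f1)
    write.csv(rbind(tab, tail),
              file.path(dir, paste0("metrics_", cl, ".csv")),
              row.names = FALSE)
  }
  js <- list(seed = report$seed)
  for (cl in report$classifiers)
    js[[cl]] <- report[[cl]]$bias[c("mean_bias", "sd_bias",
                                    "mean_bias_inclusive",
                                    "early_fraction", "n_early",
                                    "n_delayed", "n_none")]
  if (!is.null(report$comparison))
    js$comparison <- lapply(report$comparison, function(cmp)
      cmp[c("t", "df", "p", "stars")])
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
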