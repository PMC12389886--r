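#' Pseudo-online decision stream for one trial
#'
#' Scores every sliding window of a trial in time order with a fitted
#' pain-state model, exactly as a real-time system would: each decision
#' uses only that window's features, so the stream is causal by
#' construction.
#'
#' @param model a fitted `csvm_model`/`rf_model` or a [painflex()] fit
#'   (its final model is used). The model must have been trained on
#'   trials disjoint from this one for an honest test.
#' @param trial_features feature-table rows of a single trial, ordered by
#'   window onset ([build_feature_table()] output).
#' @return A data frame of class `decision_stream`: `trial_id`, `end_s`,
#'   `score` (positive means pain), `raw_label`, `smoothed_label`
#'   (initially the raw label; see [smooth_decisions()]).
#' @export
predict_stream <- function(model, trial_features) {
  if (inherits(model, "painflex")) model <- model$final_model
  stopifnot(length(unique(trial_features$trial_id)) == 1L)
  if (is.unsorted(trial_features$end_s))
    stop("windows must be ordered in time")
  pr <- predict(model, trial_features)
  out <- data.frame(trial_id = trial_features$trial_id,
                    end_s = trial_features$end_s,
                    score = pr$score, raw_label = pr$label,
                    smoothed_label = pr$label)
  class(out) <- c("decision_stream", "data.frame")
  out
}

# Majority vote of a character label vector; ties go to painless (the
# conservative state, so a tied prefix never invents a detection).
majority_label <- function(labels) {
  if (sum(labels == "pain") > length(labels) / 2) "pain" else "painless"
}

#' Majority-vote smoothing of a decision stream
#'
#' Removes sporadic isolated false positives and negatives from the raw
#' label stream. The default causal mode replaces each label by the
#' majority over the last `width` raw labels (the first windows use the
#' available prefix), usable online; the centered mode uses a symmetric
#' window and is retrospective.
#'
#' @param stream a [predict_stream()] output.
#' @param width odd vote width (5 decisions at the default 125 ms step
#'   spans ~0.75 s of signal).
#' @param mode `"causal"` (default) or `"centered"`.
#' @return The stream with `smoothed_label` replaced.
#' @export
smooth_decisions <- function(stream, width = 5L, mode = c("causal",
                                                          "centered")) {
  mode <- match.arg(mode)
  if (width < 1L || width %% 2L == 0L) stop("`width` must be odd and >= 1")
  lab <- stream$raw_label
  n <- length(lab)
  half <- (width - 1L) %/% 2L
  stream$smoothed_label <- vapply(seq_len(n), function(i) {
    idx <- if (mode == "causal") max(1L, i - width + 1L):i
    else max(1L, i - half):min(n, i + half)
    majority_label(lab[idx])
  }, "")
  stream
}

#' First painless-to-pain transition of a stream
#'
#' @param stream a decision stream (smoothed labels are used).
#' @return End time (s) of the first window whose smoothed label is pain,
#'   or `NA` if the pain state is never decided.
#' @export
detect_transition <- function(stream) {
  i <- which(stream$smoothed_label == "pain")[1L]
  if (is.na(i)) NA_real_ else stream$end_s[i]
}

# Joint angle at an arbitrary time, linearly interpolated between samples.
angle_at <- function(trial, t) {
  tt <- trial$t_start + (seq_len(nrow(trial$signal)) - 1L) / trial$fs
  approx(tt, trial$angle, xout = t, rule = 2)$y
}

#' maxAP estimate from the first detected pain state
#'
#' Reads the joint angle at the first detected painless-to-pain
#' transition. A detection at or before the pain mark is `early` and carries the
#' signed bias `true_maxap - detected angle` (positive = early = the
#' safe-side under-shoot); a detection during the hold phase is `delayed`
#' and carries no bias (the robot already holds at the maxAP, so the angle
#' difference is zero by construction and not meaningful).
#'
#' @param stream a smoothed decision stream of the trial.
#' @param trial the matching [trial_segment()]; must carry an angle trace
#'   and `true_maxap`.
#' @return A list of class `maxap_estimate`: `trial_id`, `t_detect`,
#'   `detected_angle`, `true_maxap`, `bias`, `timing`
#'   (`early`/`delayed`/`none`).
#' @export
estimate_maxap <- function(stream, trial) {
  if (is.null(trial$angle) || is.null(trial$true_maxap))
    stop("maxAP estimation requires the trial's angle trace and true maxAP")
  t_det <- detect_transition(stream)
  if (is.na(t_det)) {
    return(structure(list(trial_id = trial$trial_id, t_detect = NA_real_,
                          detected_angle = NA_real_,
                          true_maxap = trial$true_maxap, bias = NA_real_,
                          timing = "none"),
                     class = "maxap_estimate"))
  }
  ang <- angle_at(trial, t_det)
  # a detection exactly at the pain mark reads the true maxAP (bias 0)
  # and is counted on the early (safe) side
  early <- t_det <= trial$t_pain
  structure(list(trial_id = trial$trial_id, t_detect = t_det,
                 detected_angle = ang, true_maxap = trial$true_maxap,
                 bias = if (early) trial$true_maxap - ang else NA_real_,
                 timing = if (early) "early" else "delayed"),
            class = "maxap_estimate")
}

#' @export
print.maxap_estimate <- function(x, ...) {
  cat(sprintf(
    "<maxap_estimate> trial %d: %s%s\n", x$trial_id, x$timing,
    switch(x$timing,
           early = sprintf(" at %.3f s, angle %.2f deg (bias %.2f deg)",
                           x$t_detect, x$detected_angle, x$bias),
           delayed = sprintf(" at %.3f s (hold phase)", x$t_detect),
           none = " (pain state never decided)")))
  invisible(x)
}

#' Cohort summary of maxAP estimation bias
#'
#' Per-subject mean bias over early-detection trials, the cohort mean and
#' sample standard deviation of those per-subject means, and the early
#' fraction `early / (early + delayed)` over all detected trials. An
#' inclusive mean (delayed trials entering with zero bias) is reported
#' alongside.
#'
#' @param estimates list of [estimate_maxap()] results.
#' @param subject vector assigning each estimate to a subject (defaults
#'   to one subject).
#' @return A list: `per_subject` (data frame), `mean_bias`, `sd_bias`,
#'   `mean_bias_inclusive`, `early_fraction`, `n_early`, `n_delayed`,
#'   `n_none`.
#' @export
bias_summary <- function(estimates, subject = NULL) {
  stopifnot(length(estimates) >= 1L)
  if (is.null(subject)) subject <- rep(1L, length(estimates))
  df <- data.frame(
    subject = subject,
    timing = vapply(estimates, function(e) e$timing, ""),
    bias = vapply(estimates, function(e) e$bias, 0))
  n_early <- sum(df$timing == "early")
  n_delayed <- sum(df$timing == "delayed")
  per <- do.call(rbind, lapply(split(df, df$subject), function(g) {
    data.frame(subject = g$subject[1L],
               mean_bias = if (any(g$timing == "early"))
                 mean(g$bias[g$timing == "early"]) else NA_real_,
               mean_bias_inclusive = if (any(g$timing != "none"))
                 mean(ifelse(g$timing == "early", g$bias, 0)) else NA_real_,
               n_early = sum(g$timing == "early"),
               n_delayed = sum(g$timing == "delayed"),
               n_none = sum(g$timing == "none"))
  }))
  rownames(per) <- NULL
  mb <- per$mean_bias[!is.na(per$mean_bias)]
  list(per_subject = per,
       mean_bias = mean(mb),
       sd_bias = if (length(mb) > 1L) sd(mb) else NA_real_,
       mean_bias_inclusive =
         mean(per$mean_bias_inclusive, na.rm = TRUE),
       early_fraction = if (n_early + n_delayed > 0)
         n_early / (n_early + n_delayed) else NA_real_,
       n_early = n_early, n_delayed = n_delayed,
       n_none = sum(df$timing == "none"))
}
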