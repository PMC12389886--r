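#' Sliding-window feature-extraction configuration
#'
#' Defaults follow common surface-EMG practice for pseudo-online pain-state
#' detection: 250 ms windows advanced in 125 ms steps, an amplitude guard
#' of 0.005 mV on the zero-crossing and slope-sign-change counts, sample
#' entropy with embedding dimension 2 and tolerance 0.2 x the per-window
#' standard deviation, and a 3-level db4 wavelet-packet decomposition.
#'
#' @param window_ms window length, ms.
#' @param step_ms step between window onsets, ms (must be < `window_ms`).
#' @param eps_mV amplitude threshold for ZC/SSC, mV.
#' @param sampen_m sample-entropy embedding dimension.
#' @param sampen_r_coeff sample-entropy tolerance as a multiple of the
#'   per-window standard deviation.
#' @param wpt_level wavelet-packet decomposition depth.
#' @param label_rule how a window straddling the pain mark is labeled:
#'   `"full"` (default) labels a window `pain` only when it lies entirely
#'   in the hold phase; `"end"` labels it `pain` as soon as its end time
#'   passes the mark. Both rules are causal.
#' @param eps_abs apply the `eps_mV` guard to absolute successive
#'   differences (the standard Hudgins reading, default) rather than to the
#'   signed differences.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_ms = 250, step_ms = 125, eps_mV = 0.005,
                           sampen_m = 2, sampen_r_coeff = 0.2,
                           wpt_level = 3, label_rule = c("full", "end"),
                           eps_abs = TRUE) {
  stopifnot(window_ms > step_ms, step_ms > 0, eps_mV >= 0, sampen_m >= 1,
            wpt_level >= 1)
  structure(list(window_ms = window_ms, step_ms = step_ms, eps_mV = eps_mV,
                 sampen_m = as.integer(sampen_m),
                 sampen_r_coeff = sampen_r_coeff,
                 wpt_level = as.integer(wpt_level),
                 label_rule = match.arg(label_rule),
                 eps_abs = isTRUE(eps_abs)),
            class = "feature_config")
}

#' Enumerate sliding analysis windows over a trial
#'
#' Windows start at offsets 0, step, 2*step, ... and the last window lies
#' fully inside the trial, giving `floor((L - N)/S) + 1` windows for a
#' trial of `L` samples, window of `N` and step of `S` samples.
#'
#' @param trial a [trial_segment()].
#' @param cfg a [feature_config()].
#' @return A data frame with one row per window: `onset` (1-based sample
#'   index into the trial), `onset_s`, `end_s` (recording clock), `phase`
#'   (trial phase at the window end) and `label` (`painless`/`pain` under
#'   `cfg$label_rule`).
#' @export
slide_windows <- function(trial, cfg = feature_config()) {
  fs <- trial$fs
  N <- round(cfg$window_ms * fs / 1000)
  S <- round(cfg$step_ms * fs / 1000)
  L <- nrow(trial$signal)
  if (L < N)
    stop("trial ", trial$trial_id, " shorter than one window (", L, " < ",
         N, " samples)")
  k <- 0:((L - N) %/% S)
  onset <- k * S
  onset_s <- trial$t_start + onset / fs
  end_s <- onset_s + N / fs
  label <- if (cfg$label_rule == "full") {
    ifelse(onset_s >= trial$t_pain, "pain", "painless")
  } else {
    ifelse(end_s > trial$t_pain, "pain", "painless")
  }
  data.frame(onset = onset + 1L, onset_s = onset_s, end_s = end_s,
             phase = ifelse(pmin(end_s, trial$t_end) < trial$t_pain,
                            "flexion", "hold"),
             label = label)
}

#' Time-domain amplitude features of one window
#'
#' Root mean square, mean absolute value, unbiased variance and waveform
#' length (the summed absolute successive differences).
#'
#' @param x numeric window samples (mV).
#' @return Named numeric vector `RMS`, `MAV`, `VAR`, `WL`.
#' @export
time_domain_features <- function(x) {
  stopifnot(length(x) >= 2L)
  c(RMS = sqrt(mean(x^2)),
    MAV = mean(abs(x)),
    VAR = var(x),
    WL = sum(abs(diff(x))))
}

#' Threshold-guarded zero-crossing and slope-sign-change counts
#'
#' ZC counts sign changes between consecutive samples whose step exceeds
#' the guard `eps`; SSC counts interior local extrema whose steps to both
#' neighbours exceed `eps`. By default the guard compares absolute
#' differences; `eps_abs = FALSE` applies it to the signed differences.
#'
#' @param x numeric window samples (mV).
#' @param eps amplitude guard in mV.
#' @param eps_abs guard on absolute (default) or signed differences.
#' @return Named integer vector `ZC`, `SSC`.
#' @export
threshold_counts <- function(x, eps = 0.005, eps_abs = TRUE) {
  n <- length(x)
  stopifnot(n >= 3L)
  d <- diff(x)                              # d[i] = x[i+1] - x[i]
  guard <- if (eps_abs) abs(d) > eps else -d > eps
  zc <- sum(x[-n] * x[-1L] < 0 & guard)
  back <- x[2:(n - 1L)] - x[1:(n - 2L)]     # x_i - x_{i-1}
  fwd <- x[2:(n - 1L)] - x[3:n]             # x_i - x_{i+1}
  g2 <- if (eps_abs) abs(fwd) > eps & abs(back) > eps else
    fwd > eps & back > eps
  ssc <- sum(fwd * back > 0 & g2)
  c(ZC = as.integer(zc), SSC = as.integer(ssc))
}

# One-sided raw periodogram of the unwindowed segment:
# P_j = |X_j|^2 at f_j = j fs/N, j = 1..N/2.
periodogram_onesided <- function(x, fs) {
  N <- length(x)
  X <- fft(x)
  j <- seq_len(N %/% 2L)
  list(f = j * fs / N, p = Mod(X[j + 1L])^2)
}

#' Mean and median frequency of one window
#'
#' Computed from the one-sided raw periodogram: MNF is the power-weighted
#' mean bin frequency; MDF is the smallest bin frequency at which the
#' cumulative power reaches half the total.
#'
#' @param x numeric window samples (mV).
#' @param fs sampling rate in Hz.
#' @return Named numeric vector `MNF`, `MDF` (Hz); both `NA` (flagged
#'   undefined) for an all-zero window.
#' @export
spectral_features <- function(x, fs) {
  stopifnot(length(x) >= 4L)
  pg <- periodogram_onesided(x, fs)
  tot <- sum(pg$p)
  if (tot == 0) return(c(MNF = NA_real_, MDF = NA_real_))
  mnf <- sum(pg$f * pg$p) / tot
  mdf <- pg$f[which(cumsum(pg$p) >= tot / 2)[1L]]
  c(MNF = mnf, MDF = mdf)
}

#' Wavelet-packet sub-band features of one window
#'
#' Decomposes the window with [wpt_decompose()] into `2^level` sub-bands
#' (frequency-ascending) and reports the RMS, unbiased variance and energy
#' (summed squared coefficients) of each sub-band's coefficient vector.
#'
#' @param x numeric window samples (mV).
#' @param cfg a [feature_config()] (only `wpt_level` is used).
#' @return Named numeric vector `WPTRMS_1..k`, `WPTVAR_1..k`,
#'   `WPTEnergy_1..k` with `k = 2^level`.
#' @export
wpt_features <- function(x, cfg = feature_config()) {
  nodes <- wpt_decompose(x, cfg$wpt_level)
  k <- length(nodes)
  rms <- vapply(nodes, function(v) sqrt(mean(v^2)), 0)
  vr <- vapply(nodes, var, 0)
  en <- vapply(nodes, function(v) sum(v^2), 0)
  stats::setNames(c(rms, vr, en),
                  c(paste0("WPTRMS_", seq_len(k)),
                    paste0("WPTVAR_", seq_len(k)),
                    paste0("WPTEnergy_", seq_len(k))))
}

#' Sample entropy of one window
#'
#' `SampEn(m, r, N) = -ln(B^{m+1}(r) / B^m(r))` where `B^m(r)` is the mean
#' fraction of template pairs of length `m` within Chebyshev distance `r`,
#' self-matches excluded. The tolerance is `r_coeff` times the window's
#' sample standard deviation. When no template pair matches at length
#' `m + 1` (or the tolerance is zero, as on a constant window) the
#' statistic is undefined;
#' the maximum resolvable value `-ln(2 / ((N - m - 1)(N - m)))` is
#' returned with attribute `capped = TRUE`.
#'
#' @param x numeric window samples (mV).
#' @param m embedding dimension.
#' @param r_coeff tolerance coefficient (multiple of `sd(x)`).
#' @return Sample entropy (scalar); attribute `capped` marks the
#'   degenerate no-match case.
#' @export
sample_entropy <- function(x, m = 2, r_coeff = 0.2) {
  N <- length(x)
  if (N <= m + 1L) stop("need N > m + 1 samples")
  r <- r_coeff * sd(x)
  cap <- -log(2 / ((N - m - 1) * (N - m)))
  if (r == 0) return(structure(cap, capped = TRUE))
  b <- sampen_match_means(x, as.integer(m), r)
  if (is.na(b[2L]) || b[1L] == 0 || b[2L] == 0)
    return(structure(cap, capped = TRUE))
  -log(b[2L] / b[1L])
}

# All 33 features of one channel window, in the contracted column order.
channel_features <- function(x, fs, cfg) {
  td <- time_domain_features(x)
  tc <- threshold_counts(x, cfg$eps_mV, cfg$eps_abs)
  sp <- spectral_features(x, fs)
  wp <- wpt_features(x, cfg)
  se <- as.numeric(sample_entropy(x, cfg$sampen_m, cfg$sampen_r_coeff))
  c(td, tc, sp, wp, SampEn = se)
}

#' Names of the per-channel feature columns
#'
#' @param cfg a [feature_config()].
#' @return Character vector of the 33 per-channel feature names (for the
#'   default 3-level decomposition).
#' @export
feature_names <- function(cfg = feature_config()) {
  k <- 2L^cfg$wpt_level
  c("RMS", "MAV", "VAR", "WL", "ZC", "SSC", "MNF", "MDF",
    paste0("WPTRMS_", seq_len(k)), paste0("WPTVAR_", seq_len(k)),
    paste0("WPTEnergy_", seq_len(k)), "SampEn")
}

#' Labeled sliding-window feature table for a set of trials
#'
#' Extracts the full per-channel feature set (33 features per channel, 132
#' over the four channels) for every sliding window of every trial.
#' Flexion-phase windows are labeled `painless` and hold-phase windows
#' `pain`, under the straddle rule of `cfg$label_rule`.
#'
#' @param trials a list of [trial_segment()] objects (or a single one).
#' @param cfg a [feature_config()].
#' @return A data frame with columns `trial_id`, `onset_s`, `end_s`,
#'   `label`, then one column per `<channel>_<feature>` (e.g. `MRF_RMS`,
#'   `MVM_WPTEnergy_3`), channels in MRF, MVM, MBF-CL, MS order. Channel
#'   names use `.` in place of `-` to keep the columns syntactic.
#' @export
build_feature_table <- function(trials, cfg = feature_config()) {
  if (inherits(trials, "trial_segment")) trials <- list(trials)
  rows <- lapply(trials, function(trial) {
    win <- slide_windows(trial, cfg)
    N <- round(cfg$window_ms * trial$fs / 1000)
    ch <- colnames(trial$signal)
    feats <- t(vapply(seq_len(nrow(win)), function(i) {
      idx <- win$onset[i]:(win$onset[i] + N - 1L)
      unlist(lapply(ch, function(cn)
        channel_features(trial$signal[idx, cn], trial$fs, cfg)))
    }, numeric(length(ch) * length(feature_names(cfg)))))
    colnames(feats) <- as.vector(t(outer(gsub("-", ".", ch),
                                         feature_names(cfg), paste, sep = "_")))
    cbind(data.frame(trial_id = trial$trial_id, onset_s = win$onset_s,
                     end_s = win$end_s, label = win$label), feats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Split a feature table into the metadata and the numeric feature matrix.
feature_matrix <- function(features) {
  meta <- c("trial_id", "onset_s", "end_s", "label", "subject")
  as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
}
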