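#' Synthetic mobility-training trial configuration
#'
#' Defaults emulate robot-assisted knee mobility training of a
#' post-fracture stiff joint: a slow linear flexion ramp to the maximum
#' angle position (maxAP) followed by a ~5 s hold, with four-channel
#' surface EMG whose amplitude envelope rises with the latent pain level
#' and plateaus during the hold. Extensor channels (MRF, MVM) respond
#' three times more strongly than flexors (MBF-CL, MS), and a fraction of
#' carrier power shifts from the high to the low frequency band as pain
#' rises, lowering the spectral centroid. The latent pain level is tied
#' deterministically to the joint angle:
#' `p(t) = 3 * clip((angle - onset) / (maxAP - onset), 0, 1)`,
#' reaching the clinical level 3 exactly at the maxAP.
#'
#' @param fs sampling rate, Hz.
#' @param n_trials trials per recording/subject.
#' @param flexion_s,hold_s phase durations, s.
#' @param start_angle,max_ap ramp endpoints, degrees.
#' @param pain_onset_angle angle at which pain starts to rise, degrees.
#' @param baseline_mV per-channel resting envelope, mV (MRF, MVM, MBF-CL,
#'   MS order).
#' @param pain_gain_mV per-channel envelope gain at full pain, mV.
#' @param gamma envelope exponent on the pain drive (slow early rise).
#' @param envelope_sat fraction of the pain rise at which the amplitude
#'   envelope reaches its plateau. Patients' muscle activation saturates
#'   shortly before the joint reaches the maxAP (the reaction precedes
#'   the verbal pain report), which is what makes early detection of the
#'   transition possible; 0.85 places the plateau ~4.5 degrees before the
#'   maxAP under the default angles.
#' @param spectral_shift fraction of carrier power moved from the
#'   150-450 Hz band to the 20-150 Hz band at full pain.
#' @param mains_mV amplitude of 50 Hz interference, mV.
#' @param trial_jitter_sd sd of the per-trial log-normal envelope jitter.
#' @param wobble_sd sd of the slow (<1 Hz) within-trial log-envelope
#'   wobble.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 2000, n_trials = 8L, flexion_s = 10,
                         hold_s = 5, start_angle = 10, max_ap = 70,
                         pain_onset_angle = 40,
                         baseline_mV = c(0.020, 0.020, 0.015, 0.015),
                         pain_gain_mV = c(0.060, 0.060, 0.020, 0.020),
                         gamma = 2, envelope_sat = 0.85,
                         spectral_shift = 0.2,
                         mains_mV = 0.005, trial_jitter_sd = 0.10,
                         wobble_sd = 0.05) {
  stopifnot(fs > 0, flexion_s > 0, hold_s > 0, max_ap > start_angle,
            all(pain_gain_mV >= 0), all(baseline_mV > 0),
            spectral_shift >= 0, spectral_shift <= 0.5,
            envelope_sat > 0, envelope_sat <= 1)
  structure(list(fs = fs, n_trials = as.integer(n_trials),
                 flexion_s = flexion_s, hold_s = hold_s,
                 start_angle = start_angle, max_ap = max_ap,
                 pain_onset_angle = pain_onset_angle,
                 baseline_mV = stats::setNames(baseline_mV, PF_CHANNELS),
                 pain_gain_mV = stats::setNames(pain_gain_mV, PF_CHANNELS),
                 gamma = gamma, envelope_sat = envelope_sat,
                 spectral_shift = spectral_shift,
                 mains_mV = mains_mV, trial_jitter_sd = trial_jitter_sd,
                 wobble_sd = wobble_sd),
            class = "synth_config")
}

#' Healthy-control generator profile
#'
#' Rescales a configuration to the healthy-subject control profile: pain
#' gains reduced to 10% of their value and the pain-coupled spectral
#' shift disabled, so no recoverable class signal remains beyond a weak
#' amplitude trend. All other fields are untouched.
#'
#' @param cfg a [synth_config()].
#' @return The modified configuration.
#' @export
healthy_mode <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  cfg$pain_gain_mV <- 0.1 * cfg$pain_gain_mV
  cfg$spectral_shift <- 0
  cfg
}

# Band-limited unit-variance Gaussian carrier. Extra pad samples absorb
# the filter transient.
band_carrier <- function(n, fs, low, high) {
  high <- min(high, 0.45 * fs)   # keep the band inside Nyquist at low fs
  pad <- round(0.25 * fs)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, rnorm(n + 2L * pad)))
  x <- x[(pad + 1L):(pad + n)]
  x / sd(x)
}

# Slow multiplicative envelope wobble: low-pass filtered log-normal.
slow_wobble <- function(n, fs, sd_log) {
  if (sd_log <= 0) return(rep(1, n))
  lp <- signal::butter(2, min(1 / (fs / 2), 0.99), type = "low")
  w <- signal::filtfilt(lp, rnorm(n))
  w <- w / max(sd(w), 1e-12) * sd_log
  exp(w)
}

#' Generate one synthetic mobility-training trial
#'
#' Fully determined by `(cfg, trial_seed)`: the joint angle ramps linearly
#' from `start_angle` to `max_ap` over the flexion phase and holds; the
#' latent pain level follows the angle; each EMG channel is a pain-weighted
#' mix of a 20-150 Hz and a 150-450 Hz Gaussian carrier scaled by the
#' envelope `baseline + gain * (p/3)^gamma`, plus 50 Hz interference.
#'
#' @param cfg a [synth_config()].
#' @param trial_seed integer seed.
#' @param trial_id trial identifier.
#' @return A [trial_segment()] with angle trace and `true_maxap`.
#' @export
synth_trial <- function(cfg, trial_seed = 1L, trial_id = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs
  n <- round((cfg$flexion_s + cfg$hold_s) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  angle <- ifelse(t < cfg$flexion_s,
                  cfg$start_angle + (cfg$max_ap - cfg$start_angle) *
                    t / cfg$flexion_s,
                  cfg$max_ap)
  p <- 3 * pmin(pmax((angle - cfg$pain_onset_angle) /
                       (cfg$max_ap - cfg$pain_onset_angle), 0), 1)
  w_low <- 0.5 * (1 + cfg$spectral_shift * p / 3)   # low-band power share
  sig <- with_seed(trial_seed, {
    vapply(PF_CHANNELS, function(ch) {
      c_lo <- band_carrier(n, fs, 20, 150)
      c_hi <- band_carrier(n, fs, 150, 450)
      carrier <- sqrt(w_low) * c_lo + sqrt(1 - w_low) * c_hi
      jit <- exp(rnorm(1L, 0, cfg$trial_jitter_sd))
      drive <- pmin((p / 3) / cfg$envelope_sat, 1)
      env <- (cfg$baseline_mV[ch] +
                cfg$pain_gain_mV[ch] * drive^cfg$gamma) * jit *
        slow_wobble(n, fs, cfg$wobble_sd)
      phase <- runif(1L, 0, 2 * pi)
      env * carrier + cfg$mains_mV * sin(2 * pi * 50 * t + phase)
    }, numeric(n))
  })
  colnames(sig) <- PF_CHANNELS
  trial_segment(sig, fs = fs, t_start = 0, t_pain = cfg$flexion_s,
                t_end = cfg$flexion_s + cfg$hold_s, trial_id = trial_id,
                angle = angle, true_maxap = cfg$max_ap)
}

#' Generate a synthetic multi-trial recording
#'
#' Concatenates `n_trials` seeded trials with 1 s of resting baseline
#' before, between and after them into a single [emg_recording()] with
#' the matching `(start, pain, end)` marker triples and joint-angle trace
#' — the same form real recordings are read into, so it exercises the
#' full preprocessing path.
#'
#' @param cfg a [synth_config()].
#' @param seed integer master seed.
#' @param n_trials number of trials (default `cfg$n_trials`).
#' @return An [emg_recording()].
#' @export
synth_recording <- function(cfg, seed = 1L, n_trials = cfg$n_trials) {
  fs <- cfg$fs
  seeds <- derive_seeds(seed, n_trials + 1L)
  gap <- round(1 * fs)
  rest <- function(k) with_seed(seeds[n_trials + 1L] + k, {
    r <- vapply(PF_CHANNELS, function(ch)
      cfg$baseline_mV[ch] * band_carrier(gap, fs, 20, 450), numeric(gap))
    colnames(r) <- PF_CHANNELS
    r
  })
  samples <- NULL; angle <- NULL
  markers <- data.frame(time_s = numeric(0), kind = character(0))
  for (k in seq_len(n_trials)) {
    tr <- synth_trial(cfg, seeds[k], trial_id = k)
    r <- rest(k)
    t0 <- (if (is.null(samples)) 0L else nrow(samples)) + gap
    samples <- rbind(samples, r, tr$signal)
    angle <- c(angle, rep(cfg$start_angle, gap), tr$angle)
    markers <- rbind(markers, data.frame(
      time_s = (t0 + c(0L, round(cfg$flexion_s * fs),
                       nrow(tr$signal) - 1L)) / fs,
      kind = c("start", "pain", "end")))
  }
  samples <- rbind(samples, rest(n_trials + 1L))
  angle <- c(angle, rep(cfg$start_angle, gap))
  emg_recording(samples, fs = fs, markers = markers, angle = angle)
}

#' Generate a synthetic cohort
#'
#' Per-subject trials with subject-level variability: a multiplicative
#' log-normal jitter (sd 0.15) on the pain gains and a uniform +/-5
#' degree jitter on the pain-onset angle, both drawn once per subject —
#' mimicking the robot's fixed preset angle, which makes the pain
#' threshold a subject property rather than a trial property.
#' Experiment-II-style cohorts have 8 trials per subject (robot, angle
#' trace); Experiment-I-style cohorts have 5 (therapist-administered).
#'
#' @param cfg a [synth_config()].
#' @param n_subjects number of subjects.
#' @param master_seed integer seed; the cohort is fully reproducible from
#'   it.
#' @param experiment `"II"` (default, 8 trials) or `"I"` (5 trials).
#' @param n_trials override the experiment-style trial count (used for
#'   scaled-down simulation studies).
#' @return A list of subjects, each a list with `subject`, `trials`
#'   (list of [trial_segment()]), and `truth` (the jittered gains and
#'   onset angle).
#' @export
synth_cohort <- function(cfg, n_subjects = 7L, master_seed = 42L,
                         experiment = c("II", "I"), n_trials = NULL) {
  stopifnot(n_subjects >= 1L)
  experiment <- match.arg(experiment)
  if (is.null(n_trials))
    n_trials <- if (experiment == "II") 8L else 5L
  sseeds <- derive_seeds(master_seed, n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    scfg <- cfg
    jit <- with_seed(sseeds[s], list(
      gain = exp(rnorm(length(PF_CHANNELS), 0, 0.15)),
      onset = runif(1L, -5, 5)))
    scfg$pain_gain_mV <- cfg$pain_gain_mV * jit$gain
    scfg$pain_onset_angle <- min(cfg$pain_onset_angle + jit$onset,
                                 cfg$max_ap - 5)
    tseeds <- derive_seeds(sseeds[s] + 1L, n_trials)
    trials <- lapply(seq_len(n_trials), function(k)
      synth_trial(scfg, tseeds[k], trial_id = k))
    list(subject = s, trials = trials,
         truth = list(pain_gain_mV = scfg$pain_gain_mV,
                      pain_onset_angle = scfg$pain_onset_angle))
  })
}

#' Labeled feature table for a synthetic cohort
#'
#' Convenience wrapper: optional zero-phase filtering, then
#' [build_feature_table()] per subject, with a `subject` column bound on.
#'
#' @param cohort a [synth_cohort()] result.
#' @param cfg a [feature_config()].
#' @param filter apply [bandpass_notch()] to each trial first.
#' @return A feature table with a `subject` column.
#' @export
cohort_features <- function(cohort, cfg = feature_config(),
                            filter = TRUE) {
  do.call(rbind, lapply(cohort, function(subj) {
    trials <- if (filter) lapply(subj$trials, bandpass_notch)
    else subj$trials
    ft <- build_feature_table(trials, cfg)
    cbind(subject = subj$subject, ft)
  }))
}
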