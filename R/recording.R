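#' Multi-channel surface EMG recording
#'
#' Container for a four-channel surface EMG recording acquired during knee
#' mobility training: the knee extensors MRF (rectus femoris) and MVM (vastus
#' medialis) and the flexors MBF-CL (biceps femoris caput longum) and MS
#' (semitendinosus). Each trial is delimited by three event markers: a
#' `start` mark at the beginning of flexion, a `pain` mark when the patient
#' reports pain level 3 (NRS) — the maximum angle position, maxAP — and an
#' `end` mark when extension begins.
#'
#' @param samples numeric matrix, one row per sample and one column per
#'   channel, in mV. Column names must be the four channel labels (any
#'   order; they are normalized to MRF, MVM, MBF-CL, MS).
#' @param fs sampling rate in Hz.
#' @param markers data frame with columns `time_s` (seconds, strictly
#'   increasing) and `kind` (repeating `start`, `pain`, `end` triples).
#' @param angle optional numeric vector of the knee joint angle in degrees,
#'   one value per sample row.
#' @return An object of class `emg_recording` with fields `samples`, `fs`,
#'   `channels`, `markers`, `angle`.
#' @seealso [read_recording()], [bandpass_notch()], [segment_trials()]
#' @export
emg_recording <- function(samples, fs, markers, angle = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(colnames(samples)))
    stop("`samples` must have channel names as column names")
  if (!setequal(colnames(samples), PF_CHANNELS)) {
    missing <- setdiff(PF_CHANNELS, colnames(samples))
    extra <- setdiff(colnames(samples), PF_CHANNELS)
    stop("channel mismatch: ",
         if (length(missing)) paste0("missing ", paste(missing, collapse = ", ")),
         if (length(missing) && length(extra)) "; ",
         if (length(extra)) paste0("unexpected ", paste(extra, collapse = ", ")))
  }
  samples <- samples[, PF_CHANNELS, drop = FALSE]
  markers <- validate_markers(markers)
  if (!is.null(angle)) {
    angle <- as.numeric(angle)
    if (length(angle) != nrow(samples))
      stop("`angle` must have exactly one value per sample (",
           length(angle), " vs ", nrow(samples), ")")
  }
  structure(
    list(samples = samples, fs = fs, channels = PF_CHANNELS,
         markers = markers, angle = angle),
    class = "emg_recording")
}

validate_markers <- function(markers) {
  markers <- as.data.frame(markers)
  if (!all(c("time_s", "kind") %in% names(markers)))
    stop("markers need columns `time_s` and `kind`")
  markers$time_s <- as.numeric(markers$time_s)
  markers$kind <- as.character(markers$kind)
  if (nrow(markers) && any(diff(markers$time_s) <= 0))
    stop("marker times must be strictly increasing")
  bad <- setdiff(markers$kind, c("start", "pain", "end"))
  if (length(bad))
    stop("unknown marker kind: ", paste(unique(bad), collapse = ", "))
  markers[, c("time_s", "kind")]
}

#' @export
print.emg_recording <- function(x, ...) {
  dur <- nrow(x$samples) / x$fs
  cat(sprintf("<emg_recording> %d channels x %d samples (%.2f s at %g Hz)\n",
              ncol(x$samples), nrow(x$samples), dur, x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  markers:  %d (%d complete trials)%s\n",
              nrow(x$markers), nrow(x$markers) %/% 3L,
              if (is.null(x$angle)) "" else "; joint-angle trace present"))
  invisible(x)
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read an EMG recording from delimited text files
#'
#' The signal file has one header row naming the channels and one row per
#' sample (mV); the marker file has columns `time_s,kind`; the optional
#' angle file has a single `angle_deg` column aligned sample-by-sample with
#' the signal. Comma- and tab-separated files are both accepted.
#'
#' @param signal_path path to the signal file.
#' @param marker_path path to the marker file.
#' @param angle_path optional path to the joint-angle file (degrees).
#' @param fs sampling rate in Hz (2000 for the acquisition system emulated
#'   here).
#' @return An [emg_recording()].
#' @export
read_recording <- function(signal_path, marker_path, angle_path = NULL,
                           fs = 2000) {
  sig <- read.csv(signal_path, sep = detect_sep(signal_path),
                  check.names = FALSE)
  markers <- read.csv(marker_path, sep = detect_sep(marker_path))
  angle <- NULL
  if (!is.null(angle_path))
    angle <- read.csv(angle_path, sep = detect_sep(angle_path))[[1L]]
  emg_recording(as.matrix(sig), fs = fs, markers = markers, angle = angle)
}

#' Write an EMG recording to delimited text files
#'
#' Inverse of [read_recording()]: markers round-trip exactly, samples to
#' text precision.
#'
#' @param rec an [emg_recording()].
#' @param signal_path,marker_path,angle_path output paths; `angle_path` is
#'   required when the recording carries an angle trace.
#' @return `rec`, invisibly.
#' @export
write_recording <- function(rec, signal_path, marker_path,
                            angle_path = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  write.csv(as.data.frame(rec$samples), signal_path, row.names = FALSE)
  write.csv(rec$markers, marker_path, row.names = FALSE)
  if (!is.null(rec$angle)) {
    if (is.null(angle_path))
      stop("recording has an angle trace; `angle_path` is required")
    write.csv(data.frame(angle_deg = rec$angle), angle_path,
              row.names = FALSE)
  }
  invisible(rec)
}

# Second-order IIR notch (biquad), centred at f0 with quality factor Q.
notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase band-pass and mains-notch filtering
#'
#' Band-pass Butterworth filter (default 20-450 Hz, 4th order) cascaded
#' with a 2nd-order IIR notch at the mains frequency (default 50 Hz,
#' Q = 30), both applied forward-backward so the output has no group delay
#' relative to the event markers.
#'
#' @param rec an [emg_recording()] or [trial_segment] (anything with
#'   `samples`/`signal` and `fs`).
#' @param low_hz,high_hz band-pass corner frequencies in Hz.
#' @param notch_hz notch centre frequency in Hz.
#' @param order band-pass filter order (must be even; `order/2` is passed
#'   to the low/high prototype so the cascade has the stated order).
#' @param notch_q notch quality factor.
#' @return An object of the same class with filtered samples.
#' @export
bandpass_notch <- function(rec, low_hz = 20, high_hz = 450, notch_hz = 50,
                           order = 4, notch_q = 30) {
  fs <- rec$fs
  if (fs <= 2 * high_hz)
    stop("sampling rate ", fs, " Hz too low for an upper corner at ",
         high_hz, " Hz")
  if (order %% 2 != 0) stop("`order` must be even")
  x <- if (inherits(rec, "emg_recording")) rec$samples else rec$signal
  if (nrow(x) < 6L * (order + 1L))
    stop("signal too short (", nrow(x), " samples) for the filter transient")
  bp <- signal::butter(order / 2, c(low_hz, high_hz) / (fs / 2),
                       type = "pass")
  nt <- notch_coefs(notch_hz, fs, notch_q)
  y <- apply(x, 2L, function(col) {
    col <- signal::filtfilt(bp, col)
    signal::filtfilt(signal::Arma(b = nt$b, a = nt$a), col)
  })
  colnames(y) <- colnames(x)
  if (inherits(rec, "emg_recording")) rec$samples <- y else rec$signal <- y
  rec
}

# Nearest-sample index (0-based) for a time in seconds; ties round down.
snap_sample <- function(t, fs) as.integer(ceiling(t * fs - 0.5))

#' One mobility-training trial
#'
#' A slice of a recording from a `start` to an `end` marker, with the
#' `pain` marker separating the joint flexion phase (painless) from the
#' joint hold phase (pain level 3).
#'
#' @param signal numeric matrix (samples x channels, mV).
#' @param fs sampling rate in Hz.
#' @param t_start,t_pain,t_end marker times in seconds (recording clock).
#' @param trial_id integer trial identifier.
#' @param angle optional per-sample joint angle slice, degrees.
#' @param true_maxap optional true maximum angle position, degrees (the
#'   angle at `t_pain`).
#' @return An object of class `trial_segment`.
#' @export
trial_segment <- function(signal, fs, t_start, t_pain, t_end, trial_id = 1L,
                          angle = NULL, true_maxap = NULL) {
  if (!(t_start < t_pain && t_pain < t_end))
    stop("markers must satisfy t_start < t_pain < t_end")
  signal <- as.matrix(signal)
  if (!is.null(angle) && length(angle) != nrow(signal))
    stop("angle slice length mismatch")
  structure(
    list(signal = signal, fs = fs, trial_id = as.integer(trial_id),
         t_start = t_start, t_pain = t_pain, t_end = t_end,
         angle = angle, true_maxap = true_maxap),
    class = "trial_segment")
}

#' @export
print.trial_segment <- function(x, ...) {
  cat(sprintf(
    "<trial_segment> trial %d: %.2f s flexion + %.2f s hold (%d samples)%s\n",
    x$trial_id, x$t_pain - x$t_start, x$t_end - x$t_pain, nrow(x$signal),
    if (is.null(x$true_maxap)) ""
    else sprintf(", true maxAP %.1f deg", x$true_maxap)))
  invisible(x)
}

#' Trial phase at a time point
#'
#' `flexion` for `t_start <= t < t_pain`, `hold` for
#' `t_pain <= t <= t_end`.
#'
#' @param trial a [trial_segment()].
#' @param t time(s) in seconds on the recording clock.
#' @return character vector of phases.
#' @export
phase_of <- function(trial, t) {
  if (any(t < trial$t_start | t > trial$t_end))
    stop("time outside the trial")
  ifelse(t < trial$t_pain, "flexion", "hold")
}

#' Split a recording into its marked trials
#'
#' Groups the markers into `(start, pain, end)` triples and cuts one
#' [trial_segment()] per triple; samples outside any trial are discarded.
#' When the recording carries a joint-angle trace, each trial keeps its
#' angle slice and `true_maxap` is the angle at the pain mark.
#'
#' @param rec an [emg_recording()].
#' @return A list of [trial_segment()] objects.
#' @export
segment_trials <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  m <- rec$markers
  if (nrow(m) %% 3L != 0L)
    stop("incomplete final marker triple; dangling markers: ",
         paste(sprintf("%s@%.3fs", m$kind, m$time_s)[
           (3L * (nrow(m) %/% 3L) + 1L):nrow(m)], collapse = ", "))
  n_tr <- nrow(m) %/% 3L
  lapply(seq_len(n_tr), function(k) {
    tri <- m[(3L * k - 2L):(3L * k), ]
    if (!identical(tri$kind, c("start", "pain", "end")))
      stop("trial ", k, ": marker kinds are (",
           paste(tri$kind, collapse = ", "),
           "), expected (start, pain, end)")
    i0 <- snap_sample(tri$time_s[1], rec$fs)
    i2 <- snap_sample(tri$time_s[3], rec$fs)
    if (i0 < 0L || i2 >= nrow(rec$samples))
      stop("trial ", k, " extends outside the recording")
    idx <- (i0:i2) + 1L
    angle <- if (!is.null(rec$angle)) rec$angle[idx]
    tm <- if (!is.null(rec$angle))
      rec$angle[snap_sample(tri$time_s[2], rec$fs) + 1L]
    trial_segment(rec$samples[idx, , drop = FALSE], fs = rec$fs,
                  t_start = tri$time_s[1], t_pain = tri$time_s[2],
                  t_end = tri$time_s[3], trial_id = k,
                  angle = angle, true_maxap = tm)
  })
}
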