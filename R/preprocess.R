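#' Cut event-locked epochs from a continuous recording
#'
#' Trial `t` starts at `event_t + window[1]` seconds; each trial has
#' exactly `(window[2] - window[1]) * sampling_rate` samples, so a -3..0 s
#' window at 1000 Hz yields 3000 samples.
#'
#' @param recording An `eeg_recording` with events.
#' @param window `c(start_s, end_s)` relative to the event, start < end.
#' @return An `epoch_tensor`: trials x channels x samples array with
#'   attributes `window`, `sampling_rate`, `channel_labels`, `trial_ids`,
#'   `subject_id`, `condition`, `band`.
#' @export
epoch_recording <- function(recording, window = c(-3, 0)) {
  stopifnot(inherits(recording, "eeg_recording"), length(window) == 2)
  if (window[2] <= window[1])
    stop("empty epoch window: end must exceed start")
  if (!length(recording$events)) stop("recording has no events to epoch")
  fs <- recording$sampling_rate
  len <- round((window[2] - window[1]) * fs)
  start <- recording$events + round(window[1] * fs)
  bad <- which(start < 1 | start + len - 1 > ncol(recording$samples))
  if (length(bad))
    stop("epoch window overruns recording bounds for events: ",
         paste(bad, collapse = ", "))
  n_tr <- length(recording$events)
  n_ch <- nrow(recording$samples)
  out <- array(0, dim = c(n_tr, n_ch, len))
  for (t in seq_len(n_tr))
    out[t, , ] <- recording$samples[, start[t]:(start[t] + len - 1)]
  structure(out, class = "epoch_tensor", window = window,
            sampling_rate = fs, channel_labels = recording$channel_labels,
            trial_ids = seq_len(n_tr), subject_id = recording$subject_id,
            condition = recording$condition, band = recording$band)
}

#' Reject trials by peak-to-peak amplitude
#'
#' Drops every trial whose maximum per-channel peak-to-peak amplitude
#' exceeds the threshold -- a deterministic surrogate for manual or
#' ICA-based artifact cleaning.
#'
#' @param epochs An `epoch_tensor`.
#' @param threshold Peak-to-peak threshold in microvolts, > 0.
#' @return The retained `epoch_tensor`; attribute `rejection` holds the
#'   removed trial ids and the removal rate.
#' @export
reject_artifacts <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  if (threshold <= 0) stop("threshold must be positive")
  d <- dim(epochs)
  p2p <- vapply(seq_len(d[1]), function(t) {
    m <- matrix(epochs[t, , ], d[2], d[3])
    max(apply(m, 1, function(v) diff(range(v))))
  }, numeric(1))
  keep <- which(p2p <= threshold)
  if (!length(keep))
    stop("all ", d[1], " trials exceed the ", threshold,
         " uV peak-to-peak threshold; review the threshold")
  removed <- setdiff(seq_len(d[1]), keep)
  out <- epochs[keep, , , drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(epochs)[setdiff(names(attributes(epochs)),
                                                  c("dim", "trial_ids"))])
  attr(out, "trial_ids") <- attr(epochs, "trial_ids")[keep]
  attr(out, "rejection") <- list(removed = attr(epochs, "trial_ids")[removed],
                                 n_total = d[1],
                                 removal_rate = length(removed) / d[1])
  out
}

# restrict an epoch tensor to the given trial ids (keeping attributes)
subset_trials <- function(epochs, trial_ids) {
  sel <- match(trial_ids, attr(epochs, "trial_ids"))
  if (anyNA(sel)) stop("unknown trial ids")
  out <- epochs[sel, , , drop = FALSE]
  attributes(out) <- c(attributes(out),
                       attributes(epochs)[setdiff(names(attributes(epochs)),
                                                  c("dim", "trial_ids"))])
  attr(out, "trial_ids") <- trial_ids
  out
}

# Welch power spectral density: Hann-tapered segments, 50% overlap.
# seg_length sets the frequency resolution fs / seg_length.
welch_psd <- function(x, sampling_rate, seg_seconds = 2, overlap = 0.5) {
  n <- length(x)
  seg <- round(seg_seconds * sampling_rate)
  if (n < seg) stop("signal shorter than one spectral segment (",
                    seg_seconds, " s)")
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  scale <- sum(w^2) * sampling_rate
  nf <- seg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg_x <- x[s:(s + seg - 1)] * w
    p <- Mod(stats::fft(seg_x))^2 / scale
    acc <- acc + p[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1) * sampling_rate / seg,
       power = acc / length(starts))
}

#' Estimate the individual alpha frequency (IAF)
#'
#' Welch spectra (2 s Hann segments, 50% overlap, hence a 0.5 Hz grid) of
#' the eyes-closed occipital channels are averaged and the 8-12 Hz power
#' peak taken as the IAF. Ties break to the lowest frequency. When the
#' maximum is not a strict local peak inside the open interval (flat
#' spectrum, or a boundary argmax), the grid argmax is still returned but
#' the estimate is flagged with a warning.
#'
#' @param resting An `eeg_recording` with a `resting_segments$eyes_closed`
#'   range (the whole recording is used when absent).
#' @param channels Channels averaged for the spectrum.
#' @param resolution Frequency grid step in Hz.
#' @param range Search interval in Hz.
#' @return An `iaf_estimate`: list with `iaf`, `spectrum` (data frame),
#'   `channels_used`, `fallback` flag.
#' @export
estimate_iaf <- function(resting, channels = c("O1", "O2", "Oz"),
                         resolution = 0.5, range = c(8, 12)) {
  stopifnot(inherits(resting, "eeg_recording"))
  idx <- match(channels, resting$channel_labels)
  if (anyNA(idx))
    stop("channels absent from recording: ",
         paste(channels[is.na(idx)], collapse = ", "))
  seg <- resting$resting_segments$eyes_closed %||%
    c(1L, ncol(resting$samples))
  if ((seg[2] - seg[1] + 1) < 2 / resolution * resting$sampling_rate)
    stop("eyes-closed segment shorter than one ", 1 / resolution * 2,
         " s spectral window")
  pw <- NULL
  for (ch in idx) {
    p <- welch_psd(resting$samples[ch, seg[1]:seg[2]], resting$sampling_rate,
                   seg_seconds = 1 / resolution)
    pw <- if (is.null(pw)) p$power else pw + p$power
  }
  freq <- welch_psd(resting$samples[idx[1], seg[1]:seg[2]],
                    resting$sampling_rate, seg_seconds = 1 / resolution)$freq
  pw <- pw / length(idx)
  sel <- which(freq >= range[1] & freq <= range[2])
  pk <- sel[which.max(pw[sel])]               # which.max takes the first tie
  interior <- pk > 1 && pk < length(pw) &&
    pw[pk] > pw[pk - 1] && pw[pk] > pw[pk + 1] &&
    freq[pk] > range[1] && freq[pk] < range[2]
  fallback <- !interior
  if (fallback)
    warning("no strict spectral peak inside (", range[1], ", ", range[2],
            ") Hz; returning the grid argmax")
  structure(list(iaf = freq[pk],
                 spectrum = data.frame(freq = freq[sel], power = pw[sel]),
                 channels_used = channels, fallback = fallback),
            class = "iaf_estimate")
}

#' IAF-anchored frequency band definitions
#'
#' Theta is `[IAF-6, IAF-3]`, alpha `[IAF-2, IAF+2]`, beta `[IAF+3, 30]`
#' Hz; 30 Hz is the conventional beta ceiling consistent with the
#' acquisition low-pass.
#'
#' @param iaf IAF in Hz (numeric or an `iaf_estimate`), in \[8, 12\].
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
bands_from_iaf <- function(iaf) {
  if (inherits(iaf, "iaf_estimate")) iaf <- iaf$iaf
  stopifnot(is.numeric(iaf), iaf >= 8, iaf <= 12)
  list(theta = c(iaf - 6, iaf - 3),
       alpha = c(iaf - 2, iaf + 2),
       beta = c(iaf + 3, 30))
}

#' Trial-accounting arithmetic for a cohort design
#'
#' Relates a surviving-trial count to the designed total
#' (`subjects x conditions x shots`): the percentage of trials removed and
#' the average retained per recording (subject-condition).
#'
#' @param retained Number of trials surviving artifact rejection.
#' @param n_subjects,n_conditions,shots_per_condition Design counts.
#' @return List with `designed`, `retained`, `removal_rate_pct`,
#'   `mean_trials_per_recording`.
#' @export
design_trial_summary <- function(retained, n_subjects = 30,
                                 n_conditions = 3,
                                 shots_per_condition = 60) {
  designed <- n_subjects * n_conditions * shots_per_condition
  stopifnot(retained >= 0, retained <= designed)
  list(designed = designed, retained = retained,
       removal_rate_pct = 100 * (designed - retained) / designed,
       mean_trials_per_recording = retained / (n_subjects * n_conditions))
}
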