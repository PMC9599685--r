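#' Construct a continuous EEG recording object
#'
#' @param samples Channels x time numeric matrix, microvolts.
#' @param sampling_rate Hz.
#' @param channel_labels Channel names, one per row of `samples`.
#' @param events Integer sample indices of shot instants (may be empty).
#' @param subject_id,condition Labels.
#' @param resting_segments Optional named list of `c(start, end)` sample
#'   ranges (`eyes_closed`, `eyes_open`).
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels,
                          events = integer(0), subject_id = NA,
                          condition = NA, resting_segments = NULL) {
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_labels))
  events <- as.integer(events)
  if (length(events)) {
    lo <- 5 * sampling_rate
    hi <- ncol(samples) - 2 * sampling_rate
    if (any(events < lo) || any(events > hi))
      stop("events must lie at least 5 s after recording start and 2 s ",
           "before its end so the -5..+2 s window always fits")
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, events = events,
                 subject_id = subject_id, condition = condition,
                 resting_segments = resting_segments, band = NULL),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, condition %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$condition, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, length(x$events)))
  invisible(x)
}

# 1/f^alpha Gaussian noise, one column per channel, each column scaled to sd
colored_noise <- function(n, n_channels, alpha, sd_uv) {
  w <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  if (alpha > 0) {
    nfft <- stats::nextn(n, 2)
    wf <- stats::mvfft(rbind(w, matrix(0, nfft - n, n_channels)))
    k <- c(0, seq_len(nfft - 1))
    k <- pmin(k, nfft - k)                       # two-sided frequency index
    g <- c(0, k[-1]^(-alpha / 2))                # kill DC, shape 1/f^(a/2)
    w <- Re(stats::mvfft(wf * g, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
  }
  sds <- apply(w, 2, stats::sd)
  sweep(w, 2, sds / sd_uv, "/")
}

# unit-variance band-limited Gaussian noise (ideal FFT mask)
narrowband_source <- function(n, low, high, sampling_rate) {
  nfft <- stats::nextn(n, 2)
  e <- stats::fft(c(stats::rnorm(n), rep(0, nfft - n)))
  freq <- pmin(0:(nfft - 1), nfft - (0:(nfft - 1))) * sampling_rate / nfft
  e[freq < low | freq > high] <- 0
  s <- Re(stats::fft(e, inverse = TRUE))[seq_len(n)] / nfft
  s / stats::sd(s)
}

# expected ring score of round-then-clip discretization of N(mu, sd):
# rounded values below 5 count as misses (0), above 10 clip to 10
expected_ring_score <- function(mu, sd) {
  r <- 5:9
  sum(r * (stats::pnorm(r + 0.5, mu, sd) - stats::pnorm(r - 0.5, mu, sd))) +
    10 * stats::pnorm(9.5, mu, sd, lower.tail = FALSE)
}

# latent normal mean whose discretized expectation equals the target mean;
# inverts the miss-rule bias so realized ring averages match configuration
latent_score_mean <- function(target, sd) {
  target <- min(max(target, 0.05), 9.9)
  stats::uniroot(function(m) expected_ring_score(m, sd) - target,
                 lower = -10, upper = 25, tol = 1e-8)$root
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Simulate one subject (all conditions, resting EEG, scores)
#'
#' Draws the subject's true IAF (snapped to the 0.5 Hz analysis grid), a
#' latent coupling level shared across planted couplings, and per-channel
#' common-source gains; then builds one continuous recording per condition
#' (1/f background + zero-lag common source + delayed narrow-band coupled
#' oscillators), a resting recording whose eyes-closed segment carries an
#' occipital alpha peak at the true IAF, and per-condition ring scores tied
#' to the latent coupling level by a Gaussian copula.
#'
#' @param config A [sim_config()].
#' @param subject_index 1-based subject number, `<= config$n_subjects`.
#' @return List with elements `recordings` (named by condition), `resting`,
#'   `performance` (named list of score records) and `truth` (IAF, latent,
#'   per-condition coupling strengths, subject-level score means).
#' @export
simulate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "sim_config"),
            subject_index >= 1, subject_index <= config$n_subjects)
  fs <- config$sampling_rate
  k <- config$shots_per_condition
  perf <- config$performance

  set.seed(subject_seed(config, subject_index, salt = 0L))
  iaf_true <- round(2 * stats::rnorm(1, config$iaf_mean, config$iaf_sd)) / 2
  iaf_true <- min(max(iaf_true, 8), 12)
  u <- stats::rnorm(1)                        # latent coupling level
  cs_gain <- stats::runif(length(config$channel_labels), 0.5, 1.5) *
    config$common_source_gain
  bands <- bands_from_iaf(iaf_true)

  base_strength <- vapply(config$couplings, function(cp) {
    min(max(cp$strength + config$coupling_subject_sd * u, 0.02),
        1 - abs(cp$effect_delta))
  }, numeric(1))

  # resting recording: background + eyes-closed occipital alpha at the IAF
  n_rest <- round(2 * config$rest_duration * fs)
  n_ec <- round(config$rest_duration * fs)
  set.seed(subject_seed(config, subject_index, salt = 1L))
  rest <- t(colored_noise(n_rest, length(config$channel_labels),
                          config$noise_color, config$background_sd))
  occ <- match(c("O1", "Oz", "O2"), config$channel_labels)
  occ <- occ[!is.na(occ)]
  for (ch in occ) {
    osc <- narrowband_source(n_ec, iaf_true - 0.6, iaf_true + 0.6, fs)
    rest[ch, seq_len(n_ec)] <- rest[ch, seq_len(n_ec)] +
      config$alpha_amplitude * osc
  }
  resting <- eeg_recording(rest, fs, config$channel_labels,
                           subject_id = subject_index, condition = "resting",
                           resting_segments = list(
                             eyes_closed = c(1L, n_ec),
                             eyes_open = c(n_ec + 1L, n_rest)))

  lead_in <- 6
  event_s <- lead_in + (seq_len(k) - 1) * config$shot_interval
  n <- ceiling((event_s[k] + 3) * fs)
  events <- as.integer(round(event_s * fs))

  recordings <- list()
  performance <- list()
  truth_strength <- list()
  score_mean_true <- numeric(0)
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    set.seed(subject_seed(config, subject_index, salt = 10L + ci))
    x <- t(colored_noise(n, length(config$channel_labels),
                         config$noise_color, config$background_sd))
    if (config$common_source_gain > 0) {
      z <- colored_noise(n, 1, config$noise_color, config$background_sd)[, 1]
      x <- x + outer(cs_gain, z)    # zero lag in every channel
    }
    strengths <- base_strength
    for (j in seq_along(config$couplings)) {
      cp <- config$couplings[[j]]
      if (!is.na(cp$condition_effect) && cp$condition_effect == cond)
        strengths[j] <- min(strengths[j] + cp$effect_delta, 1)
      if (strengths[j] <= 0) next
      band <- bands[[cp$band]]
      f0 <- mean(band)
      s <- narrowband_source(n, band[1], band[2], fs)
      delay <- round(cp$phase_lag / (2 * pi * f0) * fs)
      amp <- config$coupling_gain * strengths[j]
      ia <- match(cp$chan_a, config$channel_labels)
      ib <- match(cp$chan_b, config$channel_labels)
      x[ia, ] <- x[ia, ] + amp * s
      x[ib, ] <- x[ib, ] + amp * circular_shift(s, delay)
    }
    recordings[[cond]] <- eeg_recording(x, fs, config$channel_labels,
                                        events = events,
                                        subject_id = subject_index,
                                        condition = cond)
    truth_strength[[cond]] <- strengths

    # ring scores: subject-level mean follows a Gaussian copula on u
    set.seed(subject_seed(config, subject_index, salt = 100L + ci))
    mu <- perf$score_mean[[cond]] + perf$score_sd[[cond]] *
      (perf$rho * u + sqrt(1 - perf$rho^2) * stats::rnorm(1))
    raw <- round(stats::rnorm(k, latent_score_mean(mu, perf$shot_sd),
                              perf$shot_sd))
    raw[raw < 5] <- 0L
    raw[raw > 10] <- 10L
    performance[[cond]] <- list(subject_id = subject_index,
                                condition = cond,
                                ring_scores = as.integer(raw),
                                mean_score = mean(raw))
    score_mean_true[cond] <- mu
  }

  list(recordings = recordings, resting = resting, performance = performance,
       truth = list(iaf = iaf_true, latent = u,
                    coupling_strength = truth_strength,
                    common_source_gain = cs_gain,
                    score_mean = score_mean_true))
}

#' Inject detectable artifact transients into flagged trials
#'
#' Each event's trial (aiming window) is contaminated independently with
#' probability `rate` by adding a 200 ms Hann-windowed transient of the
#' given peak amplitude on one random channel, leaving all other trials
#' untouched.
#'
#' @param recording An `eeg_recording` with events.
#' @param rate Contamination probability per trial, in \[0, 1\].
#' @param amplitude Transient peak amplitude in microvolts (non-negative).
#' @param seed RNG seed for trial selection and placement.
#' @param window Aiming window (seconds relative to event) inside which the
#'   transient is placed.
#' @return List with `recording` (modified) and `contaminated` (trial ids).
#' @export
inject_artifacts <- function(recording, rate, amplitude = 500, seed = 1L,
                             window = c(-3, 0)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (amplitude < 0) stop("artifact amplitude must be non-negative")
  n_ev <- length(recording$events)
  if (rate == 0 || n_ev == 0)
    return(list(recording = recording, contaminated = integer(0)))
  fs <- recording$sampling_rate
  set.seed(as.integer(seed) %% 2147483647L)
  flagged <- which(stats::runif(n_ev) < rate)
  dur <- round(0.2 * fs)
  bump <- amplitude * (0.5 - 0.5 * cos(2 * pi * seq_len(dur) / (dur + 1)))
  for (t in flagged) {
    ch <- sample.int(nrow(recording$samples), 1)
    lo <- recording$events[t] + round(window[1] * fs)
    hi <- recording$events[t] + round(window[2] * fs) - dur
    at <- if (hi > lo) sample(lo:hi, 1) else lo
    idx <- at:(at + dur - 1)
    recording$samples[ch, idx] <- recording$samples[ch, idx] + bump
  }
  list(recording = recording, contaminated = flagged)
}

#' Simulate a full cohort, optionally writing it to disk
#'
#' Runs [simulate_subject()] for every subject, applies
#' [inject_artifacts()] at the configured rate, and assembles a
#' ground-truth manifest (true IAFs, per-condition coupling strengths,
#' latent coupling levels, contaminated trial ids, planted performance
#' correlation). With `out_dir` set, writes one signal CSV (channels x
#' samples) and one events TSV per subject/condition, a scores CSV, and the
#' manifest as JSON.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return An `eeg_cohort`: list of `subjects`, `manifest`, `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  subjects <- vector("list", config$n_subjects)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    subj <- simulate_subject(config, s)
    subj <- apply_artifacts_subject(subj, config)
    for (cond in config$conditions) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = cond, iaf = subj$truth$iaf,
        latent = subj$truth$latent,
        mean_score = subj$performance[[cond]]$mean_score,
        n_contaminated = length(subj$truth$contaminated[[cond]]))
    }
    subjects[[s]] <- subj
    if (!is.null(out_dir)) write_subject(subj, config, out_dir)
  }
  manifest <- list(summary = do.call(rbind, rows),
                   performance_rho = config$performance$rho,
                   couplings = config$couplings,
                   seed = config$seed)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(summary = manifest$summary, performance_rho = manifest$performance_rho,
           seed = manifest$seed),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(subjects = subjects, manifest = manifest, config = config),
            class = "eeg_cohort")
}

#' Read one written recording back from disk
#'
#' Counterpart of the files produced by [simulate_cohort()]: reads the
#' channels x samples signal CSV and its events TSV into an
#' `eeg_recording`.
#'
#' @param dir Cohort directory.
#' @param subject Subject number.
#' @param condition Condition label.
#' @param sampling_rate Sampling rate of the stored signal, Hz.
#' @param channel_labels Channel labels for the rows of the signal matrix.
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(dir, subject, condition, sampling_rate,
                               channel_labels = montage_channels()) {
  stem <- file.path(dir, sprintf("sub-%02d_%s", subject, condition))
  sig <- paste0(stem, "_eeg.csv")
  if (!file.exists(sig)) stop("no recording at ", sig)
  samples <- as.matrix(data.table::fread(sig))
  dimnames(samples) <- NULL
  ev <- data.table::fread(paste0(stem, "_events.tsv"), sep = "\t")
  eeg_recording(samples, sampling_rate, channel_labels,
                events = ev$onset_sample, subject_id = subject,
                condition = condition)
}

write_subject <- function(subj, config, out_dir) {
  for (cond in names(subj$recordings)) {
    rec <- subj$recordings[[cond]]
    stem <- file.path(out_dir, sprintf("sub-%02d_%s", rec$subject_id, cond))
    data.table::fwrite(data.table::as.data.table(rec$samples),
                       paste0(stem, "_eeg.csv"))
    ev <- data.frame(onset_sample = rec$events,
                     onset_seconds = rec$events / rec$sampling_rate,
                     label = "shot")
    data.table::fwrite(ev, paste0(stem, "_events.tsv"), sep = "\t")
    perf <- subj$performance[[cond]]
    data.table::fwrite(data.frame(shot = seq_along(perf$ring_scores),
                                  ring_score = perf$ring_scores),
                       paste0(stem, "_scores.csv"))
  }
  invisible(NULL)
}
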