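#' Specify one planted phase-lagged coupling
#'
#' A coupling injects a shared narrow-band oscillator into a channel pair,
#' with the copy in `chan_b` delayed by `phase_lag / (2 * pi * f0)` seconds
#' (`f0` = band centre). Its band edges are resolved per subject from the
#' subject's individual alpha frequency, so "beta" means the subject's own
#' beta band. `condition_effect` adds `effect_delta` to the coupling
#' strength in one named condition, planting a group contrast.
#'
#' @param chan_a,chan_b Montage channel labels.
#' @param band One of `"theta"`, `"alpha"`, `"beta"`.
#' @param phase_lag Phase lag in radians (0, pi); zero-lag components are
#'   invisible to WPLI by construction.
#' @param strength Coupling strength in \[0, 1\]: scales the oscillator
#'   amplitude relative to [sim_config()]'s `coupling_gain`.
#' @param effect_delta Strength increment applied in `condition_effect`.
#' @param condition_effect Condition label receiving the increment, or `NA`.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(chan_a, chan_b, band = "beta",
                          phase_lag = pi / 4, strength = 0.4,
                          effect_delta = 0, condition_effect = NA_character_) {
  stopifnot(band %in% c("theta", "alpha", "beta"),
            phase_lag > 0, phase_lag < pi,
            strength >= 0, strength <= 1)
  if (strength + abs(effect_delta) > 1)
    stop("coupling strength + |effect_delta| must not exceed 1")
  structure(list(chan_a = chan_a, chan_b = chan_b, band = band,
                 phase_lag = phase_lag, strength = strength,
                 effect_delta = effect_delta,
                 condition_effect = condition_effect),
            class = "coupling_spec")
}

#' Specify the planted performance correlation
#'
#' Per-subject ring scores are tied to the subject's latent coupling level
#' through a Gaussian copula, so that the rank correlation between a
#' coupling-driven network feature (mean WPLI of the coupled band) and the
#' mean ring score equals `rho` in expectation.
#'
#' @param rho Planted Spearman correlation in \[-1, 1\].
#' @param score_mean,score_sd Named numeric vectors (one entry per
#'   condition) of the subject-level mean ring score and its between-subject
#'   standard deviation.
#' @param shot_sd Within-subject shot-to-shot score standard deviation.
#' @return A `performance_spec` list.
#' @export
performance_spec <- function(rho = 0.4,
                             score_mean = c(control = 8.02, noise = 8.00,
                                            weak_light = 5.38),
                             score_sd = c(control = 0.76, noise = 0.81,
                                          weak_light = 1.56),
                             shot_sd = 1.1) {
  stopifnot(abs(rho) <= 1, all(score_sd > 0), shot_sd > 0)
  structure(list(rho = rho, score_mean = score_mean, score_sd = score_sd,
                 shot_sd = shot_sd),
            class = "performance_spec")
}

#' Configure a synthetic shooter-EEG cohort
#'
#' Defaults mirror the study design being emulated: 30 subjects, three
#' conditions (control, noise, weak light), two sets of 30 shots per
#' condition, 1000 Hz sampling, a 30-channel 10-20 montage, eyes-closed
#' resting EEG with an occipital alpha peak at the subject's IAF, planted
#' band-limited phase-lagged coupling, a zero-lag broadband common source
#' as a volume-conduction surrogate, 1/f background noise, and ring scores
#' on the 0/5..10 scale with the published per-condition means.
#'
#' @param n_subjects Number of subjects.
#' @param conditions Condition labels.
#' @param shots_per_condition Shots (events) per subject and condition.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Montage (30 labels).
#' @param iaf_mean,iaf_sd Population mean/SD of the individual alpha
#'   frequency in Hz; per-subject draws are snapped to the 0.5 Hz analysis
#'   grid and clipped to \[8, 12\].
#' @param couplings List of [coupling_spec()] objects; `NULL` installs the
#'   default ground truth (a temporal beta coupling raised under noise and
#'   an occipital beta coupling raised under weak light).
#' @param coupling_subject_sd Between-subject SD of coupling strength (the
#'   latent that also drives the planted performance correlation).
#' @param coupling_gain Oscillator amplitude (microvolts) at strength 1.
#' @param common_source_gain Gain of the zero-lag broadband common source
#'   mixed into every channel with channel-specific random weights.
#' @param noise_color Exponent alpha of the 1/f^alpha background spectrum.
#' @param background_sd Background noise SD per channel, microvolts.
#' @param artifact_rate Probability that a trial is contaminated; the
#'   default reproduces a removal rate of roughly 3.8 percent.
#' @param artifact_amplitude Artifact transient peak amplitude, microvolts.
#' @param shot_interval Mean spacing between shots, seconds.
#' @param rest_duration Length of each resting segment (eyes closed, then
#'   eyes open), seconds.
#' @param alpha_amplitude Amplitude of the eyes-closed occipital alpha
#'   oscillation, microvolts.
#' @param performance A [performance_spec()].
#' @param seed Integer master seed; identical configurations with identical
#'   seeds reproduce the cohort exactly.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 30,
                       conditions = c("control", "noise", "weak_light"),
                       shots_per_condition = 60,
                       sampling_rate = 1000,
                       channel_labels = montage_channels(),
                       iaf_mean = 10, iaf_sd = 0.8,
                       couplings = NULL,
                       coupling_subject_sd = 0.12,
                       coupling_gain = 20,
                       common_source_gain = 0.5,
                       noise_color = 1,
                       background_sd = 10,
                       artifact_rate = 0.038,
                       artifact_amplitude = 500,
                       shot_interval = 5,
                       rest_duration = 150,
                       alpha_amplitude = 15,
                       performance = performance_spec(),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, shots_per_condition >= 1,
            sampling_rate > 0, length(channel_labels) == 30,
            iaf_sd >= 0, coupling_subject_sd >= 0, coupling_gain >= 0,
            common_source_gain >= 0, noise_color >= 0, background_sd > 0,
            artifact_rate >= 0, artifact_rate <= 1, artifact_amplitude >= 0,
            shot_interval > 0, rest_duration >= 2,
            inherits(performance, "performance_spec"))
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  if (is.null(couplings)) {
    # default ground truth: temporal beta coupling raised under noise,
    # occipital beta coupling raised under weak light (where configured)
    couplings <- list(
      coupling_spec("T7", "T8", "beta", strength = 0.4, effect_delta = 0.2,
                    condition_effect = if ("noise" %in% conditions) "noise"
                                       else NA_character_),
      coupling_spec("O1", "O2", "beta", strength = 0.4, effect_delta = 0.2,
                    condition_effect = if ("weak_light" %in% conditions)
                                         "weak_light" else NA_character_))
  }
  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) stop("couplings must be coupling_spec objects")
    bad <- setdiff(c(cp$chan_a, cp$chan_b), channel_labels)
    if (length(bad))
      stop("coupling references channels not in the montage: ",
           paste(bad, collapse = ", "))
    if (!is.na(cp$condition_effect) && !cp$condition_effect %in% conditions)
      stop("coupling condition_effect '", cp$condition_effect,
           "' is not a configured condition")
  }
  miss <- setdiff(conditions, names(performance$score_mean))
  if (length(miss))
    stop("performance spec lacks score means for: ", paste(miss, collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects), conditions = conditions,
    shots_per_condition = as.integer(shots_per_condition),
    sampling_rate = sampling_rate, channel_labels = channel_labels,
    iaf_mean = iaf_mean, iaf_sd = iaf_sd,
    couplings = couplings, coupling_subject_sd = coupling_subject_sd,
    coupling_gain = coupling_gain, common_source_gain = common_source_gain,
    noise_color = noise_color, background_sd = background_sd,
    artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
    shot_interval = shot_interval, rest_duration = rest_duration,
    alpha_amplitude = alpha_amplitude, performance = performance,
    seed = as.integer(seed)), class = "sim_config")
}

# deterministic per-subject stream seed, kept inside 32-bit range
subject_seed <- function(config, subject_index, salt = 0L) {
  (as.double(config$seed) * 2654435761 + subject_index * 97561 + salt * 131) %%
    2147483647
}
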