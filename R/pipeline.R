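# artifact injection for one simulated subject, matching the cohort layout
apply_artifacts_subject <- function(subj, config) {
  contaminated <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    sid <- subj$recordings[[cond]]$subject_id
    inj <- inject_artifacts(subj$recordings[[cond]], config$artifact_rate,
                            config$artifact_amplitude,
                            seed = subject_seed(config, sid, salt = 200L + ci))
    subj$recordings[[cond]] <- inj$recording
    contaminated[[cond]] <- inj$contaminated
  }
  subj$truth$contaminated <- contaminated
  subj
}

#' Per-subject analysis: simulate, preprocess and compute connectivity
#'
#' The single-subject pipeline behind [run_all()]: simulate the subject,
#' inject artifacts at the configured rate, estimate the IAF from the
#' eyes-closed resting EEG, derive the individualized bands, band-pass
#' filter the continuous signal (broadband 0.1-50 Hz, then each band),
#' epoch the aiming and baseline windows, reject trials by peak-to-peak
#' amplitude, and compute WPLI, baseline WPLI and ERWPLI matrices per band
#' and condition, plus graph metrics of the aiming-window network.
#'
#' @param config A [sim_config()].
#' @param subject_index Subject number.
#' @param bands Band names to analyse.
#' @param window_aiming,window_baseline Epoch windows in seconds relative
#'   to the shot.
#' @param reject_uv Peak-to-peak artifact-rejection threshold, microvolts.
#' @param trim_fraction Analytic-signal edge trim per end.
#' @param broadband Initial band-pass edges in Hz, or `NULL` to skip the
#'   broadband stage (each analysis band lies inside it, so band-limited
#'   results are unchanged; the stage mainly serves DC and line-noise
#'   removal on real recordings).
#' @param fir_order FIR filter order.
#' @param wpli_average Trial-averaging rule, see [wpli()].
#' @param compute_baseline,compute_metrics Toggle ERWPLI / graph metrics.
#' @param use_true_iaf Use the generator's true IAF instead of estimating
#'   it (only meaningful for simulated data).
#' @return List with `iaf`, `bands`, per-condition results (`wpli`,
#'   `baseline`, `erwpli`, `metrics`, `n_trials`), `performance`, `truth`
#'   and accumulated `warnings`.
#' @export
subject_connectivity <- function(config, subject_index,
                                 bands = c("theta", "alpha", "beta"),
                                 window_aiming = c(-3, 0),
                                 window_baseline = c(-4, -3),
                                 reject_uv = 150, trim_fraction = 0.10,
                                 broadband = c(0.1, 50), fir_order = 1000,
                                 wpli_average = "pooled",
                                 compute_baseline = TRUE,
                                 compute_metrics = TRUE,
                                 use_true_iaf = FALSE) {
  subj <- simulate_subject(config, subject_index)
  if (config$artifact_rate > 0) subj <- apply_artifacts_subject(subj, config)
  warnings <- character(0)
  if (use_true_iaf) {
    iaf_hz <- subj$truth$iaf
  } else {
    est <- withCallingHandlers(
      estimate_iaf(subj$resting),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    iaf_hz <- est$iaf
    if (est$fallback)
      warnings <- c(warnings, sprintf("subject %d: IAF grid-argmax fallback",
                                      subject_index))
  }
  band_defs <- bands_from_iaf(iaf_hz)[bands]
  out <- list(iaf = iaf_hz, bands = band_defs, performance = subj$performance,
              truth = subj$truth, conditions = list())
  for (cond in config$conditions) {
    rec <- subj$recordings[[cond]]
    if (!is.null(broadband))
      rec <- bandpass_fir(rec, broadband[1], broadband[2], order = fir_order)
    # artifact rejection operates on the broadband epochs; the retained
    # trial set is then shared by every analysis band
    ep_bb <- reject_artifacts(epoch_recording(rec, window_aiming), reject_uv)
    rej <- attr(ep_bb, "rejection")
    keep <- attr(ep_bb, "trial_ids")
    if (length(rej$removed))
      warnings <- c(warnings,
                    sprintf("subject %d %s: removed %d/%d aiming trials",
                            subject_index, cond,
                            length(rej$removed), rej$n_total))
    keep_base <- NULL
    if (compute_baseline) {
      epb_bb <- reject_artifacts(epoch_recording(rec, window_baseline),
                                 reject_uv)
      keep_base <- attr(epb_bb, "trial_ids")
    }
    res_b <- list()
    for (bn in names(band_defs)) {
      bd <- band_defs[[bn]]
      recb <- bandpass_fir(rec, bd[1], bd[2], order = fir_order,
                           band_label = bn)
      ep <- subset_trials(epoch_recording(recb, window_aiming), keep)
      wa <- wpli(analytic_signal(ep, trim_fraction), average = wpli_average)
      entry <- list(wpli = wa, n_trials = attr(wa, "n_trials"),
                    rejection = rej)
      if (compute_baseline) {
        epb <- subset_trials(epoch_recording(recb, window_baseline),
                             keep_base)
        wb <- wpli(analytic_signal(epb, trim_fraction),
                   average = wpli_average)
        er <- erwpli(wa, wb)
        if (nrow(attr(er, "floored") %||% matrix(0, 0, 2)))
          warnings <- c(warnings,
                        sprintf("subject %d %s %s: %d baseline entries floored",
                                subject_index, cond, bn,
                                nrow(attr(er, "floored"))))
        entry$baseline <- wb
        entry$erwpli <- er
      }
      if (compute_metrics) entry$metrics <- network_metrics(wa)
      res_b[[bn]] <- entry
    }
    out$conditions[[cond]] <- res_b
  }
  out$warnings <- warnings
  out
}

#' Run the complete simulate-analyse pipeline for a cohort
#'
#' Simulates every subject, runs [subject_connectivity()], and performs
#' the group statistics: edgewise and nodewise contrasts of every
#' non-reference condition against the first (reference) condition, global
#' and nodal metric contrasts, and Spearman correlations of network
#' features with mean ring scores -- each family BH-FDR corrected per band
#' and contrast. Deterministic given the configuration (which carries the
#' seed).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when set, tidy CSVs plus a JSON run
#'   manifest (with file checksums and accumulated warnings) are written.
#' @param ... Passed on to [subject_connectivity()].
#' @param alpha Significance level on adjusted p-values.
#' @return A `pipeline_result` list: `subjects`, `connectivity`,
#'   `mean_wpli`, `metrics_global`, `edgewise`, `nodewise`,
#'   `metric_tests`, `correlations`, `scores`, `manifest`.
#' @export
run_all <- function(config, out_dir = NULL, alpha = 0.05, ...) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    subject_connectivity(config, s, ...))
  band_names <- names(subjects[[1]]$bands)
  conds <- config$conditions
  ref <- conds[1]

  conn <- list(); nodal_mean <- list(); mg <- list()
  for (bn in band_names) {
    conn[[bn]] <- list(); nodal_mean[[bn]] <- list(); mg[[bn]] <- list()
    for (cond in conds) {
      mats <- lapply(subjects, function(s) s$conditions[[cond]][[bn]]$wpli)
      conn[[bn]][[cond]] <- mats
      nodal_mean[[bn]][[cond]] <- t(vapply(mats, channel_mean_wpli,
                                           numeric(nrow(mats[[1]]))))
      met <- lapply(subjects, function(s) s$conditions[[cond]][[bn]]$metrics)
      if (!is.null(met[[1]]))
        mg[[bn]][[cond]] <- data.frame(
          mean_wpli = vapply(mats, mean_wpli, numeric(1)),
          avg_clustering = vapply(met, `[[`, numeric(1), "avg_clustering"),
          char_path_length = vapply(met, `[[`, numeric(1), "char_path_length"),
          global_efficiency = vapply(met, `[[`, numeric(1), "global_efficiency"))
    }
  }
  scores <- sapply(conds, function(cond)
    vapply(subjects, function(s) s$performance[[cond]]$mean_score, numeric(1)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, conds))

  edgewise <- list(); nodewise <- list(); metric_tests <- list()
  correlations <- list()
  can_test <- config$n_subjects >= 2
  for (bn in band_names) {
    for (cond in setdiff(conds, ref)) {
      key <- paste(bn, cond, "vs", ref, sep = "_")
      if (can_test) {
        edgewise[[key]] <- edgewise_compare(conn[[bn]][[cond]],
                                            conn[[bn]][[ref]], alpha)
        nodewise[[key]] <- nodewise_compare(nodal_mean[[bn]][[cond]],
                                            nodal_mean[[bn]][[ref]], alpha)
        if (!is.null(mg[[bn]][[cond]])) {
          mt <- lapply(names(mg[[bn]][[cond]]), function(m) {
            res <- wilcoxon_ranksum(mg[[bn]][[cond]][[m]], mg[[bn]][[ref]][[m]])
            data.frame(metric = m, statistic = res$statistic,
                       p_raw = res$p_value)
          })
          mt <- do.call(rbind, mt)
          mt$p_adjusted <- fdr_bh(mt$p_raw)
          metric_tests[[key]] <- mt
        }
      }
    }
    if (config$n_subjects >= 5 && length(mg[[bn]]))
      for (cond in conds) {
        key <- paste(bn, cond, sep = "_")
        correlations[[key]] <- correlate_with_performance(
          mg[[bn]][[cond]], scores[, cond], alpha)
      }
  }

  warnings <- unlist(lapply(subjects, `[[`, "warnings"))
  result <- structure(list(
    subjects = subjects, connectivity = conn, nodal_mean = nodal_mean,
    metrics_global = mg, scores = scores, edgewise = edgewise,
    nodewise = nodewise, metric_tests = metric_tests,
    correlations = correlations, config = config,
    manifest = list(seed = config$seed, warnings = warnings)),
    class = "pipeline_result")
  if (!is.null(out_dir)) result$manifest <- c(
    result$manifest, write_pipeline_outputs(result, out_dir))
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (bn in names(result$connectivity))
    for (cond in names(result$connectivity[[bn]]))
      for (s in seq_along(result$connectivity[[bn]][[cond]])) {
        f <- file.path(out_dir, sprintf("wpli_sub-%02d_%s_%s.csv", s, cond, bn))
        write_conn_csv(result$connectivity[[bn]][[cond]][[s]], f)
        files <- c(files, f)
      }
  for (nm in names(result$edgewise)) {
    f <- file.path(out_dir, paste0("edgewise_", nm, ".csv"))
    data.table::fwrite(result$edgewise[[nm]], f)
    files <- c(files, f)
  }
  for (nm in names(result$nodewise)) {
    f <- file.path(out_dir, paste0("nodewise_", nm, ".csv"))
    data.table::fwrite(result$nodewise[[nm]], f)
    files <- c(files, f)
  }
  for (nm in names(result$correlations)) {
    f <- file.path(out_dir, paste0("correlations_", nm, ".csv"))
    data.table::fwrite(result$correlations[[nm]], f)
    files <- c(files, f)
  }
  manifest <- list(files = data.frame(path = basename(files),
                                      md5 = unname(tools::md5sum(files))),
                   warnings = result$manifest$warnings,
                   seed = result$config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(files = files)
}

#' Aggregate nodewise results by scalp region
#'
#' @param nodal A nodewise result data frame with columns `channel` and
#'   `p_adjusted` (as produced by [nodewise_compare()]), optionally a
#'   numeric column named by `value_col`.
#' @param regions Region map, see [default_region_map()].
#' @param alpha Significance level on adjusted p-values.
#' @param value_col Optional column to average per region.
#' @return Data frame (region, n_channels, n_significant, and mean value
#'   when requested).
#' @export
region_summary <- function(nodal, regions = default_region_map(),
                           alpha = 0.05, value_col = NULL) {
  validate_region_map(regions)
  stopifnot(all(c("channel", "p_adjusted") %in% names(nodal)))
  rows <- lapply(names(regions), function(rg) {
    sel <- nodal$channel %in% regions[[rg]]
    out <- data.frame(region = rg, n_channels = sum(sel),
                      n_significant = sum(nodal$p_adjusted[sel] < alpha))
    if (!is.null(value_col)) out$mean_value <- mean(nodal[[value_col]][sel])
    out
  })
  do.call(rbind, rows)
}
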