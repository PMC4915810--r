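#' Default analysis configuration
#'
#' Tunable parameters of the end-to-end pipeline, grouped by stage.
#' Values can be stored in / loaded from a YAML file with
#' [write_analysis_config()] / [read_analysis_config()].
#'
#' @param ... overrides of individual entries, e.g.
#'   `lick = list(threshold = 0.4)`.
#' @return nested named list.
#' @export
default_analysis_config <- function(...) {
  cfg <- list(
    lick = list(threshold = 0.5, debounce_s = 0.05),
    behavior = list(reward_window_s = 1.0),
    preprocess = list(dvdt_threshold = 10, peak_threshold = NA,
                      refractory_s = 0.002, median_window_s = 0.008),
    evoked = list(align_window = c(-1, 2), psth_bin_s = 0.05),
    bouts = list(gap_s = 1.0, min_after_stim_s = 3, min_after_bout_s = 1))
  utils::modifyList(cfg, list(...))
}

#' Read / write the analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_analysis_config()] returns the config list merged over
#'   the defaults; [write_analysis_config()] returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  utils::modifyList(default_analysis_config(), yaml::read_yaml(path))
}

#' @rdname read_analysis_config
#' @param config a config list from [default_analysis_config()].
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Analyse one session end to end
#'
#' Runs the full single-recording pipeline: lick detection, trial-table
#' construction and performance gating, spike removal, evoked hit (and,
#' when present, miss) metrics, and the spontaneous-lick-bout analysis
#' with pre-lick onset detection.
#'
#' @param s a [session_recording()] (or a path readable by
#'   [read_session()]).
#' @param config see [default_analysis_config()].
#' @return a `session_analysis` list: `licks`, `trial_table`,
#'   `performance`, `decomp`, `evoked_hit`, `evoked_miss`, `bouts`,
#'   `lick_mod`, `prelick`.
#' @export
analyze_session <- function(s, config = default_analysis_config()) {
  if (is.character(s)) s <- read_session(s)
  validate_session(s)
  fs <- s$sample_rate_vm
  licks <- detect_licks(s$lick_trace, s$sample_rate_lick,
                        threshold = config$lick$threshold,
                        debounce_s = config$lick$debounce_s)
  tt <- build_trial_table(s$stim_times, s$catch_times, licks,
                          config$behavior$reward_window_s)
  perf <- summarize_performance(tt)
  pk <- config$preprocess$peak_threshold
  decomp <- subthreshold_decomposition(
    s$vm_trace, fs,
    dvdt_threshold = config$preprocess$dvdt_threshold,
    peak_threshold = if (is.na(pk)) NULL else pk,
    refractory_s = config$preprocess$refractory_s,
    median_window_s = config$preprocess$median_window_s)
  ev_hit <- evoked_metrics(decomp$vm_sub, decomp$spike_times, fs, tt,
                           licks, outcome = "hit",
                           align_window = config$evoked$align_window,
                           psth_bin_s = config$evoked$psth_bin_s)
  ev_miss <- evoked_metrics(decomp$vm_sub, decomp$spike_times, fs, tt,
                            licks, outcome = "miss",
                            align_window = config$evoked$align_window,
                            psth_bin_s = config$evoked$psth_bin_s)
  bouts <- segment_bouts(licks, config$bouts$gap_s)
  sel <- select_spontaneous_bouts(bouts, s$stim_times,
                                  config$bouts$min_after_stim_s,
                                  config$bouts$min_after_bout_s)
  lm <- lick_aligned_modulation(decomp$vm_sub, decomp$spike_times, fs,
                                sel$bout_onsets)
  pl <- if (is.null(lm$flag))
    prelick_onset(lm$mean_trace, lm$time) else NULL
  structure(list(meta = s$meta, licks = licks, trial_table = tt,
                 performance = perf, decomp = decomp,
                 evoked_hit = ev_hit, evoked_miss = ev_miss,
                 bouts = sel, lick_mod = lm, prelick = pl),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("<session_analysis> %s/%s\n", x$meta$mouse_id,
              x$meta$cell_id))
  print(x$performance)
  print(x$evoked_hit)
  invisible(x)
}

#' Extract the per-cell metric row from a session analysis
#'
#' @param a a `session_analysis`.
#' @return one-row data frame suitable for [build_report()].
#' @export
cell_metrics_row <- function(a) {
  ev <- a$evoked_hit
  data.frame(
    cell_id = a$meta$cell_id, mouse_id = a$meta$mouse_id,
    group = a$meta$group, projection = a$meta$projection_target,
    d_prime = a$performance$d_prime,
    group_label = a$performance$group_label,
    mean_rt = a$performance$mean_reaction_time,
    n_hits = ev$n_trials_used %||% 0L,
    psp_amplitude = ev$psp_amplitude %||% NA_real_,
    dvm_late = ev$dvm_late %||% NA_real_,
    dvm_lick = ev$dvm_lick %||% NA_real_,
    dvm_alt_late = ev$dvm_alt_late %||% NA_real_,
    dvm_alt_lick = ev$dvm_alt_lick %||% NA_real_,
    ap_early = ev$ap_early %||% NA_real_,
    ap_late = ev$ap_late %||% NA_real_,
    ap_lick = ev$ap_lick %||% NA_real_,
    baseline_ap_rate = ev$baseline_ap_rate %||% NA_real_,
    miss_psp_amplitude = a$evoked_miss$psp_amplitude %||% NA_real_,
    miss_dvm_late = a$evoked_miss$dvm_late %||% NA_real_,
    miss_dvm_lick = a$evoked_miss$dvm_lick %||% NA_real_,
    dvm_lick_onset = a$lick_mod$dvm_lick_onset %||% NA_real_,
    dap_lick_onset = a$lick_mod$dap_lick_onset %||% NA_real_,
    n_bouts = a$lick_mod$n_bouts %||% 0L,
    prelick_latency = if (is.null(a$prelick)) NA_real_
                      else a$prelick$latency_s)
}

#' Analyse a cohort of sessions
#'
#' Applies [analyze_session()] to every session, drops recordings whose
#' measured d' is inconsistent with their nominal training group
#' (performance gating: good performers require d' > 1.1, naive mice
#' d' < 0.9), and assembles the per-cell metrics table and the
#' cross-group report.
#'
#' @param sessions list of [session_recording()] objects,
#'   `sim_session` objects, or session paths.
#' @param config see [default_analysis_config()].
#' @param gate apply the d' performance gate (default TRUE).
#' @return list `cells` (per-cell metrics data frame), `analyses`,
#'   `report` (see [build_report()]), `n_excluded`.
#' @export
analyze_cohort <- function(sessions, config = default_analysis_config(),
                           gate = TRUE) {
  analyses <- lapply(sessions, function(s) {
    if (inherits(s, "sim_session")) s <- s$session
    analyze_session(s, config)
  })
  cells <- do.call(rbind, lapply(analyses, cell_metrics_row))
  keep <- rep(TRUE, nrow(cells))
  if (gate) keep <- cells$group_label == cells$group
  report <- build_report(cells[keep, ],
                         metrics = c("psp_amplitude", "dvm_late",
                                     "dvm_lick", "ap_early", "ap_late",
                                     "ap_lick", "dvm_lick_onset",
                                     "dap_lick_onset"))
  list(cells = cells[keep, ], analyses = analyses, report = report,
       n_excluded = sum(!keep))
}
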