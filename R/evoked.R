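#' Align a trace around event times
#'
#' Cuts one row per event out of a continuous trace, with t = 0 at the
#' event. Events whose window would extend past either end of the trace
#' are dropped with a warning.
#'
#' @param trace numeric vector (Vm or any same-rate signal).
#' @param sample_rate Hz.
#' @param event_times event times (s).
#' @param window `c(t_min, t_max)` in s relative to the event
#'   (default `c(-1, 2)`).
#' @return matrix (events x samples) with attributes `time` (the shared
#'   relative time axis) and `dropped` (indices of skipped events).
#' @export
align_trials <- function(trace, sample_rate, event_times,
                         window = c(-1, 2)) {
  n <- length(trace)
  nw <- as.integer(round((window[2] - window[1]) * sample_rate)) + 1L
  rel <- window[1] + (0:(nw - 1L)) / sample_rate
  i_event <- as.integer(round(event_times * sample_rate)) + 1L
  i0 <- i_event + as.integer(round(window[1] * sample_rate))
  ok <- i0 >= 1L & (i0 + nw - 1L) <= n
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the trace edge; dropped",
                    sum(!ok)))
  m <- matrix(NA_real_, sum(ok), nw)
  kk <- which(ok)
  for (r in seq_along(kk))
    m[r, ] <- trace[i0[kk[r]]:(i0[kk[r]] + nw - 1L)]
  attr(m, "time") <- rel
  attr(m, "dropped") <- which(!ok)
  m
}

#' Average aligned trials
#'
#' Pointwise mean across the rows of an aligned-trial matrix.
#'
#' @param aligned matrix from [align_trials()].
#' @param rows optional row filter (logical or integer).
#' @return list `mean` (trace), `n`, `time`, and `flag`
#'   (`"no_trials"` when the selection is empty).
#' @export
average_response <- function(aligned, rows = NULL) {
  time <- attr(aligned, "time")
  if (!is.null(rows)) aligned <- aligned[rows, , drop = FALSE]
  if (nrow(aligned) == 0)
    return(list(mean = numeric(), n = 0L, time = time, flag = "no_trials"))
  list(mean = colMeans(aligned), n = nrow(aligned), time = time, flag = NULL)
}

baseline_mean <- function(trace, time, baseline_window = c(-0.005, 0)) {
  mean(trace[in_window(time, baseline_window)])
}

#' Postsynaptic-potential amplitude of an averaged response
#'
#' Peak of the trial-averaged subthreshold trace in the early search
#' window minus the pre-stimulus baseline (mean Vm over the 5 ms before
#' stimulus onset). The search window is restricted to the early response
#' (`(0, 0.05]` s by default) so slower depolarizations do not
#' contaminate the peak.
#'
#' @param mean_trace averaged AP-removed trace.
#' @param time relative time axis (s).
#' @param search_window peak search interval `(t0, t1]` (default
#'   `c(0, 0.05)`).
#' @param baseline_window baseline interval `[t0, t1)` (default
#'   `c(-0.005, 0)`).
#' @return amplitude in mV.
#' @export
psp_amplitude <- function(mean_trace, time, search_window = c(0, 0.05),
                          baseline_window = c(-0.005, 0)) {
  b <- baseline_mean(mean_trace, time, baseline_window)
  peak <- max(mean_trace[time > search_window[1] & time <= search_window[2]])
  peak - b
}

#' Baseline-subtracted mean depolarization in a window
#'
#' Mean of the averaged subthreshold trace over a half-open window minus
#' the pre-stimulus baseline. The standard windows are late
#' (`[0.05, 0.25)` s) and lick (`[0.25, 1.0)` s), with alternative
#' splits `[0.05, 0.35)` / `[0.35, 1.0)`.
#'
#' @param mean_trace averaged AP-removed trace.
#' @param time relative time axis (s).
#' @param window `c(t0, t1)`, half-open.
#' @param baseline_window baseline interval (default `c(-0.005, 0)`).
#' @return delta-Vm in mV.
#' @export
delta_vm <- function(mean_trace, time, window,
                     baseline_window = c(-0.005, 0)) {
  mean(mean_trace[in_window(time, window)]) -
    baseline_mean(mean_trace, time, baseline_window)
}

# count spikes falling in [t0, t1) for each event-relative window
count_spikes <- function(spike_times, event_times, window) {
  spike_times <- sort(spike_times)
  lo <- findInterval(event_times + window[1], spike_times,
                     left.open = TRUE)
  hi <- findInterval(event_times + window[2], spike_times,
                     left.open = TRUE)
  # spikes with t >= e+w0 and t < e+w1; findInterval(x, v) counts v <= x,
  # left.open counts v < x, so hi - lo counts w0-inclusive, w1-exclusive
  sum(hi - lo)
}

#' Spontaneous (baseline) action-potential rate from no-lick periods
#'
#' Counts spikes in the 2 s immediately preceding each trial's (real or
#' virtual) stimulus, excluding any window that contains a lick, and
#' divides by the total no-lick time. With less than `min_total_s` of
#' qualifying time the estimate is flagged low-confidence.
#'
#' @param spike_times spike times (s).
#' @param trial_stim_times stimulus times of all trials, test and catch.
#' @param lick_times lick contact times (s).
#' @param window_s pre-trial window length (default 2 s).
#' @param min_total_s minimum qualifying time (default 16 s).
#' @return list `rate` (Hz), `total_time_s`, `n_windows`, `flag`.
#' @export
baseline_ap_rate <- function(spike_times, trial_stim_times, lick_times,
                             window_s = 2, min_total_s = 16) {
  lick_times <- sort(lick_times)
  ok <- vapply(trial_stim_times, function(t0) {
    count_events_in(lick_times, t0 - window_s, t0) == 0L
  }, logical(1))
  if (!any(ok)) vm_error("no lick-free pre-trial windows",
                         "vmdetect_no_data_error")
  used <- trial_stim_times[ok]
  n_spk <- sum(vapply(used, function(t0)
    count_events_in(spike_times, t0 - window_s, t0), integer(1)))
  total <- window_s * length(used)
  list(rate = n_spk / total, total_time_s = total, n_windows = length(used),
       flag = if (total < min_total_s) "low_confidence" else NULL)
}

count_events_in <- function(sorted_times, t0, t1) {
  # events with t >= t0 and t < t1
  as.integer(findInterval(t1, sorted_times, left.open = TRUE) -
               findInterval(t0, sorted_times, left.open = TRUE))
}

#' Baseline-subtracted evoked spike rates in the early/late/lick windows
#'
#' Per-window spike rate across trials minus the spontaneous rate. Rates
#' can be negative when stimulation suppresses firing below baseline.
#'
#' @param spike_times spike times (s).
#' @param stim_times stimulus times of the analysed trials.
#' @param baseline_rate Hz, from [baseline_ap_rate()].
#' @param windows named list of half-open windows (defaults: early
#'   `[0, 0.05)`, late `[0.05, 0.25)`, lick `[0.25, 1.0)`).
#' @return named numeric vector of delta rates (Hz).
#' @export
evoked_ap_rates <- function(spike_times, stim_times, baseline_rate,
                            windows = list(early = c(0, 0.05),
                                           late = c(0.05, 0.25),
                                           lick = c(0.25, 1.0))) {
  spike_times <- sort(spike_times)
  vapply(windows, function(w) {
    n <- count_spikes(spike_times, stim_times, w)
    n / (length(stim_times) * (w[2] - w[1])) - baseline_rate
  }, numeric(1))
}

#' Peristimulus time histogram
#'
#' Spike counts in fixed bins relative to the stimulus, averaged over
#' trials and expressed in Hz; a baseline-subtracted variant is included
#' for display.
#'
#' @param spike_times spike times (s).
#' @param stim_times stimulus times of the analysed trials.
#' @param bin_s bin width in s (conventional values 0.05 and 0.01).
#' @param window PSTH extent relative to the stimulus (default
#'   `c(-1, 2)`).
#' @param baseline_rate Hz subtracted for the display variant.
#' @return list `bin_edges`, `rate` (Hz per bin), `rate_sub`
#'   (baseline-subtracted), `counts` (total spikes per bin), `n_trials`.
#' @export
build_psth <- function(spike_times, stim_times, bin_s = 0.05,
                       window = c(-1, 2), baseline_rate = 0) {
  edges <- seq(window[1], window[2], by = bin_s)
  spike_times <- sort(spike_times)
  counts <- integer(length(edges) - 1)
  for (s in stim_times) {
    rel <- spike_times[spike_times >= s + window[1] &
                         spike_times < s + window[2]] - s
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges,
                                               rightmost.closed = FALSE),
                                  nbins = length(edges) - 1)
  }
  rate <- counts / (length(stim_times) * bin_s)
  list(bin_edges = edges, rate = rate, rate_sub = rate - baseline_rate,
       counts = counts, n_trials = length(stim_times))
}

#' Quantify evoked responses of one cell for one trial outcome
#'
#' Runs the full stimulus-locked quantification on the AP-removed trace
#' and the spike train: trial alignment, averaged response, PSP
#' amplitude, delta-Vm in the late/lick windows (plus the alternative
#' 0.05–0.35 / 0.35–1.0 s split), baseline and evoked spike rates, and
#' the PSTH.
#'
#' @param vm_sub AP-removed Vm trace (mV).
#' @param spike_times spike times (s).
#' @param sample_rate Hz.
#' @param trial_table a `trial_table` for the recording.
#' @param lick_times lick contact times (s), for the no-lick baseline.
#' @param outcome which trials to analyse (`"hit"` by default).
#' @param align_window alignment window (default `c(-1, 2)` s).
#' @param psth_bin_s PSTH bin (default 0.05 s).
#' @return an `evoked_metrics` list.
#' @export
evoked_metrics <- function(vm_sub, spike_times, sample_rate, trial_table,
                           lick_times, outcome = "hit",
                           align_window = c(-1, 2), psth_bin_s = 0.05) {
  stims <- trial_table$stim_time[trial_table$outcome == outcome]
  base <- baseline_ap_rate(spike_times, trial_table$stim_time, lick_times)
  if (length(stims) == 0) {
    return(structure(list(outcome = outcome, n_trials_used = 0L,
                          flag = "no_trials",
                          baseline_ap_rate = base$rate),
                     class = "evoked_metrics"))
  }
  aligned <- suppressWarnings(
    align_trials(vm_sub, sample_rate, stims, align_window))
  dropped <- attr(aligned, "dropped")
  if (length(dropped)) stims <- stims[-dropped]
  avg <- average_response(aligned)
  time <- avg$time
  rates <- evoked_ap_rates(spike_times, stims, base$rate)
  alt <- evoked_ap_rates(spike_times, stims, base$rate,
                         windows = list(alt_late = c(0.05, 0.35),
                                        alt_lick = c(0.35, 1.0)))
  structure(list(
    outcome = outcome,
    n_trials_used = avg$n,
    baseline_vm = baseline_mean(avg$mean, time),
    psp_amplitude = psp_amplitude(avg$mean, time),
    dvm_late = delta_vm(avg$mean, time, c(0.05, 0.25)),
    dvm_lick = delta_vm(avg$mean, time, c(0.25, 1.0)),
    dvm_alt_late = delta_vm(avg$mean, time, c(0.05, 0.35)),
    dvm_alt_lick = delta_vm(avg$mean, time, c(0.35, 1.0)),
    ap_early = rates[["early"]], ap_late = rates[["late"]],
    ap_lick = rates[["lick"]],
    ap_alt_late = alt[["alt_late"]], ap_alt_lick = alt[["alt_lick"]],
    baseline_ap_rate = base$rate,
    baseline_ap_flag = base$flag,
    psth = build_psth(spike_times, stims, psth_bin_s, align_window,
                      base$rate),
    mean_trace = avg$mean, time = time, flag = NULL),
    class = "evoked_metrics")
}

#' @export
print.evoked_metrics <- function(x, ...) {
  if (identical(x$flag, "no_trials")) {
    cat(sprintf("<evoked_metrics> %s: no trials\n", x$outcome))
    return(invisible(x))
  }
  cat(sprintf(
    "<evoked_metrics> %s (n=%d): PSP %.2f mV, dVm late %.2f / lick %.2f mV\n",
    x$outcome, x$n_trials_used, x$psp_amplitude, x$dvm_late, x$dvm_lick))
  invisible(x)
}

#' Aggregate per-cell metrics at the cell or mouse level
#'
#' Cell level: mean, sem and box stats across cells. Mouse level: cells
#' are first averaged within each mouse, then summarised across mice, so
#' every mouse receives equal weight regardless of its cell count.
#'
#' @param values numeric per-cell metric values.
#' @param mouse_ids mouse identifier per cell (required for
#'   `level = "mouse"`).
#' @param level `"cell"` or `"mouse"`.
#' @return list `level`, `n`, `mean`, `sem` (NA when n = 1, flagged),
#'   `box` ([box_stats()]), `values` (the unit-level values used).
#' @export
aggregate_cells <- function(values, mouse_ids = NULL, level = c("cell",
                                                                "mouse")) {
  level <- match.arg(level)
  if (level == "mouse") {
    if (is.null(mouse_ids)) validation_error("mouse_ids required")
    values <- as.numeric(tapply(values, mouse_ids, mean))
  }
  n <- length(values)
  list(level = level, n = n, mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       box = box_stats(values), values = values,
       flag = if (n == 1) "single_unit" else NULL)
}

#' Paired hit-versus-miss comparison of a per-cell metric
#'
#' @param hit,miss paired per-cell values (same cells, same order).
#' @return list with per-group means, `percent_change`
#'   (`(mean_hit - mean_miss)/mean_miss * 100`, NA and flagged when the
#'   miss mean is 0), and the paired [signed_rank_test()].
#' @export
compare_hit_miss <- function(hit, miss) {
  if (length(hit) != length(miss) || length(hit) == 0)
    validation_error("hit and miss must be paired per-cell values")
  mh <- mean(hit); mm <- mean(miss)
  pc <- if (mm == 0) NA_real_ else (mh - mm) / mm * 100
  list(n = length(hit), mean_hit = mh, mean_miss = mm,
       percent_change = pc,
       flag = if (mm == 0) "undefined_percent_change" else NULL,
       test = signed_rank_test(hit, miss))
}
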