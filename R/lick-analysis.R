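#' Segment lick contacts into bouts
#'
#' A bout is a maximal run of licks whose inter-lick intervals are all
#' shorter than `gap_s`; the onset is the first contact and the offset
#' the last.
#'
#' @param licks sorted lick contact times (s).
#' @param gap_s silent gap delimiting bouts (default 1 s).
#' @return data frame `onset`, `offset`, `n_licks`.
#' @export
segment_bouts <- function(licks, gap_s = 1.0) {
  if (length(licks) == 0)
    return(data.frame(onset = numeric(), offset = numeric(),
                      n_licks = integer()))
  licks <- sort(licks)
  new_bout <- c(TRUE, diff(licks) >= gap_s)
  id <- cumsum(new_bout)
  data.frame(onset = as.numeric(tapply(licks, id, min)),
             offset = as.numeric(tapply(licks, id, max)),
             n_licks = as.integer(tapply(licks, id, length)))
}

#' Select spontaneous unrewarded lick bouts
#'
#' Keeps bouts whose onset is at least `min_after_stim_s` after the most
#' recent preceding whisker stimulus (bouts with no preceding stimulus
#' qualify) and at least `min_after_bout_s` after the cessation (offset)
#' of the previous bout.
#'
#' @param bouts data frame from [segment_bouts()].
#' @param stim_times real whisker-stimulus times (s) — catch trials have
#'   no stimulus and do not disqualify a bout.
#' @param min_after_stim_s default 3 s.
#' @param min_after_bout_s default 1 s.
#' @return a `lick_bout_set` list: `bout_onsets` (selected),
#'   `n_candidates`, `selected` (logical per candidate).
#' @export
select_spontaneous_bouts <- function(bouts, stim_times,
                                     min_after_stim_s = 3,
                                     min_after_bout_s = 1) {
  n <- nrow(bouts)
  if (n == 0)
    return(structure(list(bout_onsets = numeric(), n_candidates = 0L,
                          selected = logical()),
                     class = "lick_bout_set"))
  stim_times <- sort(stim_times)
  ok <- logical(n)
  for (i in seq_len(n)) {
    on <- bouts$onset[i]
    j <- findInterval(on, stim_times)   # most recent stim at or before onset
    stim_ok <- j == 0 || (on - stim_times[j]) >= min_after_stim_s
    prev_ok <- i == 1 || (on - bouts$offset[i - 1]) >= min_after_bout_s
    ok[i] <- stim_ok && prev_ok
  }
  structure(list(bout_onsets = bouts$onset[ok], n_candidates = n,
                 selected = ok),
            class = "lick_bout_set")
}

#' Lick-aligned subthreshold and spiking modulation
#'
#' Aligns the AP-removed Vm trace and the spike train at selected bout
#' onsets. Delta-Vm is the mean Vm at `[-0.1, +0.1)` s around the onset
#' minus the baseline (mean at `[-1.0, -0.6)` s before the onset);
#' delta-AP is defined analogously on spike rates.
#'
#' @param vm_sub AP-removed Vm trace (mV).
#' @param spike_times spike times (s).
#' @param sample_rate Hz.
#' @param bout_onsets selected bout onsets (s).
#' @param align_window alignment extent (default `c(-1.5, 1.5)` s).
#' @param psth_bin_s PSTH bin (default 0.05 s).
#' @return list `dvm_lick_onset` (mV), `dap_lick_onset` (Hz),
#'   `baseline_ap_rate` (Hz), `mean_trace`, `time`, `psth`, `n_bouts`,
#'   `flag` (`"no_bouts"` when empty).
#' @export
lick_aligned_modulation <- function(vm_sub, spike_times, sample_rate,
                                    bout_onsets,
                                    align_window = c(-1.5, 1.5),
                                    psth_bin_s = 0.05) {
  onset_window <- c(-0.1, 0.1)
  baseline_window <- c(-1.0, -0.6)
  if (length(bout_onsets) == 0)
    return(list(dvm_lick_onset = NA_real_, dap_lick_onset = NA_real_,
                n_bouts = 0L, flag = "no_bouts"))
  aligned <- suppressWarnings(
    align_trials(vm_sub, sample_rate, bout_onsets, align_window))
  dropped <- attr(aligned, "dropped")
  if (length(dropped)) bout_onsets <- bout_onsets[-dropped]
  avg <- average_response(aligned)
  if (avg$n == 0)
    return(list(dvm_lick_onset = NA_real_, dap_lick_onset = NA_real_,
                n_bouts = 0L, flag = "no_bouts"))
  time <- avg$time
  dvm <- mean(avg$mean[in_window(time, onset_window)]) -
    mean(avg$mean[in_window(time, baseline_window)])
  spike_times <- sort(spike_times)
  r_on <- count_spikes(spike_times, bout_onsets, onset_window) /
    (length(bout_onsets) * diff(onset_window))
  r_bl <- count_spikes(spike_times, bout_onsets, baseline_window) /
    (length(bout_onsets) * diff(baseline_window))
  list(dvm_lick_onset = dvm, dap_lick_onset = r_on - r_bl,
       baseline_ap_rate = r_bl,
       mean_trace = avg$mean, time = time,
       psth = build_psth(spike_times, bout_onsets, psth_bin_s,
                         align_window, r_bl),
       n_bouts = length(bout_onsets), flag = NULL)
}

#' Pre-lick depolarization onset latency
#'
#' Scans the lick-aligned mean trace forward from the end of the baseline
#' window and reports the first time the trace exceeds
#' `baseline mean + k_sd * SD(baseline)` and stays above threshold for at
#' least `persist_s` (noise robustness). The latency is the time before
#' lick onset; cells whose trace never crosses are reported as lacking
#' pre-lick depolarization (`NA`).
#'
#' @param mean_trace lick-aligned mean subthreshold trace.
#' @param time relative time axis (s), 0 at lick onset.
#' @param baseline_window default `c(-1.0, -0.6)` s.
#' @param k_sd threshold multiplier (default 3).
#' @param persist_s minimum supra-threshold duration (default 0.05 s).
#' @param sd_floor_mv absolute threshold floor used when the baseline SD
#'   is exactly 0 (default 0.5 mV; result flagged).
#' @return list `latency_s` (positive, or NA when absent), `threshold_mv`,
#'   `flag` (`"sd_floor"` when the floor was used).
#' @export
prelick_onset <- function(mean_trace, time, baseline_window = c(-1.0, -0.6),
                          k_sd = 3, persist_s = 0.05, sd_floor_mv = 0.5) {
  bl <- mean_trace[in_window(time, baseline_window)]
  m <- mean(bl); s <- stats::sd(bl)
  flag <- NULL
  if (is.na(s) || s == 0) {
    thr <- m + sd_floor_mv
    flag <- "sd_floor"
  } else {
    thr <- m + k_sd * s
  }
  scan <- time >= baseline_window[2] & time < 0
  idx <- which(scan)
  if (length(idx) == 0)
    return(list(latency_s = NA_real_, threshold_mv = thr, flag = flag))
  above <- mean_trace[idx] > thr
  dt <- time[2] - time[1]
  need <- max(1L, as.integer(ceiling(persist_s / dt)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0)
    return(list(latency_s = NA_real_, threshold_mv = thr, flag = flag))
  onset_t <- time[idx[starts[hit[1]]]]
  list(latency_s = -onset_t, threshold_mv = thr, flag = flag)
}

#' @export
print.lick_bout_set <- function(x, ...) {
  cat(sprintf("<lick_bout_set> %d selected of %d candidate bouts\n",
              length(x$bout_onsets), x$n_candidates))
  invisible(x)
}
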