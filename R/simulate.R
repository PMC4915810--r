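#' Simulation configuration
#'
#' Parameters of the synthetic-session generator. Defaults emulate a
#' trained ("good performer") mouse and a depolarizing S2-projecting
#' layer 2/3 neuron; [cell_type_params()] provides per-group /
#' per-projection presets.
#'
#' Scheduler: trials start at random inter-trial intervals drawn uniform
#' from `iti_range`, are catch trials with probability `catch_fraction`,
#' and are aborted (logged, not delivered) if any lick occurred in the
#' `abort_lookback_s` preceding the planned time. Behavioral model:
#' test/catch trials elicit a response bout with probability
#' `p_hit`/`p_fa` at a shifted-gamma latency; spontaneous bouts arrive as
#' a thinned Poisson process. Vm model: resting potential plus
#' Ornstein-Uhlenbeck slow fluctuations, white measurement noise, a
#' difference-of-exponentials PSP kernel per test stimulus, a slower
#' alpha-like "late" depolarization on hit (and scaled-down on miss)
#' trials, a linear pre-lick ramp with plateau for every lick bout, and
#' stereotyped spike waveforms from an inhomogeneous Poisson rate model.
#'
#' @param session_duration_s session length (default 600 s).
#' @param sample_rate Vm sampling rate in Hz (default 20000).
#' @param lick_sample_rate lick-sensor sampling rate in Hz (default 5000;
#'   behavioral sensors are typically digitised more slowly than Vm).
#' @param iti_range inter-trial-interval range in s (default `c(2, 10)`).
#' @param catch_fraction probability a trial is a catch trial; must lie
#'   in `[0.4, 0.5]` (default 0.45).
#' @param abort_lookback_s abort rule lookback (default 2 s).
#' @param reward_window_s reward window (default 1 s).
#' @param p_hit,p_fa response probabilities on test/catch trials.
#' @param rt_mean_s,rt_sd_s,rt_min_s reaction-time model (shifted gamma,
#'   truncated to the reward window).
#' @param spont_bout_rate_per_min spontaneous bout rate (default 9).
#' @param bout_lick_rate_hz licks per second within a bout (default 6).
#' @param bout_duration_mean_s mean spontaneous bout duration
#'   (exponential, clipped to `[0.3, 3]` s).
#' @param vm_rest_mv resting Vm (default -62 mV).
#' @param ou_tau_s,ou_sigma_mv slow-fluctuation OU process (defaults
#'   0.1 s, 2 mV).
#' @param noise_sigma_mv white measurement noise SD (default 0.3 mV).
#' @param psp list: `amp_mean`, `amp_sd` (per-trial peak amplitude, mV,
#'   floored at 0), `tau_rise_s`, `tau_decay_s`.
#' @param late list: `amp` (kernel peak, mV), `peak_time_s` (default
#'   0.261 s), `shape` (alpha-kernel sharpness; 4 gives ~0.3 s width),
#'   `miss_scale` (late amplitude multiplier on miss trials).
#' @param lick_ramp list: `amp` (plateau, mV), `lead_time_s` (ramp start
#'   before bout onset, default 0.26 s), `decay_tau_s` (post-bout decay).
#' @param spikes list: `rate_at_rest_hz`, `gain_per_mv`, `max_rate_hz`,
#'   `waveform_amp_mv`, `waveform_width_s`, `min_isi_s`.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(session_duration_s = 600,
                       sample_rate = 20000,
                       lick_sample_rate = 5000,
                       iti_range = c(2, 10),
                       catch_fraction = 0.45,
                       abort_lookback_s = 2,
                       reward_window_s = 1,
                       p_hit = 0.77, p_fa = 0.17,
                       rt_mean_s = 0.317, rt_sd_s = 0.1, rt_min_s = 0.05,
                       spont_bout_rate_per_min = 9,
                       bout_lick_rate_hz = 6,
                       bout_duration_mean_s = 1.0,
                       vm_rest_mv = -62,
                       ou_tau_s = 0.1, ou_sigma_mv = 2,
                       noise_sigma_mv = 0.3,
                       psp = list(amp_mean = 8.5, amp_sd = 2,
                                  tau_rise_s = 0.002, tau_decay_s = 0.03),
                       late = list(amp = 6, peak_time_s = 0.261,
                                   shape = 4, miss_scale = 0.35),
                       lick_ramp = list(amp = 2.5, lead_time_s = 0.26,
                                        decay_tau_s = 0.3),
                       spikes = list(rate_at_rest_hz = 0.3,
                                     gain_per_mv = 0.4, max_rate_hz = 15,
                                     waveform_amp_mv = 45,
                                     waveform_width_s = 0.001,
                                     min_isi_s = 0.003)) {
  cfg <- list(session_duration_s = session_duration_s,
              sample_rate = sample_rate,
              lick_sample_rate = lick_sample_rate,
              iti_range = iti_range,
              catch_fraction = catch_fraction,
              abort_lookback_s = abort_lookback_s,
              reward_window_s = reward_window_s,
              p_hit = p_hit, p_fa = p_fa, rt_mean_s = rt_mean_s,
              rt_sd_s = rt_sd_s, rt_min_s = rt_min_s,
              spont_bout_rate_per_min = spont_bout_rate_per_min,
              bout_lick_rate_hz = bout_lick_rate_hz,
              bout_duration_mean_s = bout_duration_mean_s,
              vm_rest_mv = vm_rest_mv, ou_tau_s = ou_tau_s,
              ou_sigma_mv = ou_sigma_mv, noise_sigma_mv = noise_sigma_mv,
              psp = psp, late = late, lick_ramp = lick_ramp,
              spikes = spikes)
  if (cfg$catch_fraction < 0.4 || cfg$catch_fraction > 0.5)
    validation_error("catch_fraction must lie in [0.4, 0.5]")
  if (cfg$iti_range[1] <= 0 || diff(cfg$iti_range) < 0)
    validation_error("invalid iti_range")
  if (cfg$lick_ramp$lead_time_s <= 0)
    validation_error("lick_ramp lead time must be positive")
  if (any(c(cfg$session_duration_s, cfg$sample_rate, cfg$reward_window_s,
            cfg$rt_sd_s, cfg$bout_lick_rate_hz,
            cfg$bout_duration_mean_s) <= 0))
    validation_error("rates and durations must be positive")
  structure(cfg, class = "sim_config")
}

#' Per-group / per-projection simulation presets
#'
#' Overrides [sim_config()] defaults so that simulated populations
#' resemble the published effect structure: trained mice respond with
#' high hit and low false-alarm rates and S2-projecting cells carry
#' large late/lick-period depolarization; naive mice lick
#' indiscriminately and M1-projecting cells show the larger sensory PSP.
#'
#' @param group `"good_performer"` or `"naive"`.
#' @param projection `"S2-p"` or `"M1-p"`.
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
cell_type_params <- function(group = "good_performer",
                             projection = "S2-p", ...) {
  base <- if (group == "good_performer") {
    list(p_hit = 0.77, p_fa = 0.17, rt_mean_s = 0.317)
  } else {
    list(p_hit = 0.31, p_fa = 0.28, rt_mean_s = 0.369)
  }
  phys <- if (group == "good_performer") {
    if (projection == "S2-p")
      list(psp_amp = 8.5, late_amp = 6.0, ramp_amp = 2.5)
    else
      list(psp_amp = 9.5, late_amp = 2.2, ramp_amp = 0.5)
  } else {
    if (projection == "S2-p")
      list(psp_amp = 8.41, late_amp = 0.8, ramp_amp = 0.5)
    else
      list(psp_amp = 12.20, late_amp = 2.0, ramp_amp = 1.8)
  }
  cfg <- sim_config(p_hit = base$p_hit, p_fa = base$p_fa,
                    rt_mean_s = base$rt_mean_s, ...)
  cfg$psp$amp_mean <- phys$psp_amp
  cfg$late$amp <- phys$late_amp
  cfg$lick_ramp$amp <- phys$ramp_amp
  cfg
}

# shifted-gamma reaction time truncated to the reward window
draw_rt <- function(cfg) {
  shape <- ((cfg$rt_mean_s - cfg$rt_min_s) / cfg$rt_sd_s)^2
  scale <- cfg$rt_sd_s^2 / (cfg$rt_mean_s - cfg$rt_min_s)
  repeat {
    rt <- cfg$rt_min_s + stats::rgamma(1, shape = shape, scale = scale)
    if (rt < cfg$reward_window_s - 0.02) return(rt)
  }
}

# licks of one bout starting at `onset` lasting ~`duration`
bout_licks <- function(onset, duration, rate) {
  ili <- stats::runif(ceiling(duration * rate) + 2, 0.8, 1.2) / rate
  t <- onset + c(0, cumsum(ili))
  t[t <= onset + duration]
}

#' Schedule trials against a fixed lick stream
#'
#' The scheduler primitive: walks the session drawing inter-trial
#' intervals, marks each planned trial aborted when a lick occurred in
#' the preceding `abort_lookback_s`, and assigns delivered trials
#' test/catch status. Use [simulate_behavior()] for the full closed loop
#' in which licking depends on the trials themselves.
#'
#' @param cfg a [sim_config()].
#' @param lick_times fixed lick contact times (s).
#' @return data frame `time`, `type` (`"test"`/`"catch"`; NA for
#'   aborted), `aborted`.
#' @export
schedule_trials <- function(cfg, lick_times) {
  lick_times <- sort(lick_times)
  times <- numeric(0); types <- character(0); ab <- logical(0)
  t_prev <- 2
  repeat {
    t_cand <- t_prev + stats::runif(1, cfg$iti_range[1], cfg$iti_range[2])
    if (t_cand > cfg$session_duration_s - 3) break
    aborted <- count_events_in(lick_times, t_cand - cfg$abort_lookback_s,
                               t_cand) > 0
    type <- if (aborted) NA_character_
            else if (stats::runif(1) < cfg$catch_fraction) "catch"
            else "test"
    times <- c(times, t_cand); types <- c(types, type)
    ab <- c(ab, aborted)
    t_prev <- t_cand
  }
  if (length(times) == 0)
    vm_error("session too short for a single trial",
             "vmdetect_validation_error")
  data.frame(time = times, type = types, aborted = ab)
}

#' Simulate the behavioral event streams of one session
#'
#' Runs the trial scheduler and the licking model as one sequential
#' closed loop: spontaneous bouts are drawn first as a Poisson process,
#' trials are then scheduled against the accumulating lick stream
#' (spontaneous plus earlier reward-consumption licking) under the abort
#' rule, and each delivered trial elicits a response bout with
#' probability `p_hit` (test) or `p_fa` (catch). Spontaneous bouts whose
#' onset falls inside a delivered trial's reward window are thinned, so
#' the scheduler's intended outcome always matches what a parser infers
#' from the event streams.
#'
#' @param cfg a [sim_config()].
#' @return list: `trials` (scheduler log with `time`, `type`, `aborted`,
#'   `outcome`, `first_lick_time`, `reaction_time`), `lick_times`,
#'   `valve_times`, `stim_times` (delivered test trials),
#'   `catch_times` (delivered catch trials), `spont_bouts` (data frame
#'   of surviving spontaneous bouts).
#' @export
simulate_behavior <- function(cfg) {
  dur <- cfg$session_duration_s
  # -- spontaneous bouts (candidate process, later thinned) --
  span0 <- 3; span1 <- dur - 4
  n_b <- stats::rpois(1, cfg$spont_bout_rate_per_min / 60 *
                        max(0, span1 - span0))
  onsets <- sort(stats::runif(n_b, span0, span1))
  durs <- pmin(pmax(stats::rexp(n_b, 1 / cfg$bout_duration_mean_s),
                    0.3), 3)
  keep <- rep(TRUE, n_b)
  last_end <- -Inf
  for (i in seq_len(n_b)) {
    if (onsets[i] < last_end + 0.2) keep[i] <- FALSE
    else last_end <- onsets[i] + durs[i]
  }
  onsets <- onsets[keep]; durs <- durs[keep]
  sp_licks <- lapply(seq_along(onsets), function(i)
    bout_licks(onsets[i], durs[i], cfg$bout_lick_rate_hz))
  sp_active <- rep(TRUE, length(onsets))
  resp_licks <- numeric()
  valve_times <- numeric()
  rows <- list()
  t_prev <- 2
  repeat {
    t_cand <- t_prev + stats::runif(1, cfg$iti_range[1], cfg$iti_range[2])
    if (t_cand > dur - 3) break
    licks_now <- sort(c(unlist(sp_licks[sp_active]), resp_licks))
    aborted <- length(licks_now) > 0 &&
      count_events_in(licks_now, t_cand - cfg$abort_lookback_s, t_cand) > 0
    if (aborted) {
      rows[[length(rows) + 1]] <- data.frame(
        time = t_cand, type = NA_character_, aborted = TRUE,
        outcome = NA_character_, first_lick_time = NA_real_,
        reaction_time = NA_real_)
      t_prev <- t_cand
      next
    }
    type <- if (stats::runif(1) < cfg$catch_fraction) "catch" else "test"
    p_resp <- if (type == "test") cfg$p_hit else cfg$p_fa
    respond <- stats::runif(1) < p_resp
    # spontaneous bouts starting inside the reward window would corrupt
    # the intended outcome; thin them (merged into task-related licking)
    thin_until <- t_cand + cfg$reward_window_s
    first_lick <- NA_real_; rt <- NA_real_
    if (respond) {
      rt <- draw_rt(cfg)
      first_lick <- t_cand + rt
      bdur <- pmin(pmax(stats::rexp(1, 1 / (if (type == "test") 1.5
                                            else 0.8)), 0.5), 3)
      new_licks <- bout_licks(first_lick, bdur, cfg$bout_lick_rate_hz)
      resp_licks <- c(resp_licks, new_licks)
      if (type == "test") valve_times <- c(valve_times, first_lick)
      # a mouse cannot start a spontaneous bout while still licking the
      # spout: thin spontaneous onsets overlapping the response bout
      thin_until <- max(thin_until, max(new_licks) + 0.2)
    }
    drop <- sp_active & onsets >= t_cand & onsets < thin_until
    sp_active[drop] <- FALSE
    outcome <- if (type == "test") {
      if (respond) "hit" else "miss"
    } else {
      if (respond) "false_alarm" else "correct_rejection"
    }
    rows[[length(rows) + 1]] <- data.frame(
      time = t_cand, type = type, aborted = FALSE, outcome = outcome,
      first_lick_time = first_lick, reaction_time = rt)
    t_prev <- t_cand
  }
  trials <- do.call(rbind, rows)
  lick_times <- sort(c(unlist(sp_licks[sp_active]), resp_licks))
  delivered <- trials[!trials$aborted, ]
  list(trials = trials, lick_times = lick_times,
       valve_times = sort(valve_times),
       stim_times = delivered$time[delivered$type == "test"],
       catch_times = delivered$time[delivered$type == "catch"],
       spont_bouts = data.frame(onset = onsets[sp_active],
                                offset = onsets[sp_active] +
                                  durs[sp_active]))
}

# peak-normalised difference-of-exponentials PSP kernel
psp_kernel <- function(cfg) {
  fs <- cfg$sample_rate
  t <- (0:as.integer(round(0.3 * fs))) / fs
  k <- exp(-t / cfg$psp$tau_decay_s) - exp(-t / cfg$psp$tau_rise_s)
  k / max(k)
}

# alpha-like late-depolarization kernel, peak-normalised, peak at
# late$peak_time_s; shape 4 gives a full width at half maximum ~0.3 s
late_kernel <- function(cfg) {
  fs <- cfg$sample_rate
  tp <- cfg$late$peak_time_s
  a <- cfg$late$shape
  t <- (0:as.integer(round(2 * fs))) / fs
  (t / tp)^a * exp(a * (1 - t / tp))
}

# pre-lick ramp -> plateau -> exponential decay kernel for one bout
ramp_kernel <- function(cfg, plateau_s) {
  fs <- cfg$sample_rate
  lead <- cfg$lick_ramp$lead_time_s
  n_lead <- as.integer(round(lead * fs))
  n_plat <- as.integer(round(plateau_s * fs))
  n_dec <- as.integer(round(5 * cfg$lick_ramp$decay_tau_s * fs))
  c(seq(0, 1, length.out = n_lead + 1L)[-(n_lead + 1L)],
    rep(1, n_plat),
    exp(-(1:n_dec) / (cfg$lick_ramp$decay_tau_s * fs)))
}

# clipped index range of a kernel starting at start_idx in a trace of
# length n; NULL when fully outside
kernel_span <- function(start_idx, klen, n) {
  i0 <- max(1L, start_idx)
  i1 <- min(n, start_idx + klen - 1L)
  if (i0 > i1) return(NULL)
  k0 <- i0 - start_idx + 1L
  list(i = i0:i1, k = k0:(k0 + (i1 - i0)))
}

#' Generate the Vm trace and its ground truth for one session
#'
#' Assembles the noise-free signal (PSP per test stimulus with per-trial
#' amplitude, late depolarization on hit/miss trials, lick ramp per
#' bout), adds Ornstein-Uhlenbeck background, white noise, and spikes
#' drawn from an inhomogeneous Poisson rate model with stereotyped
#' waveforms, and records the ground truth needed for parameter-recovery
#' tests.
#'
#' @param cfg a [sim_config()].
#' @param beh output of [simulate_behavior()].
#' @return list: `vm` (the recorded trace), `vm_clean` (noise-free
#'   signal, incl. resting Vm), `spike_times`, `psp_amps` (per test
#'   trial), `truth` (per-cell true `psp_amp`, `dvm_late`, `dvm_lick`,
#'   `dvm_lick_onset` computed from the clean trace).
#' @export
generate_vm <- function(cfg, beh) {
  fs <- cfg$sample_rate
  n <- as.integer(round(cfg$session_duration_s * fs))
  clean <- numeric(n)
  kp <- psp_kernel(cfg); kl <- late_kernel(cfg)
  delivered <- beh$trials[!beh$trials$aborted, ]
  test <- delivered[delivered$type == "test", ]
  psp_amps <- pmax(0, stats::rnorm(nrow(test), cfg$psp$amp_mean,
                                   cfg$psp$amp_sd))
  for (i in seq_len(nrow(test))) {
    i0 <- as.integer(round(test$time[i] * fs)) + 1L
    sp_ <- kernel_span(i0, length(kp), n)
    if (!is.null(sp_))
      clean[sp_$i] <- clean[sp_$i] + psp_amps[i] * kp[sp_$k]
    amp_l <- if (test$outcome[i] == "hit") cfg$late$amp
             else cfg$late$amp * cfg$late$miss_scale
    if (amp_l != 0) {
      sp_ <- kernel_span(i0, length(kl), n)
      if (!is.null(sp_))
        clean[sp_$i] <- clean[sp_$i] + amp_l * kl[sp_$k]
    }
  }
  # lick ramps: every bout in the final stream (spontaneous + responses)
  all_bouts <- segment_bouts(beh$lick_times, gap_s = 1.0)
  if (cfg$lick_ramp$amp != 0) {
    for (i in seq_len(nrow(all_bouts))) {
      plateau <- all_bouts$offset[i] - all_bouts$onset[i]
      kr <- ramp_kernel(cfg, plateau)
      i0 <- as.integer(round((all_bouts$onset[i] -
                                cfg$lick_ramp$lead_time_s) * fs)) + 1L
      sp_ <- kernel_span(i0, length(kr), n)
      if (!is.null(sp_))
        clean[sp_$i] <- clean[sp_$i] + cfg$lick_ramp$amp * kr[sp_$k]
    }
  }
  # background fluctuations + measurement noise
  if (cfg$ou_sigma_mv > 0) {
    a <- exp(-1 / (cfg$ou_tau_s * fs))
    ou <- as.numeric(stats::filter(
      stats::rnorm(n, 0, cfg$ou_sigma_mv * sqrt(1 - a^2)), a,
      method = "recursive"))
  } else ou <- numeric(n)
  # spikes: inhomogeneous Poisson on the subthreshold depolarization
  sp <- cfg$spikes
  lam_of <- function(idx) pmin(sp$max_rate_hz,
                               sp$rate_at_rest_hz *
                                 exp(sp$gain_per_mv * (clean[idx] + ou[idx])))
  edge <- 2
  n_cand <- stats::rpois(1, sp$max_rate_hz *
                           (cfg$session_duration_s - 2 * edge))
  cand <- sort(stats::runif(n_cand, edge, cfg$session_duration_s - edge))
  cand_idx <- as.integer(round(cand * fs)) + 1L
  keep <- stats::runif(n_cand) < lam_of(cand_idx) / sp$max_rate_hz
  spk <- (cand_idx[keep] - 1L) / fs
  if (length(spk) > 1) {               # absolute refractoriness
    ok <- rep(TRUE, length(spk)); last <- spk[1]
    for (i in 2:length(spk)) {
      if (spk[i] - last < sp$min_isi_s) ok[i] <- FALSE else last <- spk[i]
    }
    spk <- spk[ok]
  }
  vm <- clean + ou +
    (if (cfg$noise_sigma_mv > 0) stats::rnorm(n, 0, cfg$noise_sigma_mv)
     else 0)
  if (length(spk)) {
    w <- as.integer(round(sp$waveform_width_s * fs))
    wave <- sp$waveform_amp_mv * (1 - abs(-w:w) / w)
    for (t0 in spk) {
      sp_ <- kernel_span(as.integer(round(t0 * fs)) + 1L - w,
                         length(wave), n)
      if (!is.null(sp_)) vm[sp_$i] <- vm[sp_$i] + wave[sp_$k]
    }
  }
  clean <- clean + cfg$vm_rest_mv
  vm <- vm + cfg$vm_rest_mv
  truth <- clean_trace_truth(cfg, beh, clean)
  list(vm = vm, vm_clean = clean, spike_times = spk,
       psp_amps = psp_amps, truth = truth)
}

# True per-cell metrics: window statistics of the noise-free trace after
# the same AP-removal (median) filtering the pipeline applies. The filter
# slightly attenuates sharp PSP peaks; that smoothing is part of the
# estimand (the analysis measures the peak of the filtered average), so
# ground truth is defined on the filtered noise-free signal and recovery
# error quantifies noise, spikes and trial sampling only.
clean_trace_truth <- function(cfg, beh, clean) {
  fs <- cfg$sample_rate
  clean <- remove_spikes_median(clean, fs)
  n <- length(clean)
  win_mean_at <- function(events, w) {
    v <- vapply(events, function(e) {
      i0 <- as.integer(round((e + w[1]) * fs)) + 1L
      i1 <- as.integer(round((e + w[2]) * fs))
      if (i0 < 1 || i1 > n) return(NA_real_)
      mean(clean[i0:i1])
    }, numeric(1))
    v
  }
  delivered <- beh$trials[!beh$trials$aborted, ]
  hits <- delivered$time[delivered$type == "test" &
                           delivered$outcome == "hit"]
  hits <- hits[hits > 1 & hits < cfg$session_duration_s - 2]
  truth <- list(dvm_late = NA_real_, dvm_lick = NA_real_,
                psp_amp = NA_real_, dvm_lick_onset = NA_real_,
                n_hits = length(hits))
  if (length(hits)) {
    bl <- win_mean_at(hits, c(-0.005, 0))
    peak <- vapply(hits, function(e) {
      i0 <- as.integer(round(e * fs)) + 2L
      i1 <- as.integer(round((e + 0.05) * fs)) + 1L
      max(clean[i0:i1])
    }, numeric(1))
    # true metrics follow the same definition as the pipeline, applied to
    # the trial-averaged noise-free trace
    truth$psp_amp <- mean(peak) - mean(bl)
    truth$dvm_late <- mean(win_mean_at(hits, c(0.05, 0.25))) - mean(bl)
    truth$dvm_lick <- mean(win_mean_at(hits, c(0.25, 1.0))) - mean(bl)
  }
  sel <- select_spontaneous_bouts(segment_bouts(beh$lick_times, 1.0),
                                  beh$stim_times)
  on <- sel$bout_onsets
  on <- on[on > 1.5 & on < cfg$session_duration_s - 1.5]
  if (length(on)) {
    truth$dvm_lick_onset <-
      mean(win_mean_at(on, c(-0.1, 0.1))) -
      mean(win_mean_at(on, c(-1.0, -0.6)))
    truth$n_selected_bouts <- length(on)
  }
  truth
}

#' Simulate one complete synthetic session
#'
#' Combines [simulate_behavior()] and [generate_vm()] and renders the
#' lick-sensor trace (30 ms unit pulses at each tongue contact plus
#' sensor noise), returning a [session_recording()] together with the
#' generator's ground truth.
#'
#' @param cfg a [sim_config()] (see [cell_type_params()]).
#' @param meta metadata list for the emitted session.
#' @return a `sim_session` list: `session` (a `session_recording` whose
#'   `catch_times` carry the virtual stimulus times), `truth` (scheduler
#'   log, true spike times and bout onsets, per-trial PSP amplitudes,
#'   per-cell true metrics).
#' @export
simulate_session <- function(cfg = sim_config(), meta = list()) {
  beh <- simulate_behavior(cfg)
  gv <- generate_vm(cfg, beh)
  fs <- cfg$sample_rate
  fl <- cfg$lick_sample_rate
  nl <- as.integer(round(cfg$session_duration_s * fl))
  lick_trace <- stats::rnorm(nl, 0, 0.02)
  pw <- as.integer(round(0.03 * fl))
  for (t0 in beh$lick_times) {
    i0 <- as.integer(round(t0 * fl)) + 1L
    i1 <- min(nl, i0 + pw - 1L)
    if (i0 >= 1 && i0 <= nl) lick_trace[i0:i1] <- lick_trace[i0:i1] + 1
  }
  s <- session_recording(gv$vm, lick_trace, fs, fl,
                         stim_times = beh$stim_times,
                         valve_times = beh$valve_times,
                         catch_times = beh$catch_times,
                         meta = meta)
  structure(list(session = s,
                 truth = list(trials = beh$trials,
                              lick_times = beh$lick_times,
                              spont_bouts = beh$spont_bouts,
                              spike_times = gv$spike_times,
                              psp_amps = gv$psp_amps,
                              cell = gv$truth)),
            class = "sim_session")
}

#' Simulate a cohort of recordings
#'
#' Generates one session per cell with per-cell RNG substreams derived
#' from a master seed, assigning cells to mice (about two cells per
#' mouse, as in typical awake whole-cell datasets). The default cohort
#' mirrors the published design: 31 S2-p and 22 M1-p cells in trained
#' mice, 14 S2-p and 12 M1-p cells in naive mice.
#'
#' @param spec data frame with columns `group`, `projection`, `n_cells`.
#' @param seed master seed (integer).
#' @param out_dir optional directory; when given, each session is written
#'   via [write_session()] under `<out_dir>/<cell_id>` and a ground-truth
#'   manifest is written as `ground_truth.json`.
#' @param cells_per_mouse cells recorded per mouse (default 2).
#' @param apply_fn optional function applied to each `sim_session` as it
#'   is generated; when given, only its return values are kept and the
#'   full sessions are discarded, so large cohorts can be processed in
#'   bounded memory.
#' @param ... overrides forwarded to [cell_type_params()] (e.g.
#'   `session_duration_s`).
#' @return list of `sim_session` objects (or of `apply_fn` results),
#'   with a `manifest` attribute data frame of true per-cell metrics.
#' @export
simulate_cohort <- function(spec = data.frame(
                              group = rep(c("good_performer", "naive"),
                                          each = 2),
                              projection = rep(c("S2-p", "M1-p"), 2),
                              n_cells = c(31, 22, 14, 12)),
                            seed = 1, out_dir = NULL,
                            cells_per_mouse = 2, apply_fn = NULL, ...) {
  set.seed(seed)
  total <- sum(spec$n_cells)
  cell_seeds <- sample.int(.Machine$integer.max - 1, total)
  sessions <- vector("list", total)
  manifest <- list()
  k <- 0
  for (r in seq_len(nrow(spec))) {
    for (i in seq_len(spec$n_cells[r])) {
      k <- k + 1
      set.seed(cell_seeds[k])
      cfg <- cell_type_params(spec$group[r], spec$projection[r], ...)
      mouse <- sprintf("%s_m%02d", abbreviate_group(spec$group[r]),
                       ceiling(i / cells_per_mouse) +
                         100 * match(spec$projection[r], c("S2-p", "M1-p")))
      cell <- sprintf("cell%03d", k)
      ss <- simulate_session(cfg, meta = list(
        mouse_id = mouse, cell_id = cell,
        projection_target = spec$projection[r], group = spec$group[r],
        liquid_junction_corrected = FALSE))
      sessions[[k]] <- if (is.null(apply_fn)) ss else apply_fn(ss)
      manifest[[k]] <- data.frame(
        cell_id = cell, mouse_id = mouse, group = spec$group[r],
        projection = spec$projection[r],
        true_psp_amp = ss$truth$cell$psp_amp,
        true_dvm_late = ss$truth$cell$dvm_late,
        true_dvm_lick = ss$truth$cell$dvm_lick,
        true_dvm_lick_onset = ss$truth$cell$dvm_lick_onset,
        n_true_spikes = length(ss$truth$spike_times))
      if (!is.null(out_dir)) {
        write_session(ss$session, file.path(out_dir, cell))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  attr(sessions, "manifest") <- manifest
  sessions
}

abbreviate_group <- function(g) if (g == "good_performer") "gp" else "nv"
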