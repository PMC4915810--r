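no_spike_cfg <- function(...) {
  cfg <- sim_config(...)
  cfg$spikes$rate_at_rest_hz <- 0
  cfg
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(catch_fraction = 0.2),
               class = "vmdetect_validation_error")
  expect_error(sim_config(iti_range = c(-1, 5)),
               class = "vmdetect_validation_error")
  expect_error(sim_config(bout_lick_rate_hz = 0),
               class = "vmdetect_validation_error")
  cfg <- cell_type_params("naive", "M1-p")
  expect_equal(cfg$p_hit, 0.31)
  expect_equal(cfg$psp$amp_mean, 12.2)
})

test_that("the scheduler aborts trials with recent licking", {
  cfg <- sim_config(session_duration_s = 300)
  # no licks -> no aborts
  set.seed(2)
  log1 <- schedule_trials(cfg, numeric())
  expect_false(any(log1$aborted))
  expect_true(all(diff(log1$time) >= cfg$iti_range[1] - 1e-9))
  expect_true(all(diff(log1$time) <= cfg$iti_range[2] + 1e-9))

  # continuous licking -> everything aborted, nothing delivered
  set.seed(3)
  log2 <- schedule_trials(cfg, seq(0, 300, by = 0.2))
  expect_true(all(log2$aborted))
})

test_that("catch fraction concentrates at its configured value", {
  set.seed(17)
  cfg <- sim_config(session_duration_s = 62000, catch_fraction = 0.45)
  log <- schedule_trials(cfg, numeric())
  expect_gt(nrow(log), 9000)
  frac <- mean(log$type == "catch")
  expect_lt(abs(frac - 0.45), 0.02)
})

test_that("behavior simulation respects the abort rule on its own output", {
  set.seed(29)
  cfg <- cell_type_params("good_performer", "S2-p",
                          session_duration_s = 400)
  b <- simulate_behavior(cfg)
  delivered <- b$trials[!b$trials$aborted, ]
  expect_gt(nrow(delivered), 10)
  for (t0 in delivered$time) {
    expect_equal(sum(b$lick_times >= t0 - cfg$abort_lookback_s &
                       b$lick_times < t0), 0)
  }
})

test_that("parsing simulator streams reproduces the scheduler's outcomes", {
  set.seed(37)
  cfg <- cell_type_params("good_performer", "S2-p",
                          session_duration_s = 500)
  b <- simulate_behavior(cfg)
  t <- build_trial_table(b$stim_times, b$catch_times, b$lick_times)
  delivered <- b$trials[!b$trials$aborted, ]
  ord <- order(delivered$time)
  expect_equal(t$outcome, delivered$outcome[ord])
  expect_equal(t$stim_time, delivered$time[ord])
  # hit reaction times agree with the generator's draws
  hit <- t$outcome == "hit"
  expect_equal(t$reaction_time[hit],
               delivered$reaction_time[ord][hit], tolerance = 1e-9)
})

test_that("deterministic extremes: always/never responding", {
  set.seed(41)
  cfg <- sim_config(session_duration_s = 300, p_hit = 1, p_fa = 0,
                    spont_bout_rate_per_min = 0)
  b <- simulate_behavior(cfg)
  t <- build_trial_table(b$stim_times, b$catch_times, b$lick_times)
  p <- summarize_performance(t)
  expect_equal(p$hit_rate, 1)
  expect_equal(p$fa_rate, 0)
  expect_true(is.finite(p$d_prime))
})

test_that("identical seeds give identical sessions", {
  gen <- function() {
    set.seed(99)
    cfg <- cell_type_params("naive", "S2-p", session_duration_s = 40)
    simulate_session(cfg)
  }
  a <- gen(); b <- gen()
  expect_identical(a$session$vm_trace, b$session$vm_trace)
  expect_identical(a$session$lick_trace, b$session$lick_trace)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  expect_identical(a$truth$trials, b$truth$trials)
})

test_that("silent configuration yields a constant trace at rest", {
  set.seed(43)
  cfg <- no_spike_cfg(session_duration_s = 40, ou_sigma_mv = 0,
                      noise_sigma_mv = 0, p_fa = 0,
                      spont_bout_rate_per_min = 0)
  cfg$psp$amp_mean <- 0; cfg$psp$amp_sd <- 0
  cfg$late$amp <- 0; cfg$lick_ramp$amp <- 0
  beh <- simulate_behavior(cfg)
  gv <- generate_vm(cfg, beh)
  expect_equal(unique(gv$vm), cfg$vm_rest_mv)
  expect_length(gv$spike_times, 0)
})

test_that("a noiseless PSP is recovered at its configured amplitude", {
  set.seed(47)
  cfg <- no_spike_cfg(session_duration_s = 120, ou_sigma_mv = 0,
                      noise_sigma_mv = 0, p_fa = 0, p_hit = 1,
                      spont_bout_rate_per_min = 0)
  cfg$psp$amp_mean <- 8; cfg$psp$amp_sd <- 0
  cfg$late$amp <- 0; cfg$lick_ramp$amp <- 0
  beh <- simulate_behavior(cfg)
  gv <- generate_vm(cfg, beh)
  # on the unfiltered trace the peak equals the configured amplitude
  # (kernel is peak-normalised); restrict to trials clear of lick ramps
  stims <- beh$stim_times
  m <- suppressWarnings(align_trials(gv$vm, cfg$sample_rate, stims))
  a <- average_response(m)
  expect_equal(psp_amplitude(a$mean, a$time), 8, tolerance = 0.01)
  # the AP-removal median filter attenuates the sharp peak slightly;
  # ground truth is therefore defined on the filtered signal
  expect_lt(gv$truth$psp_amp, 8)
  expect_gt(gv$truth$psp_amp, 8 * 0.9)
})

test_that("cohort generation is reproducible and correctly sized", {
  spec <- data.frame(group = "good_performer",
                     projection = c("S2-p", "M1-p"), n_cells = c(3, 2))
  s1 <- simulate_cohort(spec, seed = 7, session_duration_s = 30)
  s2 <- simulate_cohort(spec, seed = 7, session_duration_s = 30)
  expect_length(s1, 5)
  expect_identical(s1[[3]]$session$vm_trace, s2[[3]]$session$vm_trace)
  man <- attr(s1, "manifest")
  expect_equal(nrow(man), 5)
  expect_equal(sum(man$projection == "S2-p"), 3)
  # streaming mode returns apply_fn results with the same manifest
  s3 <- simulate_cohort(spec, seed = 7, session_duration_s = 30,
                        apply_fn = function(ss)
                          length(ss$truth$spike_times))
  expect_identical(attr(s3, "manifest")$n_true_spikes, unlist(s3))
})

test_that("the end-to-end pipeline produces coherent session analyses", {
  set.seed(53)
  cfg <- cell_type_params("good_performer", "S2-p",
                          session_duration_s = 300)
  ss <- simulate_session(cfg, meta = list(mouse_id = "mA",
                                          cell_id = "cA"))
  a <- analyze_session(ss$session)
  expect_s3_class(a$trial_table, "trial_table")
  expect_equal(nrow(a$trial_table),
               sum(!ss$truth$trials$aborted))
  expect_gt(a$evoked_hit$n_trials_used, 0)
  expect_true(is.finite(a$evoked_hit$psp_amplitude))
  expect_true(is.finite(a$lick_mod$dvm_lick_onset))
  # detected licks match the generator's contact times
  expect_equal(length(a$licks), length(ss$truth$lick_times))
  expect_lt(max(abs(a$licks - ss$truth$lick_times)), 1e-3)
})
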