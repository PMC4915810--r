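test_that("lick detection finds pulse onsets and debounces bounce", {
  fs <- 1000
  # all-zero trace -> no licks
  expect_length(detect_licks(rep(0, 10 * fs), fs, threshold = 0.5), 0)

  # single rectangular pulse at 5.00 s
  tr <- rep(0, 10 * fs)
  tr[(5 * fs + 1):(5 * fs + 30)] <- 1
  expect_equal(detect_licks(tr, fs, threshold = 0.5), 5.0)

  # two pulses 30 ms apart with 50 ms debounce merge into one event
  tr2 <- rep(0, 10 * fs)
  tr2[(5 * fs + 1):(5 * fs + 10)] <- 1
  tr2[(5 * fs + 41):(5 * fs + 50)] <- 1        # 30 ms gap after pulse end
  expect_equal(detect_licks(tr2, fs, threshold = 0.5, debounce_s = 0.05),
               5.0)
  # same pulses with a shorter debounce resolve as two licks
  expect_length(detect_licks(tr2, fs, threshold = 0.5, debounce_s = 0.02),
                2)

  expect_error(detect_licks(c(0, NA, 0), fs),
               class = "vmdetect_validation_error")
})

test_that("trial classification follows the 1 s half-open reward window", {
  # hit with 0.3 s reaction time
  t <- build_trial_table(10.0, numeric(), 10.3)
  expect_equal(t$outcome, "hit")
  expect_equal(t$reaction_time, 0.3)

  # no lick in window -> miss
  expect_equal(build_trial_table(10.0, numeric(), 11.5)$outcome, "miss")

  # catch trial with lick at +1.2 s (outside [0,1)) -> correct rejection
  expect_equal(build_trial_table(numeric(), 10.0, 11.2)$outcome,
               "correct_rejection")
  # window is half-open: lick exactly at +1.0 s does not count
  expect_equal(build_trial_table(10.0, numeric(), 11.0)$outcome, "miss")
  expect_equal(build_trial_table(10.0, numeric(), 10.0)$outcome, "hit")

  expect_error(build_trial_table(c(10, 10.5), numeric(), numeric()),
               class = "vmdetect_validation_error")
})

test_that("outcome counts partition trials on random event streams", {
  set.seed(303)
  for (rep in 1:40) {
    n_tr <- sample(5:25, 1)
    times <- cumsum(runif(n_tr, 1.5, 4))
    is_test <- runif(n_tr) < 0.55
    licks <- sort(runif(sample(0:30, 1), 0, max(times) + 2))
    t <- build_trial_table(times[is_test], times[!is_test], licks)
    expect_equal(nrow(t), n_tr)
    expect_equal(sum(t$outcome %in% c("hit", "miss")), sum(is_test))
    expect_equal(sum(t$outcome %in% c("false_alarm", "correct_rejection")),
                 sum(!is_test))
    # agrees with the literal trial-by-trial oracle
    expect_equal(t$outcome,
                 naive_classify_trials(times[is_test], times[!is_test],
                                       licks))
    # reaction times, when present, lie in (0, 1]
    rt <- t$reaction_time[!is.na(t$reaction_time)]
    expect_true(all(rt >= 0 & rt < 1))
  }
})

test_that("d-prime matches the normal-quantile definition and correction", {
  # equal rates -> 0 by symmetry
  expect_equal(compute_d_prime(5, 10, 5, 10), 0)
  # worked value against the quantile oracle
  expect_equal(compute_d_prime(77, 100, 17, 100),
               qnorm(0.77) - qnorm(0.17), tolerance = 1e-12)
  # FAR = 0 corrected to 1/(2N) before the quantile
  expect_equal(compute_d_prime(8, 10, 0, 10),
               qnorm(0.8) - qnorm(0.05), tolerance = 1e-12)
  # HR = 1 corrected to 1 - 1/(2N), N of the rate being corrected
  expect_equal(compute_d_prime(20, 20, 3, 10),
               qnorm(1 - 1 / 40) - qnorm(0.3), tolerance = 1e-12)
  expect_error(compute_d_prime(0, 0, 0, 5),
               class = "vmdetect_validation_error")
})

test_that("d-prime is antisymmetric, monotone, and finite at the extremes", {
  for (n in c(5, 10, 40)) {
    for (h in 0:n) {
      for (f in c(0, 1, n %/% 2, n)) {
        d <- compute_d_prime(h, n, f, n)
        expect_true(is.finite(d))
        # swapping HR and FAR negates d'
        expect_equal(compute_d_prime(f, n, h, n), -d, tolerance = 1e-12)
      }
    }
    # monotone increasing in hits, decreasing in false alarms
    dh <- vapply(0:n, function(h) compute_d_prime(h, n, 2, n), numeric(1))
    expect_true(all(diff(dh) > 0))
    df <- vapply(0:n, function(f) compute_d_prime(2, n, f, n), numeric(1))
    expect_true(all(diff(df) < 0))
  }
})

test_that("performance gates classify d' into training groups", {
  expect_equal(classify_performance(2.12), "good_performer")
  expect_equal(classify_performance(1.0), "indeterminate")
  expect_equal(classify_performance(0.03), "naive")
  # boundary values are indeterminate (strict inequalities)
  expect_equal(classify_performance(1.1), "indeterminate")
  expect_equal(classify_performance(0.9), "indeterminate")
})

test_that("reaction-time summaries average hit trials", {
  t1 <- build_trial_table(10, numeric(), 10.317)
  expect_equal(reaction_times(t1)$mean, 0.317)
  t2 <- build_trial_table(c(10, 20), numeric(), c(10.2, 20.4))
  expect_equal(reaction_times(t2)$mean, 0.3)
  t3 <- build_trial_table(10, numeric(), numeric())
  expect_equal(reaction_times(t3)$flag, "no_hits")
})

test_that("simulated reaction times recover the configured mean", {
  set.seed(55)
  cfg <- cell_type_params("good_performer", "S2-p",
                          session_duration_s = 2800)
  b <- simulate_behavior(cfg)
  rt <- b$trials$reaction_time[b$trials$outcome %in% "hit" &
                                 !is.na(b$trials$reaction_time)]
  expect_gte(length(rt), 100)
  sem <- sd(rt) / sqrt(length(rt))
  expect_lt(abs(mean(rt) - 0.317), 3 * sem)
  # truncation: all latencies inside (0.05, 1.0)
  all_rt <- b$trials$reaction_time[!is.na(b$trials$reaction_time)]
  expect_true(all(all_rt > 0.05 & all_rt < 1.0))
})
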