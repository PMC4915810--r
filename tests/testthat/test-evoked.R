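test_that("trial alignment places events at t = 0 with the right shape", {
  fs <- 20000
  tr <- rep(-60, 10 * fs)
  m <- align_trials(tr, fs, 5.0, window = c(-1, 2))
  expect_equal(dim(m), c(1, 3 * fs + 1))
  expect_true(all(m == -60))

  # a delta 0.1 s after the stim lands at the t = 0.1 column
  tr2 <- rep(0, 10 * fs)
  tr2[round(5.1 * fs) + 1] <- 7
  m2 <- align_trials(tr2, fs, 5.0)
  tm <- attr(m2, "time")
  expect_equal(m2[1, which.min(abs(tm - 0.1))], 7)

  # 30 events at 20 kHz -> 30 x 60001 matrix
  tr3 <- rep(0, 120 * fs)
  ev <- seq(2, 119 - 2, length.out = 30)
  m3 <- align_trials(tr3, fs, ev)
  expect_equal(dim(m3), c(30, 60001))

  # events too close to the edge are dropped with a warning
  expect_warning(m4 <- align_trials(tr, fs, c(0.2, 5)), "dropped")
  expect_equal(nrow(m4), 1)
})

test_that("averaging reduces to the row for identical trials and cancels noise", {
  fs <- 1000
  tr <- sin(seq(0, 20, length.out = 20 * fs))
  m <- align_trials(tr, fs, c(5, 5, 5), window = c(-0.5, 0.5))
  a <- average_response(m)
  expect_equal(a$mean, m[1, ])
  # symmetric rows average to zero
  m2 <- rbind(rep(1, 11), rep(-1, 11))
  attr(m2, "time") <- seq(-0.005, 0.005, by = 0.001)
  expect_equal(average_response(m2)$mean, rep(0, 11))
  expect_equal(average_response(m2, rows = integer())$flag, "no_trials")

  # CLT: mean of noisy rows approaches the kernel
  set.seed(13)
  kernel <- 5 * exp(-(0:999) / 200)
  rows <- t(replicate(30, kernel + rnorm(1000, 0, 2)))
  attr(rows, "time") <- (0:999) / fs
  err <- max(abs(average_response(rows)$mean - kernel))
  expect_lt(mean(abs(average_response(rows)$mean - kernel)),
            3 * 2 / sqrt(30))
})

test_that("PSP amplitude is peak minus baseline on the averaged trace", {
  fs <- 20000
  tm <- seq(-0.1, 0.2, by = 1 / fs)
  tr <- rep(-65, length(tm))
  tr[tm > 0.005 & tm < 0.015] <- -57
  expect_equal(psp_amplitude(tr, tm), 8)
  expect_equal(psp_amplitude(rep(-60, length(tm)), tm), 0)
})

test_that("delta-Vm obeys window algebra and offset invariance", {
  fs <- 20000
  tm <- seq(-0.5, 1.5, by = 1 / fs)
  flat <- rep(-62, length(tm))
  expect_equal(delta_vm(flat, tm, c(0.05, 0.25)), 0)

  # +4 mV step over exactly [0.05, 0.25) isolates into the late window
  step <- flat + 4 * (tm >= 0.05 & tm < 0.25)
  expect_equal(delta_vm(step, tm, c(0.05, 0.25)), 4)
  expect_equal(delta_vm(step, tm, c(0.25, 1.0)), 0)

  # adding a constant leaves delta-Vm and PSP amplitude unchanged
  set.seed(4)
  noisy <- flat + rnorm(length(tm))
  for (w in list(c(0.05, 0.25), c(0.25, 1.0), c(0.05, 0.35),
                 c(0.35, 1.0))) {
    expect_equal(delta_vm(noisy + 11.3, tm, w), delta_vm(noisy, tm, w),
                 tolerance = 1e-9)
  }
  expect_equal(psp_amplitude(noisy + 11.3, tm), psp_amplitude(noisy, tm),
               tolerance = 1e-9)
})

test_that("baseline AP rate uses lick-free 2 s pre-trial windows", {
  # no spikes -> 0 Hz
  expect_equal(baseline_ap_rate(numeric(), c(10, 20), numeric())$rate, 0)

  # 8 windows x 2 s with 4 spikes total -> 0.25 Hz
  trials <- seq(10, by = 10, length.out = 8)
  spikes <- c(8.5, 18.2, 38.9, 59.0)
  r <- baseline_ap_rate(spikes, trials, numeric())
  expect_equal(r$rate, 0.25)
  expect_equal(r$total_time_s, 16)
  expect_null(r$flag)

  # windows containing licks are excluded (hand-enumerated)
  licks <- c(18.5, 48.7)               # poisons windows before 20 and 50
  r2 <- baseline_ap_rate(spikes, trials, licks)
  expect_equal(r2$n_windows, 6)
  expect_equal(r2$rate, 3 / 12)        # spike at 18.2 excluded with window
  expect_equal(r2$flag, "low_confidence")

  expect_error(baseline_ap_rate(numeric(), 10, 9.5),
               class = "vmdetect_error")
})

test_that("evoked AP rates are baseline-subtracted and oracle-consistent", {
  # no spikes, baseline 0.5 Hz -> all windows at -0.5 Hz
  r <- evoked_ap_rates(numeric(), c(10, 20), 0.5)
  expect_equal(unname(r), rep(-0.5, 3))

  # one spike at +0.02 s on each of 10 trials -> early = 20 Hz
  stims <- seq(10, by = 5, length.out = 10)
  r2 <- evoked_ap_rates(stims + 0.02, stims, 0)
  expect_equal(r2[["early"]], 20)
  expect_equal(r2[["late"]], 0)

  # random spike trains match the per-spike assignment oracle, and the
  # early/late/lick windows partition (0, 1): totals are conserved
  set.seed(31)
  wins <- list(early = c(0, 0.05), late = c(0.05, 0.25),
               lick = c(0.25, 1.0))
  for (rep in 1:25) {
    stims <- sort(runif(5, 5, 50))
    spikes <- sort(runif(60, 0, 60))
    got <- evoked_ap_rates(spikes, stims, 0)
    for (w in names(wins)) {
      expect_equal(got[[w]], naive_window_rate(spikes, stims, wins[[w]]))
    }
    n_each <- vapply(wins, function(w) sum(vapply(stims, function(s)
      sum(spikes >= s + w[1] & spikes < s + w[2]), numeric(1))),
      numeric(1))
    n_total <- sum(vapply(stims, function(s)
      sum(spikes >= s & spikes < s + 1), numeric(1)))
    expect_equal(sum(n_each), n_total)
  }
})

test_that("PSTH bins conserve spike counts and convert to Hz", {
  # single spike at +0.07 s, one trial, 50 ms bins: only [0.05, 0.10)
  p <- build_psth(10.07, 10, bin_s = 0.05, window = c(-1, 2))
  hot <- which(p$counts > 0)
  expect_length(hot, 1)
  expect_equal(p$bin_edges[hot], 0.05)
  expect_equal(p$rate[hot], 20)

  # no spikes -> all bins at -baseline after subtraction
  p2 <- build_psth(numeric(), c(5, 10), bin_s = 0.05, baseline_rate = 2)
  expect_true(all(p2$rate_sub == -2))

  # conservation: total counts equal spikes inside the PSTH window
  set.seed(8)
  stims <- seq(10, by = 6, length.out = 12)
  spikes <- sort(runif(300, 0, 90))
  for (b in c(0.05, 0.01)) {
    p3 <- build_psth(spikes, stims, bin_s = b, window = c(-1, 2))
    n_in <- sum(vapply(stims, function(s)
      sum(spikes >= s - 1 & spikes < s + 2), numeric(1)))
    expect_equal(sum(p3$counts), n_in)
  }

  # uniform Poisson spiking: every bin close to lambda
  set.seed(88)
  lam <- 20
  stims <- seq(5, by = 4, length.out = 100)
  spikes <- sort(runif(rpois(1, lam * 410), 0, 410))
  p4 <- build_psth(spikes, stims, bin_s = 0.05, window = c(-1, 2))
  expect_lt(max(abs(p4$rate - lam)), 5 * sqrt(lam / (100 * 0.05)))
})

test_that("aggregation weights mice equally at the mouse level", {
  a1 <- aggregate_cells(3.2)
  expect_equal(a1$mean, 3.2)
  expect_equal(a1$flag, "single_unit")
  expect_true(is.na(a1$sem))

  # mouse A has one cell at 0, mouse B three cells at 2:
  # cell mean 1.5, mouse mean 1.0
  v <- c(0, 2, 2, 2)
  mice <- c("A", "B", "B", "B")
  expect_equal(aggregate_cells(v, level = "cell")$mean, 1.5)
  expect_equal(aggregate_cells(v, mice, level = "mouse")$mean, 1.0)
  expect_equal(aggregate_cells(v, mice, level = "mouse")$n, 2)
})

test_that("hit/miss comparison reports the percent increase", {
  # printed-mean magnitudes: 2.63 vs 0.71 mV is a 270% increase after
  # rounding to the nearest 10%
  r <- compare_hit_miss(rep(2.63, 19), rep(0.71, 19))
  expect_equal(round(r$percent_change / 10) * 10, 270)

  r2 <- compare_hit_miss(c(1, 2), c(1, 2))
  expect_equal(r2$percent_change, 0)

  r3 <- compare_hit_miss(c(1, 2), c(-1, 1))
  expect_equal(r3$flag, "undefined_percent_change")
  expect_true(is.na(r3$percent_change))
})
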