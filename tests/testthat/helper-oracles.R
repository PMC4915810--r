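# Independent brute-force oracles used to validate the vectorised
# implementations. These deliberately use the most literal possible
# formulation of each rule.

# per-sample sorted-window running median with reflect padding
naive_median_filter <- function(x, k) {
  n <- length(x)
  h <- (k - 1) %/% 2
  padded <- c(rev(x[2:(h + 1)]), x, rev(x[(n - h):(n - 1)]))
  vapply(seq_len(n), function(i) {
    sort(padded[i:(i + k - 1)])[h + 1]
  }, numeric(1))
}

# trial-by-trial outcome classification by direct scan
naive_classify_trials <- function(stim_times, catch_times, licks,
                                  reward = 1.0) {
  all_t <- sort(c(stim_times, catch_times))
  is_test <- all_t %in% stim_times
  out <- character(length(all_t))
  for (i in seq_along(all_t)) {
    in_win <- licks[licks >= all_t[i] & licks < all_t[i] + reward]
    licked <- length(in_win) > 0
    out[i] <- if (is_test[i]) {
      if (licked) "hit" else "miss"
    } else {
      if (licked) "false_alarm" else "correct_rejection"
    }
  }
  out
}

# per-spike window assignment: rate in [w0, w1) after each stim
naive_window_rate <- function(spike_times, stim_times, w) {
  n <- 0
  for (s in stim_times) {
    for (t in spike_times) if (t >= s + w[1] && t < s + w[2]) n <- n + 1
  }
  n / (length(stim_times) * (w[2] - w[1]))
}

# interval-scan bout segmentation
naive_segment_bouts <- function(licks, gap) {
  licks <- sort(licks)
  bouts <- list()
  cur <- licks[1]
  for (t in licks[-1]) {
    if (t - cur[length(cur)] >= gap) {
      bouts[[length(bouts) + 1]] <- cur
      cur <- t
    } else cur <- c(cur, t)
  }
  bouts[[length(bouts) + 1]] <- cur
  data.frame(onset = vapply(bouts, min, numeric(1)),
             offset = vapply(bouts, max, numeric(1)),
             n_licks = vapply(bouts, length, numeric(1)))
}

# literal rule evaluation for spontaneous-bout selection
naive_select_bouts <- function(bouts, stims, after_stim = 3,
                               after_bout = 1) {
  ok <- logical(nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    on <- bouts$onset[i]
    prior <- stims[stims <= on]
    s_ok <- length(prior) == 0 || (on - max(prior)) >= after_stim
    b_ok <- i == 1 || (on - bouts$offset[i - 1]) >= after_bout
    ok[i] <- s_ok && b_ok
  }
  ok
}

# exact two-tailed rank-sum p-value by enumeration of all assignments of
# ranks to group 1 (small n only)
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact two-tailed signed-rank p-value by enumeration of sign patterns
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# quick flat session for I/O tests
make_toy_session <- function(dur = 2, fs = 20000, stim = numeric(),
                             catch = numeric(), meta = list()) {
  session_recording(vm_trace = rep(-60, dur * fs),
                    lick_trace = rep(0, dur * fs),
                    sample_rate_vm = fs, stim_times = stim,
                    catch_times = catch, meta = meta)
}
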