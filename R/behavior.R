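#' Detect individual lick contacts from the lick-sensor trace
#'
#' A lick contact is the first sample of each supra-threshold excursion of
#' the sensor signal; excursions starting less than `debounce_s` after the
#' end of the previous excursion are merged into it (sensor bounce).
#'
#' @param lick_trace numeric sensor trace (finite).
#' @param sample_rate Hz.
#' @param threshold detection threshold in sensor units. `NULL` (default)
#'   uses the midpoint between the 5th and 95th percentiles of the trace;
#'   for sensors that spend little time in contact this midpoint can sit in
#'   the noise, so pipelines with a known contact level should pass an
#'   explicit threshold (the package's analysis config uses 0.5 for the
#'   simulated 0/1 sensor).
#' @param debounce_s minimum silent gap separating two licks (default
#'   0.05 s).
#' @return strictly increasing numeric vector of contact times (s).
#' @export
detect_licks <- function(lick_trace, sample_rate, threshold = NULL,
                         debounce_s = 0.05) {
  if (!all(is.finite(lick_trace)))
    validation_error("lick_trace contains non-finite samples")
  if (length(lick_trace) == 0) return(numeric())
  if (is.null(threshold))
    threshold <- mean(stats::quantile(lick_trace, c(0.05, 0.95),
                                      names = FALSE))
  above <- lick_trace > threshold
  if (!any(above)) return(numeric())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  exc_start <- starts[r$values]
  exc_end <- ends[r$values]
  keep_start <- exc_start[1]
  times <- numeric(length(exc_start))
  times[1] <- (exc_start[1] - 1) / sample_rate
  k <- 1
  if (length(exc_start) > 1) {
    for (i in 2:length(exc_start)) {
      gap <- (exc_start[i] - exc_end[i - 1] - 1) / sample_rate
      if (gap >= debounce_s) {
        k <- k + 1
        times[k] <- (exc_start[i] - 1) / sample_rate
      }
    }
  }
  times[seq_len(k)]
}

#' Build the trial table from stimulus, catch and lick event streams
#'
#' Test trials (real whisker deflection) are classified hit/miss and catch
#' trials (virtual stimulus time, no deflection) false-alarm/correct-
#' rejection by the presence of a lick in the half-open reward window
#' `[stim, stim + reward_window_s)`.
#'
#' @param stim_times test-trial stimulus times (s), sorted.
#' @param catch_times catch-trial virtual stimulus times (s), sorted.
#' @param licks lick contact times (s) from [detect_licks()].
#' @param reward_window_s reward window duration (default 1 s).
#' @return a `trial_table` data frame with columns `trial_id`, `type`
#'   (`"test"`/`"catch"`), `stim_time`, `outcome` (`"hit"`, `"miss"`,
#'   `"false_alarm"`, `"correct_rejection"`), `first_lick_time` and
#'   `reaction_time` (NA when no lick fell in the window).
#' @export
build_trial_table <- function(stim_times, catch_times, licks,
                              reward_window_s = 1.0) {
  type <- c(rep("test", length(stim_times)), rep("catch", length(catch_times)))
  tt <- c(stim_times, catch_times)
  ord <- order(tt)
  tt <- tt[ord]; type <- type[ord]
  if (length(tt) > 1 && any(diff(tt) < reward_window_s))
    validation_error("overlapping trial windows")
  licks <- sort(licks)
  first_lick <- rep(NA_real_, length(tt))
  for (i in seq_along(tt)) {
    # first lick at or after the stimulus (window is [stim, stim + w))
    j <- findInterval(tt[i], licks, left.open = TRUE) + 1
    if (j <= length(licks) && licks[j] < tt[i] + reward_window_s)
      first_lick[i] <- licks[j]
  }
  licked <- !is.na(first_lick)
  outcome <- ifelse(type == "test",
                    ifelse(licked, "hit", "miss"),
                    ifelse(licked, "false_alarm", "correct_rejection"))
  t <- data.frame(trial_id = seq_along(tt), type = type, stim_time = tt,
                  outcome = outcome, first_lick_time = first_lick,
                  reaction_time = first_lick - tt)
  class(t) <- c("trial_table", "data.frame")
  t
}

#' Signal-detection discriminability with the 1/(2N) rate correction
#'
#' Computes d' = qnorm(HR) - qnorm(FAR). A hit or false-alarm rate
#' measured as exactly 0 or 1 is replaced by `1/(2N)` or `1 - 1/(2N)`,
#' where N is the trial count of that rate, so d' is always finite.
#'
#' @param hits,n_test hit count and number of test trials.
#' @param fas,n_catch false-alarm count and number of catch trials.
#' @return d' (unitless scalar).
#' @export
compute_d_prime <- function(hits, n_test, fas, n_catch) {
  if (n_test < 1 || n_catch < 1)
    validation_error("need at least one test and one catch trial")
  hr <- correct_rate(hits / n_test, n_test)
  far <- correct_rate(fas / n_catch, n_catch)
  stats::qnorm(hr) - stats::qnorm(far)
}

correct_rate <- function(rate, n) {
  if (rate == 0) return(1 / (2 * n))
  if (rate == 1) return(1 - 1 / (2 * n))
  rate
}

#' Classify a recording's task performance from d'
#'
#' Recordings with d' > 1.1 count as good performers, d' < 0.9 as naive;
#' anything between the gates is indeterminate and excluded downstream.
#'
#' @param d_prime scalar d'.
#' @param good_gate,naive_gate classification gates.
#' @return `"good_performer"`, `"naive"` or `"indeterminate"`.
#' @export
classify_performance <- function(d_prime, good_gate = 1.1, naive_gate = 0.9) {
  if (d_prime > good_gate) "good_performer"
  else if (d_prime < naive_gate) "naive"
  else "indeterminate"
}

#' Reaction times of hit trials
#'
#' @param t a `trial_table`.
#' @return list with `times` (per-hit reaction times, s), `mean`, `sem`,
#'   `n`, and `flag` (`"no_hits"` when empty).
#' @export
reaction_times <- function(t) {
  rt <- t$reaction_time[t$outcome == "hit"]
  rt <- rt[!is.na(rt)]
  if (length(rt) == 0)
    return(list(times = numeric(), mean = NA_real_, sem = NA_real_,
                n = 0L, flag = "no_hits"))
  list(times = rt, mean = mean(rt),
       sem = if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt)) else NA_real_,
       n = length(rt), flag = NULL)
}

#' Summarise behavioral performance of one recording
#'
#' @param t a `trial_table`.
#' @return a `performance_summary` list: `n_test`, `n_catch`, `hit_rate`,
#'   `fa_rate` (uncorrected), `d_prime` (corrected), `mean_reaction_time`,
#'   `group_label`.
#' @export
summarize_performance <- function(t) {
  n_test <- sum(t$type == "test")
  n_catch <- sum(t$type == "catch")
  hits <- sum(t$outcome == "hit")
  fas <- sum(t$outcome == "false_alarm")
  d <- compute_d_prime(hits, n_test, fas, n_catch)
  rt <- reaction_times(t)
  structure(list(n_test = n_test, n_catch = n_catch,
                 hit_rate = hits / n_test, fa_rate = fas / n_catch,
                 d_prime = d, mean_reaction_time = rt$mean,
                 group_label = classify_performance(d)),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "<performance> HR %.2f (%d test) FAR %.2f (%d catch) d' %.2f [%s]\n",
    x$hit_rate, x$n_test, x$fa_rate, x$n_catch, x$d_prime, x$group_label))
  if (is.finite(x$mean_reaction_time %||% NA))
    cat(sprintf("  mean reaction time %.0f ms\n",
                1000 * x$mean_reaction_time))
  invisible(x)
}
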