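#' Detect action potentials in a Vm trace
#'
#' A spike is the peak sample of a supra-threshold excursion whose rising
#' slope exceeds `dvdt_threshold`; detections closer than `refractory_s`
#' to the previous accepted spike are discarded, so two genuine spikes
#' inside one refractory period yield a single detection.
#'
#' The slope is evaluated over a 0.25 ms lag (robust to sample-to-sample
#' measurement noise at 20 kHz), within the 1 ms preceding the
#' threshold crossing.
#'
#' @param vm_trace Vm in mV.
#' @param sample_rate Hz (>= 10 kHz).
#' @param dvdt_threshold rising-slope threshold in mV/ms (default 10).
#' @param peak_threshold absolute peak threshold in mV; default
#'   `median(vm_trace) + 25`.
#' @param refractory_s minimum inter-spike interval (default 2 ms).
#' @return sorted spike times (s); possibly empty.
#' @export
detect_spikes <- function(vm_trace, sample_rate, dvdt_threshold = 10,
                          peak_threshold = NULL, refractory_s = 0.002) {
  stopifnot(sample_rate >= 10000)
  if (is.null(peak_threshold))
    peak_threshold <- stats::median(vm_trace) + 25
  n <- length(vm_trace)
  above <- vm_trace > peak_threshold
  if (!any(above)) return(numeric())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  exc_start <- starts[r$values]
  exc_end <- ends[r$values]
  lag <- max(1L, as.integer(round(sample_rate * 0.00025)))
  pre <- as.integer(round(sample_rate * 0.001))
  peaks <- numeric(0)
  for (i in seq_along(exc_start)) {
    idx <- exc_start[i]:exc_end[i]
    pk <- idx[which.max(vm_trace[idx])]
    # max lagged slope in the 1 ms leading into the excursion
    j0 <- max(lag + 1L, exc_start[i] - pre)
    j1 <- min(n, exc_start[i] + lag)
    jj <- j0:j1
    slope <- (vm_trace[jj] - vm_trace[jj - lag]) * sample_rate / (lag * 1000)
    if (max(slope) > dvdt_threshold) peaks <- c(peaks, pk)
  }
  if (length(peaks) == 0) return(numeric())
  t <- (peaks - 1) / sample_rate
  keep <- rep(TRUE, length(t))
  last <- t[1]
  if (length(t) > 1) {
    for (i in 2:length(t)) {
      if (t[i] - last < refractory_s) keep[i] <- FALSE else last <- t[i]
    }
  }
  t[keep]
}

#' Remove action potentials by median filtering
#'
#' Centered running median with reflect padding at the edges, the
#' standard way to strip 1–2 ms action-potential waveforms from a Vm
#' trace while preserving the subthreshold envelope. The window must be
#' substantially wider than an action potential.
#'
#' @param vm_trace Vm in mV.
#' @param sample_rate Hz.
#' @param median_window_s filter window in seconds (default 8 ms; rounded
#'   to an odd number of samples, minimum 3).
#' @return filtered trace, same length as the input.
#' @export
remove_spikes_median <- function(vm_trace, sample_rate,
                                 median_window_s = 0.008) {
  if (median_window_s < 0.004)
    warning("median window shorter than twice a typical AP width (~2 ms); ",
            "spikes may survive filtering")
  k <- as.integer(round(median_window_s * sample_rate))
  if (k %% 2 == 0) k <- k + 1L
  k <- max(k, 3L)
  n <- length(vm_trace)
  h <- (k - 1L) %/% 2L
  if (n <= h + 1) return(rep(stats::median(vm_trace), n))
  padded <- c(rev(vm_trace[2:(h + 1)]), vm_trace,
              rev(vm_trace[(n - h):(n - 1)]))
  out <- stats::runmed(padded, k, endrule = "keep")
  out[(h + 1):(h + n)]
}

#' Decompose a Vm trace into spikes and subthreshold Vm
#'
#' Convenience wrapper running [detect_spikes()] and
#' [remove_spikes_median()] with one parameter set.
#'
#' @param vm_trace Vm in mV.
#' @param sample_rate Hz.
#' @param dvdt_threshold,peak_threshold,refractory_s see [detect_spikes()].
#' @param median_window_s see [remove_spikes_median()].
#' @return a `subthreshold_decomp` list: `spike_times`, `vm_sub`,
#'   `detection_params`.
#' @export
subthreshold_decomposition <- function(vm_trace, sample_rate,
                                       dvdt_threshold = 10,
                                       peak_threshold = NULL,
                                       refractory_s = 0.002,
                                       median_window_s = 0.008) {
  spikes <- detect_spikes(vm_trace, sample_rate, dvdt_threshold,
                          peak_threshold, refractory_s)
  vm_sub <- remove_spikes_median(vm_trace, sample_rate, median_window_s)
  structure(list(spike_times = spikes, vm_sub = vm_sub,
                 detection_params = list(
                   dvdt_threshold = dvdt_threshold,
                   peak_threshold = peak_threshold,
                   refractory_s = refractory_s,
                   median_window_s = median_window_s)),
            class = "subthreshold_decomp")
}

#' @export
print.subthreshold_decomp <- function(x, ...) {
  cat(sprintf("<subthreshold_decomp> %d spikes, %d subthreshold samples\n",
              length(x$spike_times), length(x$vm_sub)))
  invisible(x)
}
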