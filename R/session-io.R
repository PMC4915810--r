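#' Construct a session recording
#'
#' A `session_recording` bundles the raw data of one whole-cell recording:
#' the membrane-potential trace, the lick-sensor trace, stimulus
#' (whisker-deflection) and water-valve event times, and recording
#' metadata. Times are seconds from recording start; Vm is in mV.
#'
#' @param vm_trace numeric vector, membrane potential in mV.
#' @param lick_trace numeric vector, lick-sensor signal (arbitrary units).
#'   May be sampled at a different rate than the Vm trace.
#' @param sample_rate_vm sampling rate of `vm_trace` in Hz (default 20000).
#' @param sample_rate_lick sampling rate of `lick_trace` in Hz.
#' @param stim_times strictly increasing whisker-stimulus times (s).
#' @param valve_times water-valve opening times (s).
#' @param catch_times virtual stimulus times of catch trials (s), as
#'   logged by the behavioral controller (no whisker deflection occurs).
#' @param meta list with elements `mouse_id`, `cell_id`,
#'   `projection_target` (`"M1-p"` or `"S2-p"`), `group`
#'   (`"good_performer"` or `"naive"`) and `liquid_junction_corrected`
#'   (logical; recordings are conventionally *not* corrected).
#' @return an object of class `session_recording`.
#' @seealso [read_session()], [write_session()]
#' @export
session_recording <- function(vm_trace, lick_trace,
                              sample_rate_vm = 20000,
                              sample_rate_lick = sample_rate_vm,
                              stim_times = numeric(),
                              valve_times = numeric(),
                              catch_times = numeric(),
                              meta = list()) {
  meta_defaults <- list(mouse_id = "mouse0", cell_id = "cell0",
                        projection_target = "S2-p", group = "good_performer",
                        liquid_junction_corrected = FALSE)
  meta <- utils::modifyList(meta_defaults, meta)
  s <- structure(list(vm_trace = as.double(vm_trace),
                      lick_trace = as.double(lick_trace),
                      sample_rate_vm = as.double(sample_rate_vm),
                      sample_rate_lick = as.double(sample_rate_lick),
                      stim_times = as.double(stim_times),
                      valve_times = as.double(valve_times),
                      catch_times = as.double(catch_times),
                      meta = meta),
                 class = "session_recording")
  validate_session(s)
}

#' Validate a session recording
#'
#' Checks the container invariants: finite Vm samples, strictly increasing
#' stimulus times, all event times within the recording, positive sampling
#' rates and recognised metadata labels.
#'
#' @param s a `session_recording`.
#' @return `s` invisibly-checked (returned unchanged) or a validation error.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "session_recording"))
    validation_error("not a session_recording")
  if (length(s$vm_trace) < 1 || !all(is.finite(s$vm_trace)))
    validation_error("vm_trace must be non-empty and finite")
  if (s$sample_rate_vm <= 0 || s$sample_rate_lick <= 0)
    validation_error("sampling rates must be positive")
  dur <- length(s$vm_trace) / s$sample_rate_vm
  if (length(s$stim_times) > 1 && any(diff(s$stim_times) <= 0))
    validation_error("stim_times must be strictly increasing")
  if (length(s$catch_times) > 1 && any(diff(s$catch_times) <= 0))
    validation_error("catch_times must be strictly increasing")
  ev <- c(s$stim_times, s$valve_times, s$catch_times)
  if (length(ev) && (any(ev < 0) || any(ev > dur)))
    validation_error("event times must lie within [0, trace duration]")
  if (!s$meta$projection_target %in% c("M1-p", "S2-p"))
    validation_error("projection_target must be 'M1-p' or 'S2-p'")
  if (!s$meta$group %in% c("good_performer", "naive"))
    validation_error("group must be 'good_performer' or 'naive'")
  s
}

#' @export
print.session_recording <- function(x, ...) {
  dur <- length(x$vm_trace) / x$sample_rate_vm
  cat(sprintf("<session_recording> %s / %s (%s, %s)\n",
              x$meta$mouse_id, x$meta$cell_id,
              x$meta$projection_target, x$meta$group))
  cat(sprintf("  Vm: %.1f s @ %g Hz; lick: %d samples @ %g Hz\n",
              dur, x$sample_rate_vm, length(x$lick_trace),
              x$sample_rate_lick))
  cat(sprintf("  events: %d stimuli, %d catch trials, %d valve openings\n",
              length(x$stim_times), length(x$catch_times),
              length(x$valve_times)))
  invisible(x)
}

# --- on-disk container -----------------------------------------------------
#
# A session is stored as a directory:
#   meta.json                  format tag + rates + sample counts + metadata
#   traces/vm.dat              float64 little-endian, mV
#   traces/lick.dat            float64 little-endian, sensor units
#   events/stimulus_times.dat  float64 little-endian, s
#   events/valve_times.dat     float64 little-endian, s
#   events/catch_times.dat     float64 little-endian, s (optional)
# Raw binary arrays guarantee bit-identical round trips; meta.json makes the
# layout self-describing (flat-binary + sidecar metadata, as in common ephys
# acquisition formats).

CONTAINER_FORMAT <- "vmdetect-session"
CONTAINER_VERSION <- 1L

write_f64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(x), con, size = 8, endian = "little")
  invisible(path)
}

read_f64 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8, endian = "little")
}

#' Write a session recording to a session directory
#'
#' Serialises a [session_recording()] to the package's documented on-disk
#' layout: `meta.json` plus raw little-endian float64 arrays under
#' `traces/` and `events/`. Arrays round-trip bit-identically through
#' [read_session()].
#'
#' @param s a valid `session_recording`.
#' @param path directory to create (must not be an existing non-session
#'   file).
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) format_error(sprintf("cannot create '%s'", path))
  dir.create(file.path(path, "traces"), showWarnings = FALSE)
  dir.create(file.path(path, "events"), showWarnings = FALSE)
  meta <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
               sample_rate_vm = s$sample_rate_vm,
               sample_rate_lick = s$sample_rate_lick,
               n_vm = length(s$vm_trace), n_lick = length(s$lick_trace),
               n_stim = length(s$stim_times),
               n_valve = length(s$valve_times),
               n_catch = length(s$catch_times),
               meta = s$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_f64(s$vm_trace, file.path(path, "traces", "vm.dat"))
  write_f64(s$lick_trace, file.path(path, "traces", "lick.dat"))
  write_f64(s$stim_times, file.path(path, "events", "stimulus_times.dat"))
  write_f64(s$valve_times, file.path(path, "events", "valve_times.dat"))
  write_f64(s$catch_times, file.path(path, "events", "catch_times.dat"))
  invisible(path)
}

#' Read a session recording from a session directory
#'
#' @param path a directory written by [write_session()].
#' @return a validated [session_recording()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) format_error(sprintf("no session at '%s'", path))
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) format_error("missing dataset 'meta.json'")
  m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(m$format, CONTAINER_FORMAT))
    format_error("not a vmdetect session container")
  need <- c(file.path("traces", "vm.dat"), file.path("traces", "lick.dat"),
            file.path("events", "stimulus_times.dat"),
            file.path("events", "valve_times.dat"))
  for (f in need)
    if (!file.exists(file.path(path, f)))
      format_error(sprintf("missing dataset '%s'", f))
  s <- structure(list(
    vm_trace = read_f64(file.path(path, "traces", "vm.dat"), m$n_vm),
    lick_trace = read_f64(file.path(path, "traces", "lick.dat"), m$n_lick),
    sample_rate_vm = m$sample_rate_vm,
    sample_rate_lick = m$sample_rate_lick,
    stim_times = read_f64(file.path(path, "events", "stimulus_times.dat"),
                          m$n_stim),
    valve_times = read_f64(file.path(path, "events", "valve_times.dat"),
                           m$n_valve),
    catch_times = {
      cp <- file.path(path, "events", "catch_times.dat")
      if (file.exists(cp)) read_f64(cp, m$n_catch %||% 0) else numeric()
    },
    meta = m$meta), class = "session_recording")
  validate_session(s)
}

#' Concatenate acquisition sweeps into one continuous session
#'
#' Acquisition systems often record short fixed-length sweeps (e.g. 1 min).
#' This helper concatenates per-sweep Vm/lick arrays and maps sweep-local
#' event times to continuous session time.
#'
#' @param sweeps list of lists, each with `vm_trace`, `lick_trace`,
#'   `stim_times`, `valve_times` (sweep-local seconds).
#' @param sample_rate_vm,sample_rate_lick sampling rates (Hz).
#' @param meta metadata list, see [session_recording()].
#' @return a `session_recording` spanning all sweeps.
#' @export
concat_sweeps <- function(sweeps, sample_rate_vm = 20000,
                          sample_rate_lick = sample_rate_vm, meta = list()) {
  offset <- 0
  vm <- list(); lick <- list(); st <- list(); vt <- list()
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    vm[[i]] <- sw$vm_trace
    lick[[i]] <- sw$lick_trace %||% numeric()
    st[[i]] <- (sw$stim_times %||% numeric()) + offset
    vt[[i]] <- (sw$valve_times %||% numeric()) + offset
    offset <- offset + length(sw$vm_trace) / sample_rate_vm
  }
  session_recording(unlist(vm), unlist(lick), sample_rate_vm,
                    sample_rate_lick, unlist(st), unlist(vt), meta)
}

# --- trial-table export ----------------------------------------------------

TRIAL_COLS <- c("trial_id", "type", "stim_time", "outcome",
                "first_lick_time", "reaction_time")

#' Export a trial table to CSV
#'
#' Writes one row per trial with the fixed column order
#' `trial_id, type, stim_time, outcome, first_lick_time, reaction_time`.
#' Absent lick/reaction times are written as empty fields. The file
#' re-imports losslessly with [import_trial_table()].
#'
#' @param t a trial table (see [build_trial_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trial_table <- function(t, path) {
  stopifnot(all(TRIAL_COLS %in% names(t)))
  utils::write.csv(t[, TRIAL_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Re-import a trial table written by [export_trial_table()]
#'
#' @param path CSV path.
#' @return a `trial_table` data frame.
#' @export
import_trial_table <- function(path) {
  t <- utils::read.csv(path, colClasses = c(trial_id = "integer",
                                            type = "character",
                                            stim_time = "numeric",
                                            outcome = "character",
                                            first_lick_time = "numeric",
                                            reaction_time = "numeric"))
  class(t) <- c("trial_table", "data.frame")
  t
}
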