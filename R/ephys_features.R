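# Action-potential feature extraction from current-clamp sweeps: AP
# detection by a one-sided dV/dt threshold crossing, rise speed as the peak
# of the voltage derivative over the rising phase, and the per-cell mean of
# the first AP's rise speed across suprathreshold steps. Units: time in
# seconds, voltage in mV, derivative in V/s (1 mV/ms = 1 V/s).

#' Current-clamp sweep container
#'
#' @param time sample times in seconds, uniformly spaced.
#' @param voltage membrane potential in mV, same length as `time`.
#' @param sampling_rate sampling rate in Hz; must match the time grid to
#'   1e-9 relative tolerance.
#' @param step_current stimulus step amplitude in pA (metadata only).
#' @return An object of class `cc_sweep`.
#' @export
cc_sweep <- function(time, voltage, sampling_rate, step_current = NA_real_) {
  if (length(time) != length(voltage)) {
    ps_stop("time and voltage must have equal length")
  }
  if (length(time) < 5L) ps_stop("sweep too short (%d samples)", length(time))
  stopifnot_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) ps_stop("sampling_rate must be > 0")
  dt <- diff(time)
  expected <- 1 / sampling_rate
  if (any(dt <= 0) || any(abs(dt - expected) > 1e-9 * expected)) {
    ps_stop("non-uniform sampling: time must increase in steps of 1/%g s",
            sampling_rate)
  }
  structure(
    list(time = as.numeric(time), voltage = as.numeric(voltage),
         sampling_rate = sampling_rate, step_current = step_current),
    class = "cc_sweep"
  )
}

#' @export
print.cc_sweep <- function(x, ...) {
  cat(sprintf("<cc_sweep> %d samples at %g kHz, step %g pA\n",
              length(x$time), x$sampling_rate / 1000, x$step_current))
  invisible(x)
}

# central-difference derivative in V/s from mV samples; one-sided at the ends
voltage_derivative <- function(voltage, sampling_rate) {
  n <- length(voltage)
  d <- numeric(n)
  d[1L] <- (voltage[2L] - voltage[1L]) * sampling_rate
  d[n] <- (voltage[n] - voltage[n - 1L]) * sampling_rate
  idx <- 2:(n - 1L)
  d[idx] <- (voltage[idx + 1L] - voltage[idx - 1L]) * sampling_rate / 2
  d / 1000 # mV/s -> V/s
}

#' Detect action potentials in a sweep
#'
#' An AP is registered at each upward crossing of the dV/dt threshold that is
#' followed by a voltage peak of at least `min_peak` within `peak_window`
#' seconds; crossings within `merge_window` of the previous accepted crossing
#' are merged (refractory rule). The threshold is one-sided, so a
#' time-reversed trace never yields APs.
#'
#' @param sweep a [cc_sweep()].
#' @param dvdt_threshold detection threshold on dV/dt, V/s; default 10.
#' @param min_peak minimum voltage peak, mV; default -10.
#' @param merge_window refractory merge window, seconds; default 1 ms.
#' @param peak_window window to search for the peak, seconds; default 5 ms.
#' @return Numeric vector of AP times (seconds, at the threshold crossing);
#'   empty when no AP is found.
#' @export
detect_aps <- function(sweep, dvdt_threshold = 10, min_peak = -10,
                       merge_window = 1e-3, peak_window = 5e-3) {
  if (!inherits(sweep, "cc_sweep")) ps_stop("expected a cc_sweep")
  d <- voltage_derivative(sweep$voltage, sweep$sampling_rate)
  above <- d >= dvdt_threshold
  crossings <- which(!above[-length(above)] & above[-1L]) + 1L
  if (!length(crossings)) return(numeric())

  n <- length(sweep$voltage)
  peak_samples <- max(1L, round(peak_window * sweep$sampling_rate))
  ap_times <- numeric()
  last_time <- -Inf
  for (i in crossings) {
    t_i <- sweep$time[i]
    if (t_i - last_time < merge_window) next
    window <- i:min(n, i + peak_samples)
    if (max(sweep$voltage[window]) >= min_peak) {
      ap_times <- c(ap_times, t_i)
      last_time <- t_i
    }
  }
  ap_times
}

#' AP rise speed: peak dV/dt over the rising phase
#'
#' The maximum of the central-difference voltage derivative between the
#' detection crossing and the following voltage peak, in V/s.
#'
#' @param sweep a [cc_sweep()].
#' @param ap_time an AP time returned by [detect_aps()] for this sweep.
#' @param peak_window as in [detect_aps()].
#' @return Rise speed in V/s (positive for a real AP).
#' @export
ap_rise_speed <- function(sweep, ap_time, peak_window = 5e-3) {
  if (!inherits(sweep, "cc_sweep")) ps_stop("expected a cc_sweep")
  i <- which.min(abs(sweep$time - ap_time))
  if (abs(sweep$time[i] - ap_time) > 1.5 / sweep$sampling_rate) {
    ps_stop("ap_time %g s not on the sweep's time grid", ap_time)
  }
  n <- length(sweep$voltage)
  peak_samples <- max(1L, round(peak_window * sweep$sampling_rate))
  window <- i:min(n, i + peak_samples)
  peak_idx <- window[which.max(sweep$voltage[window])]
  rising <- i:peak_idx
  if (length(rising) < 1L) ps_stop("empty rising segment at %g s", ap_time)
  d <- voltage_derivative(sweep$voltage, sweep$sampling_rate)
  max(d[rising])
}

#' Per-cell AP rise speed
#'
#' For each suprathreshold sweep (at least one detected AP), the rise speed
#' of its *first* AP; the cell value is the mean across those sweeps.
#' Subthreshold sweeps are ignored.
#'
#' @param sweeps a list of [cc_sweep()] objects.
#' @param ... passed to [detect_aps()].
#' @return A list: `cell_rise_speed` (V/s), `per_sweep` (`data.frame` with
#'   `sweep`, `step_current`, `n_aps`, `first_ap_time`,
#'   `first_ap_rise_speed`; subthreshold sweeps have NA features).
#' @export
cell_rise_speed <- function(sweeps, ...) {
  if (inherits(sweeps, "cc_sweep")) sweeps <- list(sweeps)
  if (!length(sweeps)) ps_stop("no sweeps supplied")
  rows <- lapply(seq_along(sweeps), function(j) {
    sw <- sweeps[[j]]
    aps <- detect_aps(sw, ...)
    if (length(aps)) {
      data.frame(sweep = j, step_current = sw$step_current,
                 n_aps = length(aps), first_ap_time = aps[1L],
                 first_ap_rise_speed = ap_rise_speed(sw, aps[1L]))
    } else {
      data.frame(sweep = j, step_current = sw$step_current, n_aps = 0L,
                 first_ap_time = NA_real_, first_ap_rise_speed = NA_real_)
    }
  })
  per_sweep <- do.call(rbind, rows)
  supra <- per_sweep$n_aps > 0L
  if (!any(supra)) ps_stop("no suprathreshold sweeps (no APs detected)")
  list(cell_rise_speed = mean(per_sweep$first_ap_rise_speed[supra]),
       per_sweep = per_sweep)
}
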