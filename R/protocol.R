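#' Voltage step protocol
#'
#' Describes the transjunctional voltage (Vj) schedule of a dual whole-cell
#' recording: one step per trace, each preceded by a stretch at the holding
#' potential.
#'
#' @param vj_steps Ordered transjunctional voltages (mV), one per step.
#' @param step_duration Step length (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param pre_step_baseline Seconds recorded at the holding potential before
#'   each step.
#' @param inter_step_holding Holding transjunctional voltage (mV).
#' @return An object of class `"gj_protocol"`.
#' @export
step_protocol <- function(vj_steps, step_duration, sampling_rate = 10000,
                          pre_step_baseline = 0.1, inter_step_holding = 0) {
  stopifnot(is.numeric(vj_steps), length(vj_steps) > 0, all(is.finite(vj_steps)))
  if (step_duration <= 0) stop("'step_duration' must be > 0")
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  if (pre_step_baseline < 0) stop("'pre_step_baseline' must be >= 0")
  structure(list(vj_steps = vj_steps, step_duration = step_duration,
                 sampling_rate = sampling_rate,
                 pre_step_baseline = pre_step_baseline,
                 inter_step_holding = inter_step_holding),
            class = "gj_protocol")
}

#' Standard +/-20..100 mV gating protocol
#'
#' The voltage-clamp protocol used throughout: pulses from +/-20 to +/-100 mV
#' in 20 mV increments, alternating polarity, 7 s per step by default (long
#' enough that the final 500 ms is at gating steady state for the kinetic
#' defaults used here).
#'
#' @inheritParams step_protocol
#' @param vj_max Largest absolute voltage (mV).
#' @export
vj_protocol <- function(step_duration = 7, vj_max = 100, sampling_rate = 10000,
                        pre_step_baseline = 0.1) {
  v <- seq(20, vj_max, by = 20)
  step_protocol(as.numeric(rbind(v, -v)), step_duration, sampling_rate,
                pre_step_baseline)
}

#' @export
print.gj_protocol <- function(x, ...) {
  cat(sprintf("Vj step protocol: %d steps of %.3g s at %g Hz (baseline %.3g s at %g mV)\n",
              length(x$vj_steps), x$step_duration, x$sampling_rate,
              x$pre_step_baseline, x$inter_step_holding))
  cat("  Vj (mV):", paste(x$vj_steps, collapse = ", "), "\n")
  invisible(x)
}

#' Recording noise description
#'
#' White Gaussian noise of standard deviation `sigma` added to the simulated
#' current and then low-pass filtered at `acquisition_cutoff`, mimicking an
#' analog acquisition chain (1 kHz by default).
#'
#' @param sigma Pre-filter white-noise SD (pA).
#' @param acquisition_cutoff Low-pass cutoff applied before storage (Hz).
#' @return An object of class `"gj_noise"`.
#' @export
recording_noise <- function(sigma = 1, acquisition_cutoff = 1000) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  structure(list(sigma = sigma, acquisition_cutoff = acquisition_cutoff),
            class = "gj_noise")
}
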