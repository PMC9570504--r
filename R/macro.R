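# Macroscopic junctional current reduction: peak and steady-state currents,
# conductances, normalized steady-state conductance, pair-level coupling.

baseline_current <- function(trace) {
  n_pre <- round(trace$t_on * trace$sampling_rate)
  if (n_pre >= 10) mean(trace$samples[seq_len(n_pre)]) else 0
}

#' Peak junctional current of a step
#'
#' The peak amplitude is measured at the beginning of the junctional current:
#' the mean over `[t_on + blank, t_on + blank + peak_window]`, baseline
#' subtracted.  The blank skips the capacitive transient; the window is kept
#' shorter than any plausible gating relaxation.
#'
#' @param trace A [gj_trace()].
#' @param blank Seconds skipped after step onset (default 5 ms).
#' @param peak_window Averaging window length (s, default 10 ms).
#' @return Peak current (pA, signed).
#' @export
measure_peak <- function(trace, blank = 0.005, peak_window = 0.010) {
  stopifnot(inherits(trace, "gj_trace"))
  fs <- trace$sampling_rate
  i0 <- round((trace$t_on + blank) * fs) + 1L
  i1 <- round((trace$t_on + blank + peak_window) * fs)
  if (i1 > length(trace$samples))
    stop("peak window [blank, blank + peak_window] exceeds the trace")
  mean(trace$samples[i0:i1]) - baseline_current(trace)
}

#' Steady-state junctional current of a step
#'
#' Mean of the final `window` seconds (500 ms by default) of the trace,
#' baseline subtracted.
#'
#' @inheritParams measure_peak
#' @param window Averaging window at the end of the step (s).
#' @return Steady-state current (pA, signed).
#' @export
measure_steady_state <- function(trace, window = 0.5) {
  stopifnot(inherits(trace, "gj_trace"))
  fs <- trace$sampling_rate
  step_len <- length(trace$samples) / fs - trace$t_on
  if (step_len < window)
    stop(sprintf("step (%.3g s) shorter than the %.3g s steady-state window",
                 step_len, window))
  n <- length(trace$samples)
  mean(trace$samples[(n - round(window * fs) + 1L):n]) - baseline_current(trace)
}

#' Reduce a trace set to per-step conductances and pair-level coupling
#'
#' Computes, per step, the peak and steady-state currents and conductances
#' (`g = i / vj`, pA/mV = nS) and the normalized steady-state conductance
#' `g_norm = g_ss / g_peak`.  The pair-level coupling conductance `g_j` is
#' taken from the +/-20 mV steps (where voltage gating is negligible), and
#' the pair is called coupled when `g_j` exceeds a detection threshold.
#' Pairs with `g_j` at or above `gating_exclusion` (9 nS) are flagged for
#' exclusion from gating analysis, to limit voltage-clamp errors.
#'
#' @param traces A `"gj_traceset"`.
#' @param blank,peak_window Passed to [measure_peak()].
#' @param ss_window Passed to [measure_steady_state()].
#' @param detection_threshold Coupling detection threshold (nS).
#' @param gating_exclusion Exclusion threshold (nS).
#' @return A data frame of class `"gj_macro_summary"` with columns `vj`,
#'   `i_peak`, `i_ss`, `g_peak`, `g_ss`, `g_norm`, and attributes `g_j`,
#'   `coupled`, `gating_excluded`.
#' @export
macro_summary <- function(traces, blank = 0.005, peak_window = 0.010,
                          ss_window = 0.5, detection_threshold = 0.01,
                          gating_exclusion = 9) {
  stopifnot(length(traces) > 0)
  vj <- vapply(traces, `[[`, 0, "vj")
  if (any(vj == 0)) {
    warning("skipping step(s) with vj = 0: conductance undefined")
    traces <- traces[vj != 0]
    vj <- vj[vj != 0]
  }
  i_peak <- vapply(traces, measure_peak, 0, blank = blank,
                   peak_window = peak_window)
  i_ss <- vapply(traces, measure_steady_state, 0, window = ss_window)
  g_peak <- i_peak / vj
  g_ss <- i_ss / vj
  out <- data.frame(vj = vj, i_peak = i_peak, i_ss = i_ss,
                    g_peak = g_peak, g_ss = g_ss, g_norm = g_ss / g_peak)
  low <- abs(vj) == min(abs(vj))
  g_j <- mean(g_ss[low])
  structure(out, class = c("gj_macro_summary", "data.frame"),
            g_j = g_j,
            coupled = is.finite(g_j) && g_j > detection_threshold,
            gating_excluded = is.finite(g_j) && g_j >= gating_exclusion)
}

#' @export
print.gj_macro_summary <- function(x, ...) {
  cat(sprintf("Macroscopic summary: g_j = %.3g nS, coupled = %s, gating-excluded = %s\n",
              attr(x, "g_j"), attr(x, "coupled"), attr(x, "gating_excluded")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
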