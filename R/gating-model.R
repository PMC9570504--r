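#' Voltage-gating model of a gap junction channel population
#'
#' Bundles the Boltzmann steady-state parameters (per transjunctional-voltage
#' polarity) with the kinetic and conductance parameters needed to simulate
#' junctional currents.  The steady-state open probability at transjunctional
#' voltage `vj` is `1 / (1 + exp(a * (|vj| - v0)))` with the polarity-matched
#' `(v0, a)`; `k0` sets the kinetic time scale (it is the opening and closing
#' rate at `|vj| = v0`, where the two are equal) and does not affect the
#' stationary law.
#'
#' A closing transition enters the residual (subconductance) state with
#' probability `1 - p_fullclose`, otherwise the fully closed state; both
#' gated states reopen with the same voltage-dependent rate, so lumping them
#' leaves the open-state stationary probability Boltzmann-distributed.
#'
#' @param v0_pos,v0_neg Half-deactivation voltage (mV, absolute value) for the
#'   positive and negative polarity. `v0_neg` defaults to `v0_pos`.
#' @param a_pos,a_neg Gating sensitivity (1/mV), `>= 0`.
#' @param k0 Rate scale at `|vj| = v0` (1/s).
#' @param gamma_main Main-open-state unitary conductance (pS).
#' @param gamma_res Residual-state unitary conductance (pS),
#'   `0 <= gamma_res <= gamma_main` (equality makes gating invisible in the
#'   current, a useful degenerate case).
#' @param p_fullclose Probability that a closing event enters the fully closed
#'   rather than the residual state.
#' @param rate_max Overflow guard: opening/closing rates are clamped to this
#'   value (1/s) with a warning.
#' @param label Construct label carried into simulated trace metadata.
#' @return An object of class `"gj_gating_model"`.
#' @seealso [gj_preset()] for models populated from published parameter
#'   tables, [simulate_channels()], [steady_state_curve()].
#' @export
gating_model <- function(v0_pos, v0_neg = v0_pos, a_pos, a_neg = a_pos,
                         k0 = 0.5, gamma_main = 192, gamma_res = 0,
                         p_fullclose = 0, rate_max = 1e4, label = "custom") {
  stopifnot(is.numeric(v0_pos), is.numeric(v0_neg),
            is.numeric(a_pos), is.numeric(a_neg),
            length(v0_pos) == 1L, length(v0_neg) == 1L)
  if (a_pos < 0 || a_neg < 0)
    stop("gating sensitivities 'a_pos'/'a_neg' must be >= 0")
  if (k0 <= 0) stop("'k0' must be > 0")
  if (gamma_res < 0 || gamma_res > gamma_main)
    stop("'gamma_res' must satisfy 0 <= gamma_res <= gamma_main")
  if (p_fullclose < 0 || p_fullclose > 1)
    stop("'p_fullclose' must lie in [0, 1]")
  if (rate_max <= 0) stop("'rate_max' must be > 0")
  structure(list(v0_pos = v0_pos, v0_neg = v0_neg,
                 a_pos = a_pos, a_neg = a_neg, k0 = k0,
                 gamma_main = gamma_main, gamma_res = gamma_res,
                 p_fullclose = p_fullclose, rate_max = rate_max,
                 label = label),
            class = "gj_gating_model")
}

#' @export
print.gj_gating_model <- function(x, ...) {
  cat("Gap junction gating model:", x$label, "\n")
  cat(sprintf("  Boltzmann (+): v0 = %.1f mV, a = %.3f /mV\n", x$v0_pos, x$a_pos))
  cat(sprintf("  Boltzmann (-): v0 = %.1f mV, a = %.3f /mV\n", x$v0_neg, x$a_neg))
  cat(sprintf("  gamma_main = %.0f pS, gamma_res = %.1f pS (Gmin = %.3f)\n",
              x$gamma_main, x$gamma_res, x$gamma_res / x$gamma_main))
  cat(sprintf("  k0 = %.2f /s, p_fullclose = %.2f\n", x$k0, x$p_fullclose))
  invisible(x)
}

polarity_params <- function(model, vj) {
  pos <- vj >= 0
  list(v0 = ifelse(pos, model$v0_pos, model$v0_neg),
       a  = ifelse(pos, model$a_pos, model$a_neg))
}

#' Boltzmann steady-state normalized conductance
#'
#' Evaluates the two-state Boltzmann law
#' `Gmin + (1 - Gmin) / (1 + exp(a * (|vj| - v0)))` with the polarity-matched
#' parameters, where `Gmin = gamma_res / gamma_main` is the normalized
#' residual conductance.  This is the stationary normalized macroscopic
#' conductance of the model when closing events all enter the residual state
#' (`p_fullclose = 0`); with `p_fullclose > 0` the macroscopic floor is
#' reduced to `Gmin * (1 - p_fullclose)` while the open-state occupancy is
#' unchanged.
#'
#' @param model A [gating_model()].
#' @param vj Transjunctional voltage(s), mV.  Sign selects the polarity.
#' @return Normalized conductance in `[Gmin, 1]`, vectorized over `vj`.
#' @export
steady_state_curve <- function(model, vj) {
  stopifnot(inherits(model, "gj_gating_model"), is.numeric(vj), all(is.finite(vj)))
  p <- polarity_params(model, vj)
  gmin <- model$gamma_res / model$gamma_main
  gmin + (1 - gmin) / (1 + exp(p$a * (abs(vj) - p$v0)))
}

#' Voltage-dependent opening and closing rates
#'
#' Splits the Boltzmann exponent symmetrically between the opening rate
#' `alpha = k0 * exp(-a (|vj| - v0) / 2)` and the closing rate
#' `beta = k0 * exp(+a (|vj| - v0) / 2)`, so that `alpha / (alpha + beta)`
#' equals the Boltzmann open probability exactly at every voltage.
#'
#' @inheritParams steady_state_curve
#' @param rate_max Clamp applied to both rates (1/s); defaults to the model's
#'   guard.  Clamping triggers a warning.
#' @return A list with numeric components `alpha` and `beta` (1/s), each
#'   vectorized over `vj`.
#' @export
gating_rates <- function(model, vj, rate_max = model$rate_max) {
  stopifnot(inherits(model, "gj_gating_model"), is.numeric(vj), all(is.finite(vj)))
  p <- polarity_params(model, vj)
  expo <- p$a * (abs(vj) - p$v0) / 2
  alpha <- model$k0 * exp(-expo)
  beta  <- model$k0 * exp(expo)
  if (any(alpha > rate_max) || any(beta > rate_max)) {
    warning(sprintf("gating rate exceeded %g /s and was clamped", rate_max))
    alpha <- pmin(alpha, rate_max)
    beta  <- pmin(beta, rate_max)
  }
  list(alpha = alpha, beta = beta)
}
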