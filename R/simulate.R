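#' Construct a junctional current trace
#'
#' @param vj Step transjunctional voltage (mV).
#' @param samples Current samples (pA) at a uniform sampling interval.
#' @param sampling_rate Hz.
#' @param t_on Step onset time (s) from the start of the trace (the samples
#'   before `t_on` are recorded at the holding potential).
#' @param metadata Named list (construct label, seed, channel count, ...).
#' @return An object of class `"gj_trace"`.
#' @export
gj_trace <- function(vj, samples, sampling_rate, t_on = 0, metadata = list()) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  structure(list(vj = vj, samples = samples, sampling_rate = sampling_rate,
                 t_on = t_on, metadata = metadata),
            class = "gj_trace")
}

#' @export
print.gj_trace <- function(x, ...) {
  cat(sprintf("Junctional current trace: Vj = %g mV, %d samples at %g Hz (%.3g s)\n",
              x$vj, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.null(x$metadata$construct))
    cat("  construct:", x$metadata$construct, "\n")
  invisible(x)
}

#' @export
print.gj_traceset <- function(x, ...) {
  cat(sprintf("Set of %d junctional current traces", length(x)))
  if (!is.null(attr(x, "construct"))) cat(" [", attr(x, "construct"), "]", sep = "")
  cat("\n  Vj (mV):", paste(vapply(x, `[[`, 0, "vj"), collapse = ", "), "\n")
  invisible(x)
}

stationary_init <- function(n_channels, p_open, p_fullclose) {
  u <- runif(n_channels)
  st <- integer(n_channels)            # 0 open
  gated <- u >= p_open
  # split the non-open mass between residual (1) and fully closed (2) in the
  # stationary ratio (1 - p_fullclose) : p_fullclose
  st[gated] <- ifelse(runif(sum(gated)) < p_fullclose, 2L, 1L)
  st
}

sim_segment <- function(states, n, rates, p_fullclose, dt, keep_states) {
  p_leave <- 1 - exp(-rates$beta * dt)
  p_back  <- 1 - exp(-rates$alpha * dt)
  sim_markov_cpp(states, n, p_leave, p_fullclose, p_back, keep_states)
}

#' Simulate junctional current traces
#'
#' Evolves `n_channels` independent three-state gating chains (main open /
#' residual / fully closed) in discrete time at the sampling interval, one
#' trace per protocol step.  Per-sample transition probabilities are
#' `1 - exp(-rate * dt)` with the voltage-dependent rates of
#' [gating_rates()]; channels start each step from the stationary
#' distribution at the holding potential.  The trace current is
#' `vj * (n_open * gamma_main + n_res * gamma_res) / 1000` pA plus filtered
#' Gaussian recording noise.
#'
#' @param model A [gating_model()].
#' @param protocol A [step_protocol()].
#' @param n_channels Number of channels in the junction (>= 1).
#' @param noise A [recording_noise()]; default noise-free.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param return_states If `TRUE` and `n_channels == 1`, each trace carries
#'   the integer state path (0 open, 1 residual, 2 closed) as `$states`.
#' @return A `"gj_traceset"`: list of [gj_trace()] objects.
#' @export
simulate_channels <- function(model, protocol, n_channels = 1,
                              noise = recording_noise(0), seed = NULL,
                              return_states = FALSE) {
  stopifnot(inherits(model, "gj_gating_model"), inherits(protocol, "gj_protocol"))
  if (n_channels < 1) stop("'n_channels' must be >= 1")
  fs <- protocol$sampling_rate
  dt <- 1 / fs
  if (noise$sigma > 0 && noise$acquisition_cutoff > fs / 2)
    stop("noise acquisition cutoff exceeds the Nyquist frequency")
  all_v <- c(protocol$vj_steps, protocol$inter_step_holding)
  r_all <- gating_rates(model, all_v)
  if (dt * max(r_all$alpha, r_all$beta) > 0.1)
    stop("dt * max(rate) > 0.1: discrete-time stepping invalid at this ",
         "sampling rate; reduce rates or raise the sampling rate")
  if (!is.null(seed)) set.seed(seed)
  keep <- return_states && n_channels == 1
  n_pre  <- round(fs * protocol$pre_step_baseline)
  n_step <- round(fs * protocol$step_duration)
  vh <- protocol$inter_step_holding
  rh <- gating_rates(model, vh)
  p_open_h <- rh$alpha / (rh$alpha + rh$beta)

  traces <- lapply(protocol$vj_steps, function(vj) {
    st <- stationary_init(n_channels, p_open_h, model$p_fullclose)
    rv <- gating_rates(model, vj)
    if (n_pre > 0) {
      pre <- sim_segment(st, n_pre, rh, model$p_fullclose, dt, keep)
      st <- pre$final
    } else pre <- NULL
    stp <- sim_segment(st, n_step, rv, model$p_fullclose, dt, keep)
    g_pre <- if (n_pre > 0)
      pre$n_open * model$gamma_main + pre$n_res * model$gamma_res else numeric(0)
    g_stp <- stp$n_open * model$gamma_main + stp$n_res * model$gamma_res
    i <- c(vh * g_pre, vj * g_stp) / 1000   # pS * mV -> pA
    if (noise$sigma > 0) {
      wn <- rnorm(length(i), sd = noise$sigma)
      i <- i + gauss_filter_vec(wn, noise$acquisition_cutoff, fs)
    }
    tr <- gj_trace(vj, i, fs, t_on = n_pre / fs,
                   metadata = list(construct = model$label, seed = seed,
                                   n_channels = n_channels, holding = vh))
    if (keep) tr$states <- c(if (n_pre > 0) pre$states[, 1] else integer(0),
                             stp$states[, 1])
    tr
  })
  structure(traces, class = "gj_traceset", construct = model$label,
            seed = seed, n_channels = n_channels)
}
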