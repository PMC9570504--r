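# All-point amplitude histograms and sum-of-Gaussians level fitting for
# single-channel records.

#' All-point amplitude histogram
#'
#' Histograms the current samples of the first `window` seconds of the step
#' (the early part of the record, before voltage gating has removed most
#' openings).  Bin width follows Freedman-Diaconis with a floor of 0.05 pA;
#' counts conserve the number of samples.
#'
#' @param x A [gj_trace()] (typically already filtered with
#'   [gaussian_filter()]) or a numeric vector of samples.
#' @param window Seconds from step onset to histogram (`Inf` for the whole
#'   step); ignored for bare numeric input.
#' @param bw Optional bin width override (pA).
#' @return An object of class `"gj_aph"`: list with `mids` (bin centres,
#'   pA), `counts`, `bw` (bin width, pA) and `n` (samples histogrammed).
#' @export
all_point_histogram <- function(x, window = 2, bw = NULL) {
  if (inherits(x, "gj_trace")) {
    fs <- x$sampling_rate
    i0 <- round(x$t_on * fs) + 1L
    i1 <- min(length(x$samples), round((x$t_on + min(window, 1e9)) * fs))
    v <- x$samples[i0:i1]
  } else v <- as.numeric(x)
  if (length(v) == 0) stop("empty segment")
  if (is.null(bw)) {
    iqr <- stats::IQR(v)
    fd <- 2 * iqr / length(v)^(1 / 3)
    # Freedman-Diaconis, but never coarser than ~50 bins across the range:
    # on strongly bimodal segments the IQR can straddle two conductance
    # levels, and the resulting handful of bins cannot carry a Gaussian fit.
    span <- diff(range(v))
    if (span > 0) fd <- min(fd, span / 50)
    bw <- max(fd, 0.05)
  }
  lo <- floor(min(v) / bw) * bw - bw / 2
  breaks <- seq(lo, max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
  structure(list(mids = h$mids, counts = h$counts, bw = bw, n = length(v)),
            class = "gj_aph")
}

#' @export
print.gj_aph <- function(x, ...) {
  cat(sprintf("All-point histogram: %d samples, %d bins of %.3g pA\n",
              x$n, length(x$mids), x$bw))
  invisible(x)
}

#' @export
plot.gj_aph <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "s", xlab = "i (pA)",
                 ylab = "count", ...)
  invisible(x)
}

running_mean <- function(v, w) {
  k <- rep(1 / w, w)
  n <- length(v)
  out <- stats::filter(c(rep(v[1], w), v, rep(v[n], w)), k, sides = 2)
  as.numeric(out[(w + 1):(w + n)])
}

# Prominence-flavoured peak seeding: local maxima of the smoothed counts,
# tall enough relative to the tallest mode, greedily thinned to a minimum
# separation so noise ripples on one level do not spawn extra components.
seed_peaks <- function(h, max_components, min_height = 0.02) {
  w <- max(3L, min(5L, length(h$counts) %/% 6L))
  sm <- running_mean(h$counts, w)
  n <- length(sm)
  if (n < 3) return(integer(0))
  loc <- which(sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) &
                 sm > min_height * max(sm))
  if (length(loc) == 0) return(integer(0))
  # collapse plateaus
  loc <- loc[c(TRUE, diff(loc) > 1)]
  sep <- max(3 * h$bw, 0.2)
  keep <- integer(0)
  for (i in loc[order(sm[loc], decreasing = TRUE)]) {
    if (all(abs(h$mids[i] - h$mids[keep]) >= sep)) keep <- c(keep, i)
    if (length(keep) == max_components) break
  }
  sort(keep)
}

#' Fit conductance levels to an all-point histogram
#'
#' Decomposes an all-point histogram into a sum of 2-4 Gaussian components
#' by least squares on the bin counts, seeded by prominence-based peak
#' detection.  The component nearest 0 pA is the baseline; the main open
#' level is the component farthest from baseline carrying at least
#' `min_weight` of the samples; remaining components are subconductance
#' levels.  The unitary current is `i_j = |mu_open - mu_baseline|`.
#'
#' A unimodal histogram yields a "no events" result (`no_events = TRUE`,
#' `i_j = NA`), not an error.
#'
#' The baseline component must lie close to the zero-current reference
#' (within `baseline_tol`, by default 4 baseline-widths or 0.5 pA,
#' whichever is larger): a stretch in which the channel never fully closes
#' has no zero-current level in its histogram, and accepting the residual
#' level as baseline there would bias the unitary amplitude low.  Such
#' stretches are rejected as "no events".
#'
#' @param h A `"gj_aph"` histogram from [all_point_histogram()].
#' @param max_components Maximum number of Gaussian components (2-4).
#' @param min_weight Minimum sample fraction for the main open component.
#' @param vj Voltage label carried into the result (mV).
#' @param baseline_ref Zero-current reference level (pA), e.g. the mean
#'   pre-step current.
#' @param baseline_tol Maximum allowed distance of the baseline component
#'   from `baseline_ref`; `NULL` for the adaptive default.
#' @return An object of class `"gj_levels"`: `components` data frame
#'   (`mean`, `sd`, `amplitude`, `weight`, `role`), `i_j` (pA, magnitude),
#'   `sign` (sign of the open-level excursion), `n_components`, `rss`,
#'   `no_events`, `vj`.
#' @export
fit_levels <- function(h, max_components = 4, min_weight = 0.05, vj = NA_real_,
                       baseline_ref = 0, baseline_tol = NULL) {
  stopifnot(inherits(h, "gj_aph"))
  max_components <- max(2L, min(4L, as.integer(max_components)))
  pk <- seed_peaks(h, max_components)
  if (length(pk) < 2) {
    return(structure(list(components = NULL, i_j = NA_real_, sign = NA_real_,
                          n_components = length(pk), rss = NA_real_,
                          no_events = TRUE, vj = vj),
                     class = "gj_levels"))
  }
  K <- length(pk)
  m <- h$mids; cts <- h$counts
  s0 <- max(2 * h$bw, 0.1)
  par0 <- c(pmax(cts[pk], 1), m[pk], rep(s0, K))
  span <- diff(range(m)) + h$bw
  # a conductance level is a narrow mode: cap sigma well below the span so
  # no component can degenerate into a broad pedestal under the others
  lower <- c(rep(0, K), rep(min(m) - h$bw, K), rep(h$bw / 3, K))
  upper <- c(rep(Inf, K), rep(max(m) + h$bw, K), rep(span / 4, K))
  model <- function(p) {
    A <- p[1:K]; mu <- p[K + 1:K]; s <- p[2 * K + 1:K]
    rowSums(vapply(1:K, function(k) A[k] * exp(-(m - mu[k])^2 / (2 * s[k]^2)),
                   numeric(length(m))))
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(p) cts - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  A <- p[1:K]; mu <- p[K + 1:K]; s <- p[2 * K + 1:K]
  weight <- A * s * sqrt(2 * pi) / h$bw / h$n
  ord <- order(mu)
  comp <- data.frame(mean = mu[ord], sd = s[ord], amplitude = A[ord],
                     weight = weight[ord], role = "sub",
                     stringsAsFactors = FALSE)
  comp <- comp[comp$weight >= 1e-3, , drop = FALSE]   # null components
  if (nrow(comp) < 2) {
    return(structure(list(components = comp, i_j = NA_real_, sign = NA_real_,
                          n_components = nrow(comp), rss = sum(fit$fvec^2),
                          no_events = TRUE, vj = vj),
                     class = "gj_levels"))
  }
  ib <- which.min(abs(comp$mean - baseline_ref))
  tol <- if (is.null(baseline_tol)) max(0.5, 4 * comp$sd[ib]) else baseline_tol
  if (abs(comp$mean[ib] - baseline_ref) > tol) {
    # no component at the zero-current level: the channel never fully
    # closed in this stretch, so no unbiased amplitude can be measured
    return(structure(list(components = comp, i_j = NA_real_, sign = NA_real_,
                          n_components = nrow(comp), rss = sum(fit$fvec^2),
                          no_events = TRUE, vj = vj),
                     class = "gj_levels"))
  }
  comp$role[ib] <- "baseline"
  cand <- which(comp$role != "baseline" & comp$weight >= min_weight)
  if (length(cand) == 0) {
    return(structure(list(components = comp, i_j = NA_real_, sign = NA_real_,
                          n_components = K, rss = sum(fit$fvec^2),
                          no_events = TRUE, vj = vj),
                     class = "gj_levels"))
  }
  io <- cand[which.max(abs(comp$mean[cand] - comp$mean[ib]))]
  comp$role[io] <- "main_open"
  structure(list(components = comp,
                 i_j = abs(comp$mean[io] - comp$mean[ib]),
                 sign = sign(comp$mean[io] - comp$mean[ib]),
                 n_components = K, rss = sum(fit$fvec^2),
                 no_events = FALSE, vj = vj),
            class = "gj_levels")
}

#' @export
print.gj_levels <- function(x, ...) {
  if (x$no_events) {
    cat("Amplitude estimate: no events (histogram effectively unimodal)\n")
    return(invisible(x))
  }
  cat(sprintf("Amplitude estimate%s: i_j = %.3g pA (%d Gaussian components)\n",
              if (is.finite(x$vj)) sprintf(" at Vj = %g mV", x$vj) else "",
              x$i_j, x$n_components))
  print(x$components, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Filter, histogram and fit levels in one call
#'
#' Convenience wrapper for the standard single-channel amplitude chain:
#' Gaussian low-pass filter at `fc`, all-point histogram over the first
#' `window` seconds of the step, sum-of-Gaussians level fit.
#'
#' @param trace A [gj_trace()].
#' @param fc Analysis filter cutoff (Hz, default 200).
#' @param window Histogram window (s).
#' @param ... Passed to [fit_levels()].
#' @return A `"gj_levels"` object (with the trace's `vj` attached).
#' @export
estimate_amplitudes <- function(trace, fc = 200, window = 2, ...) {
  stopifnot(inherits(trace, "gj_trace"))
  f <- gaussian_filter(trace, fc)
  fit_levels(all_point_histogram(f, window = window), vj = trace$vj, ...)
}
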