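#' Fit the two-state Boltzmann voltage-gating law
#'
#' Fits `g_norm = (g_max - g_min) / (1 + exp(a * (|vj| - v0))) + g_min` to
#' normalized steady-state conductance points of one transjunctional-voltage
#' polarity, by bounded Levenberg-Marquardt least squares with a multistart
#' over the half-deactivation voltage (`v0` in 20, 40, 60, 80 mV).  Bounds:
#' `0 <= g_min, g_max <= 1.5`, `0 <= a <= 1` (1/mV), `0 <= v0 <= 150` (mV).
#' The best converged start (lowest residual sum of squares) is reported.
#'
#' `v0` is the voltage at which the conductance has fallen halfway from
#' `g_max` to `g_min`; `a` is the gating sensitivity.  A fit pinned at
#' `a = 0` (no voltage dependence resolvable) is flagged degenerate.
#'
#' @param object Numeric vector of transjunctional voltages (mV), or a
#'   [macro_summary()] data frame (columns `vj`, `g_norm`).
#' @param ... Passed to methods.
#' @return An object of class `"boltzmann_fit"` with components
#'   `coefficients` (`g_max`, `g_min`, `v0`, `a`), `rss`, `converged`,
#'   `degenerate`, `polarity`, `data` and `n`.  Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()` and
#'   `plot()`.
#' @examples
#' vj <- seq(20, 100, by = 20)
#' g <- 0.24 + (1 - 0.24) / (1 + exp(0.09 * (vj - 39.1)))
#' fit <- fit_boltzmann(vj, g)
#' coef(fit)
#' @export
fit_boltzmann <- function(object, ...) UseMethod("fit_boltzmann")

#' @rdname fit_boltzmann
#' @param g_norm Normalized steady-state conductances matching `object`.
#' @param polarity `"+"` or `"-"`: which voltage polarity to fit.  Points of
#'   the other polarity (and `vj = 0`) are dropped.
#' @param weights Optional least-squares weights (default unweighted).
#' @param starts_v0 Multistart grid for `v0` (mV).
#' @export
fit_boltzmann.default <- function(object, g_norm, polarity = c("+", "-"),
                                  weights = NULL,
                                  starts_v0 = c(20, 40, 60, 80), ...) {
  vj <- object
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(vj), is.numeric(g_norm), length(vj) == length(g_norm))
  keep <- if (polarity == "+") vj > 0 else vj < 0
  keep <- keep & is.finite(g_norm)
  x <- abs(vj[keep])
  y <- g_norm[keep]
  w <- if (is.null(weights)) rep(1, length(x)) else weights[keep]
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct |vj| values on the requested polarity")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; w <- w[ord]

  lower <- c(g_max = 0, g_min = 0, v0 = 0, a = 0)
  upper <- c(g_max = 1.5, g_min = 1.5, v0 = 150, a = 1)
  g_hi <- min(max(y), 1.5)
  g_lo <- max(min(y), 0)
  best <- NULL
  for (v0s in starts_v0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ g_min + (g_max - g_min) / (1 + exp(a * (x - v0))),
        start = list(g_max = g_hi, g_min = g_lo, v0 = v0s, a = 0.1),
        lower = lower, upper = upper, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    out <- structure(list(coefficients = c(g_max = NA_real_, g_min = NA_real_,
                                           v0 = NA_real_, a = NA_real_),
                          rss = NA_real_, converged = FALSE, degenerate = TRUE,
                          polarity = polarity,
                          data = data.frame(vj_abs = x, g_norm = y, w = w),
                          n = length(x)),
                     class = "boltzmann_fit")
    return(out)
  }
  cf <- coef(best$fit)[c("g_max", "g_min", "v0", "a")]
  degenerate <- cf[["a"]] < 1e-4 || cf[["g_max"]] - cf[["g_min"]] < 1e-4
  structure(list(coefficients = cf, rss = best$rss, converged = TRUE,
                 degenerate = degenerate, polarity = polarity,
                 data = data.frame(vj_abs = x, g_norm = y, w = w),
                 n = length(x)),
            class = "boltzmann_fit")
}

#' @rdname fit_boltzmann
#' @export
fit_boltzmann.gj_macro_summary <- function(object, polarity = c("+", "-"), ...) {
  fit_boltzmann(object$vj, object$g_norm, polarity = match.arg(polarity), ...)
}

boltzmann_curve <- function(cf, vj_abs) {
  cf[["g_min"]] + (cf[["g_max"]] - cf[["g_min"]]) /
    (1 + exp(cf[["a"]] * (vj_abs - cf[["v0"]])))
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$vj_abs
       else if (is.list(newdata)) abs(newdata$vj) else abs(newdata)
  if (!object$converged) return(rep(NA_real_, length(x)))
  boltzmann_curve(object$coefficients, x)
}

#' @export
fitted.boltzmann_fit <- function(object, ...) predict(object)

#' @export
residuals.boltzmann_fit <- function(object, ...) object$data$g_norm - fitted(object)

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit (%s polarity, %d points)\n", x$polarity, x$n))
  if (!x$converged) {
    cat("  did not converge from any start\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  g_max = %.3f, g_min = %.3f, v0 = %.1f mV, a = %.3f /mV\n",
              cf[["g_max"]], cf[["g_min"]], cf[["v0"]], cf[["a"]]))
  cat(sprintf("  RSS = %.3g%s\n", x$rss,
              if (x$degenerate) "  [degenerate: no resolvable voltage dependence]" else ""))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  rse <- if (object$converged && object$n > 4)
    sqrt(object$rss / (object$n - 4)) else NA_real_
  structure(list(fit = object, rse = rse), class = "summary.boltzmann_fit")
}

#' @export
print.summary.boltzmann_fit <- function(x, ...) {
  print(x$fit)
  if (is.finite(x$rse))
    cat(sprintf("  residual standard error: %.3g on %d df\n",
                x$rse, x$fit$n - 4))
  invisible(x)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$vj_abs, d$g_norm, xlab = "|Vj| (mV)",
                 ylab = expression(G[j][",ss"]),
                 main = sprintf("Boltzmann fit (%s polarity)", x$polarity),
                 ylim = c(0, max(1, d$g_norm)), ...)
  if (x$converged) {
    xx <- seq(0, max(d$vj_abs) * 1.05, length.out = 200)
    graphics::lines(xx, boltzmann_curve(x$coefficients, xx))
  }
  invisible(x)
}
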