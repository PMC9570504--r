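#' Slope unitary conductance from unitary current amplitudes
#'
#' Regresses unitary current amplitude `i_j` (pA) on absolute
#' transjunctional voltage `|vj|` (mV) with a free intercept.  Amplitudes
#' measured at the same `|vj|` within a cell pair (e.g. the two polarities)
#' are averaged first; each pair then contributes one ordinary
#' least-squares slope, and the slope in pA/mV times 1000 is the unitary
#' conductance in pS.  Also reported is the pooled regression on the
#' pair-averaged `i_j`-`|vj|` points, the standard construction of the
#' published unitary current-voltage plots.
#'
#' @param data Data frame with columns `pair` (identifier), `vj` (mV, either
#'   polarity) and `i_j` (pA, magnitude).
#' @return An object of class `"gamma_fit"`: `per_pair` data frame (`pair`,
#'   `slope_pS`, `intercept_pA`, `n_points`), `mean_slope`/`sd_slope` (pS,
#'   across pairs), `pooled` (named vector: intercept pA, slope pS),
#'   `points` (pair-averaged i-V points) and `n_pairs`.  Supports `print()`,
#'   `coef()`, `predict()` and `plot()`.
#' @export
slope_gamma <- function(data) {
  stopifnot(is.data.frame(data), all(c("pair", "vj", "i_j") %in% names(data)))
  d <- data.frame(pair = as.character(data$pair), av = abs(data$vj),
                  i_j = abs(data$i_j))
  d <- d[is.finite(d$i_j) & is.finite(d$av), ]
  if (nrow(d) == 0) stop("no finite amplitude points")
  # average the polarities / repeats at each |vj| within a pair
  d <- aggregate(i_j ~ pair + av, data = d, FUN = mean)

  per <- lapply(split(d, d$pair), function(p) {
    if (length(unique(p$av)) < 2) return(NULL)
    cf <- coef(lm(i_j ~ av, data = p))
    data.frame(pair = p$pair[1], slope_pS = 1000 * cf[[2]],
               intercept_pA = cf[[1]], n_points = nrow(p))
  })
  dropped <- names(per)[vapply(per, is.null, TRUE)]
  if (length(dropped))
    warning("pair(s) with a single |vj| excluded: ",
            paste(dropped, collapse = ", "))
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no pair contributed >= 2 distinct |vj| values")
  rownames(per) <- NULL

  pts <- aggregate(i_j ~ av, data = d[d$pair %in% per$pair, ], FUN = mean)
  pooled_cf <- coef(lm(i_j ~ av, data = pts))
  structure(list(per_pair = per,
                 mean_slope = mean(per$slope_pS),
                 sd_slope = if (nrow(per) > 1) sd(per$slope_pS) else NA_real_,
                 pooled = c(intercept_pA = pooled_cf[[1]],
                            slope_pS = 1000 * pooled_cf[[2]]),
                 points = pts, n_pairs = nrow(per)),
            class = "gamma_fit")
}

#' @export
coef.gamma_fit <- function(object, ...) object$pooled

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Slope unitary conductance: %.0f +/- %.0f pS (n = %d pairs)\n",
              x$mean_slope, x$sd_slope, x$n_pairs))
  cat(sprintf("  pooled regression: gamma_j = %.0f pS, intercept = %.2f pA\n",
              x$pooled[["slope_pS"]], x$pooled[["intercept_pA"]]))
  invisible(x)
}

#' @export
predict.gamma_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$av
       else if (is.list(newdata)) abs(newdata$vj) else abs(newdata)
  object$pooled[["intercept_pA"]] + object$pooled[["slope_pS"]] / 1000 * x
}

#' @export
plot.gamma_fit <- function(x, ...) {
  graphics::plot(x$points$av, x$points$i_j, xlab = "|Vj| (mV)",
                 ylab = expression(i[j] ~ "(pA)"),
                 main = sprintf("gamma_j = %.0f pS", x$pooled[["slope_pS"]]), ...)
  graphics::abline(x$pooled[["intercept_pA"]], x$pooled[["slope_pS"]] / 1000)
  invisible(x)
}
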