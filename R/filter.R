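# Gaussian low-pass filtering as used in single-channel analysis software:
# the kernel standard deviation in time is sigma_t = 0.1325 / fc, which puts
# the -3 dB point of the frequency response at fc.

gauss_kernel <- function(fc, sampling_rate) {
  sigma_n <- 0.1325 * sampling_rate / fc
  r <- max(1L, ceiling(4 * sigma_n))
  k <- dnorm(seq(-r, r), sd = sigma_n)
  k / sum(k)
}

gauss_filter_vec <- function(x, fc, sampling_rate) {
  if (fc >= sampling_rate / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  k <- gauss_kernel(fc, sampling_rate)
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (n == 0L) return(x)
  # reflect at both edges so the DC gain stays 1 near the boundaries
  pad_l <- x[pmin(n, pmax(1L, seq(r + 1L, 2L, by = -1L)))]
  pad_r <- x[pmin(n, pmax(1L, seq(n - 1L, n - r, by = -1L)))]
  y <- stats::filter(c(pad_l, x, pad_r), k, sides = 2)
  as.numeric(y[(r + 1L):(r + n)])
}

#' Gaussian low-pass filter
#'
#' Convolves the trace with a Gaussian kernel whose -3 dB cutoff is `fc`
#' (kernel sigma in time `0.1325 / fc`, the convention of standard
#' single-channel analysis software).  Edges are handled by reflection and
#' the length is preserved.
#'
#' @param x A [gj_trace()] or a numeric vector.
#' @param fc Cutoff frequency (Hz), must be below Nyquist.
#' @param sampling_rate Required when `x` is a bare numeric vector.
#' @return An object of the same kind as `x`.
#' @export
gaussian_filter <- function(x, fc, sampling_rate = NULL) {
  if (inherits(x, "gj_trace")) {
    x$samples <- gauss_filter_vec(x$samples, fc, x$sampling_rate)
    x$metadata$filter_fc <- fc
    x
  } else {
    if (is.null(sampling_rate))
      stop("'sampling_rate' is required for a bare numeric vector")
    gauss_filter_vec(as.numeric(x), fc, sampling_rate)
  }
}
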