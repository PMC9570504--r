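#' Half-amplitude threshold idealization
#'
#' Classifies each sample of the (200 Hz Gaussian-filtered) step segment as
#' open or closed by a threshold halfway between the baseline and main-open
#' level means, then merges sojourns shorter than the filter dead time
#' `2 * (0.3321 / fc)` (twice the filter rise time) into the flanking
#' sojourn, so band-limited spikes never create events.
#'
#' @param trace A [gj_trace()] (raw; the analysis filter is applied here
#'   unless `fc = NULL`).
#' @param levels A `"gj_levels"` amplitude estimate containing baseline and
#'   main-open components (see [fit_levels()]).
#' @param fc Analysis filter cutoff (Hz); `NULL` to skip filtering.
#' @param dead_time Merge threshold (s); default `2 * 0.3321 / fc`.
#' @return An object of class `"gj_events"`: data frame with columns
#'   `state` (`"open"`/`"closed"`) and `duration` (s), attributes
#'   `dead_time` and `vj`.  If the threshold lies outside the trace range,
#'   an empty event list is returned ("no events").
#' @export
idealize <- function(trace, levels, fc = 200,
                     dead_time = if (is.null(fc)) 0 else 2 * 0.3321 / fc) {
  stopifnot(inherits(trace, "gj_trace"), inherits(levels, "gj_levels"))
  if (levels$no_events)
    return(empty_events(dead_time, trace$vj))
  comp <- levels$components
  mu_b <- comp$mean[comp$role == "baseline"]
  mu_o <- comp$mean[comp$role == "main_open"]
  fs <- trace$sampling_rate
  x <- if (is.null(fc)) trace$samples else gauss_filter_vec(trace$samples, fc, fs)
  x <- x[(round(trace$t_on * fs) + 1L):length(x)]
  thr <- (mu_b + mu_o) / 2
  if (thr <= min(x) || thr >= max(x))
    return(empty_events(dead_time, trace$vj))
  open <- if (mu_o > mu_b) x > thr else x < thr
  r <- rle(open)
  st <- ifelse(r$values, "open", "closed")
  dur <- r$lengths / fs
  m <- merge_short_sojourns(st, dur, dead_time)
  structure(data.frame(state = m$state, duration = m$duration,
                       stringsAsFactors = FALSE),
            class = c("gj_events", "data.frame"),
            dead_time = dead_time, vj = trace$vj)
}

empty_events <- function(dead_time, vj) {
  structure(data.frame(state = character(0), duration = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("gj_events", "data.frame"),
            dead_time = dead_time, vj = vj)
}

# Iteratively absorb the shortest sub-dead-time sojourn into its flanks:
# interior events rejoin the two same-state neighbours into one sojourn,
# edge events are absorbed by their single neighbour.  Merging never
# increases the event count.
merge_short_sojourns <- function(state, duration, dead_time) {
  repeat {
    n <- length(duration)
    if (n <= 1) break
    short <- which(duration < dead_time)
    if (length(short) == 0) break
    i <- short[which.min(duration[short])]
    if (i == 1) {
      duration[2] <- duration[2] + duration[1]
      state <- state[-1]; duration <- duration[-1]
    } else if (i == n) {
      duration[n - 1] <- duration[n - 1] + duration[n]
      state <- state[-n]; duration <- duration[-n]
    } else {
      duration[i - 1] <- duration[i - 1] + duration[i] + duration[i + 1]
      state <- state[-c(i, i + 1)]; duration <- duration[-c(i, i + 1)]
    }
  }
  list(state = state, duration = duration)
}

#' @export
print.gj_events <- function(x, ...) {
  vj <- attr(x, "vj")
  cat(sprintf("Idealized record%s: %d sojourns (%d open), dead time %.2f ms\n",
              if (!is.null(vj) && is.finite(vj)) sprintf(" at Vj = %g mV", vj) else "",
              nrow(x), sum(x$state == "open"), 1000 * attr(x, "dead_time")))
  invisible(x)
}

#' Mean open dwell time per voltage
#'
#' Arithmetic mean of the open-sojourn durations of each idealized record,
#' grouped by transjunctional voltage.  Voltages with no open events are
#' absent from the result (not reported as zero).
#'
#' @param events A `"gj_events"` object or a list of them (each carrying its
#'   `vj` attribute, as produced by [idealize()]).
#' @return Data frame with columns `vj` (mV), `mean_open` (s) and
#'   `n_events`.
#' @export
dwell_stats <- function(events) {
  if (inherits(events, "gj_events")) events <- list(events)
  rows <- lapply(events, function(e) {
    op <- e$duration[e$state == "open"]
    if (length(op) == 0) return(NULL)
    data.frame(vj = attr(e, "vj"), mean_open = mean(op), n_events = length(op))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(vj = numeric(0), mean_open = numeric(0),
                      n_events = integer(0)))
  out <- aggregate(cbind(total = mean_open * n_events, n_events) ~ vj,
                   data = out, FUN = sum)
  data.frame(vj = out$vj, mean_open = out$total / out$n_events,
             n_events = out$n_events)
}
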