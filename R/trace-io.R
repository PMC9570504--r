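# Plain-text trace container.  Each trace block starts with "## trace <i>",
# followed by "# key = value" header lines (required: vj_mV,
# sampling_rate_Hz, construct, seed, n_channels) and one sample (pA) per
# line.  Samples are written with 6 decimals (sub-fA), which is the stated
# round-trip precision.

required_trace_keys <- c("vj_mV", "sampling_rate_Hz", "construct", "seed",
                         "n_channels")

#' Write a trace set to a text file
#'
#' @param traces A `"gj_traceset"` (or plain list of [gj_trace()] objects).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_traces()]
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "gj_trace"))
    md <- tr$metadata
    writeLines(c(
      sprintf("## trace %d", i),
      sprintf("# vj_mV = %.10g", tr$vj),
      sprintf("# sampling_rate_Hz = %.10g", tr$sampling_rate),
      sprintf("# construct = %s", if (is.null(md$construct)) "NA" else md$construct),
      sprintf("# seed = %s", if (is.null(md$seed)) "NA" else format(md$seed)),
      sprintf("# n_channels = %s",
              if (is.null(md$n_channels)) "NA" else format(md$n_channels)),
      sprintf("# t_on_s = %.10g", tr$t_on)), con)
    writeLines(sprintf("%.6f", tr$samples), con)
  }
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#'
#' Malformed headers, missing required keys, or non-numeric sample tokens are
#' rejected with an error naming the offending line.
#'
#' @param path File path.
#' @return A `"gj_traceset"`.
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  starts <- grep("^## trace", lines)
  if (length(lines) > 0 && (length(starts) == 0 || starts[1] != 1)) {
    bad <- setdiff(seq_len(if (length(starts)) starts[1] - 1 else length(lines)),
                   which(!nzchar(trimws(lines))))
    if (length(bad))
      stop(sprintf("line %d: content before the first '## trace' block", bad[1]))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  traces <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):ends[b]]
    offset <- starts[b]                      # global line number of block header
    hdr_idx <- grep("^#", block)
    if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx)))
      stop(sprintf("line %d: header line after sample data",
                   offset + hdr_idx[which(hdr_idx != seq_along(hdr_idx))[1]]))
    hdr <- list()
    for (j in hdr_idx) {
      m <- regmatches(block[j], regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", block[j]))[[1]]
      if (length(m) != 3)
        stop(sprintf("line %d: malformed header '%s'", offset + j, block[j]))
      hdr[[m[2]]] <- trimws(m[3])
    }
    missing <- setdiff(required_trace_keys, names(hdr))
    if (length(missing))
      stop(sprintf("line %d: trace block missing required header key(s): %s",
                   offset, paste(missing, collapse = ", ")))
    samp_lines <- block[setdiff(seq_along(block), hdr_idx)]
    samp_lines_idx <- setdiff(seq_along(block), hdr_idx)
    keepers <- nzchar(trimws(samp_lines))
    samp_lines <- samp_lines[keepers]
    samp_lines_idx <- samp_lines_idx[keepers]
    samples <- suppressWarnings(as.numeric(samp_lines))
    if (anyNA(samples))
      stop(sprintf("line %d: non-numeric sample '%s'",
                   offset + samp_lines_idx[which(is.na(samples))[1]],
                   samp_lines[which(is.na(samples))[1]]))
    traces[[b]] <- gj_trace(
      vj = as.numeric(hdr$vj_mV),
      samples = samples,
      sampling_rate = as.numeric(hdr$sampling_rate_Hz),
      t_on = if (!is.null(hdr$t_on_s)) as.numeric(hdr$t_on_s) else 0,
      metadata = list(construct = hdr$construct,
                      seed = suppressWarnings(as.integer(hdr$seed)),
                      n_channels = suppressWarnings(as.integer(hdr$n_channels))))
  }
  structure(traces, class = "gj_traceset",
            construct = if (length(traces)) traces[[1]]$metadata$construct else NULL)
}
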