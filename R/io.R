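#' Export a trace set to tidy CSV
#'
#' Long format with columns `time`, `site`, `variable`, `value`, `holding`,
#' `replicate`; voltage traces per recorded site plus, for clamped runs, the
#' clamp and baseline-subtracted synaptic currents.
#'
#' @param ts A `trace_set` from [simulate_cable()].
#' @param path Output CSV path.
#' @param replicate Replicate label stored in the file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(ts, path, replicate = 1L) {
  hold <- if (ts$meta$clamped) ts$meta$holding else NA_real_
  blocks <- lapply(seq_along(ts$meta$record), function(j) {
    data.frame(time = ts$time, site = ts$meta$record[j], variable = "voltage",
               value = ts$voltage[, j], holding = hold, replicate = replicate)
  })
  if (ts$meta$clamped) {
    blocks <- c(blocks, list(
      data.frame(time = ts$time, site = ts$meta$record[1],
                 variable = "clamp_current", value = ts$clamp_current,
                 holding = hold, replicate = replicate),
      data.frame(time = ts$time, site = ts$meta$record[1],
                 variable = "syn_current", value = ts$syn_current,
                 holding = hold, replicate = replicate)))
  }
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy trace CSV
#'
#' @param path CSV written by [write_trace_csv()].
#' @return Data frame in the tidy layout.
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export conductance traces to tidy CSV
#'
#' @param traces List of [conductance_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_conductance_csv <- function(traces, path) {
  blocks <- lapply(traces, function(tr) {
    data.frame(time = tr$time, g_uS = tr$g, polarity = tr$polarity,
               method = tr$method, reversal = tr$reversal)
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}
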