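# Plain-CSV interchange for the pipeline's tables.

#' Read and write the standard pipeline CSV files
#'
#' Trials tables, long spike tables and waveform templates are exchanged as
#' plain CSV with fixed columns so sessions can be stored and reloaded
#' without loss. Waveforms use a long format (`unit_id`, `session_id`,
#' `channel`, `sample_index`, `amplitude`).
#'
#' @param trials,spikes Completed tables as produced by [simulate_agent()] /
#'   [simulate_population()].
#' @param path File path.
#' @return Readers return the corresponding data structure; writers return
#'   `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_trials(tr, need_choices = FALSE)
  tr
}

#' @rdname pipeline_io
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_spikes_csv <- function(path) utils::read.csv(path)

#' @rdname pipeline_io
#' @param templates Named list of 4 x S waveform templates (one per unit).
#' @param session_id Session identifier stored with each template.
#' @export
write_waveforms_csv <- function(templates, path, session_id = 1L) {
  rows <- lapply(seq_along(templates), function(u) {
    w <- as.matrix(templates[[u]])
    data.frame(unit_id = u, session_id = session_id,
               channel = rep(seq_len(nrow(w)), each = ncol(w)),
               sample_index = rep(seq_len(ncol(w)), times = nrow(w)),
               amplitude = as.vector(t(w)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_waveforms_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$unit_id), function(d) {
    nc <- max(d$channel); ns <- max(d$sample_index)
    w <- matrix(0, nc, ns)
    w[cbind(d$channel, d$sample_index)] <- d$amplitude
    w
  })
  out[order(as.integer(names(out)))]
}
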