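#' Read and write event and sample tables
#'
#' Plain-CSV round trips for the tables the pipeline exchanges. Event files
#' carry the columns `animal_id, period, session, start_s, duration_s,
#' amplitude_uv` plus any extras (e.g. `group`, `racine`); dialysis files
#' carry `run, condition, concentration_ug_ml`. EEG records round-trip as a
#' two-column CSV (`time_s, amplitude_uv`) with the metadata in a header
#' comment line.
#'
#' @param events,samples Tibble to write.
#' @param path File path.
#' @return The tibble (invisibly for writers).
#' @name sonictal-io
NULL

#' @rdname sonictal-io
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(events)
}

#' @rdname sonictal-io
#' @export
read_events_csv <- function(path) {
  ev <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("animal_id", "period", "start_s", "duration_s")
  if (!all(need %in% names(ev)))
    stop_invalid("event file must carry columns: %s",
                 paste(need, collapse = ", "))
  ev
}

#' @rdname sonictal-io
#' @export
write_dialysis_csv <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE)
  invisible(samples)
}

#' @rdname sonictal-io
#' @export
read_dialysis_csv <- function(path) {
  s <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("run", "condition", "concentration_ug_ml")
  if (!all(need %in% names(s)))
    stop_invalid("dialysis file must carry columns: %s",
                 paste(need, collapse = ", "))
  s
}

#' @rdname sonictal-io
#' @param record An [eeg_record()].
#' @export
write_eeg_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# animal_id=%s period=%s session=%d sampling_rate=%g start_time=%g",
                     record$animal_id, record$period, record$session,
                     record$sampling_rate, record$start_time), con)
  writeLines("amplitude_uv", con)
  writeLines(format(record$samples, trim = TRUE, digits = 10), con)
  invisible(record)
}

#' @rdname sonictal-io
#' @export
read_eeg_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  x <- read.csv(path, skip = 1)
  eeg_record(x$amplitude_uv, as.numeric(meta[["sampling_rate"]]),
             animal_id = meta[["animal_id"]], period = meta[["period"]],
             session = as.integer(meta[["session"]]),
             start_time = as.numeric(meta[["start_time"]]))
}
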