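# Event-table I/O: spindle and slow-oscillation events as TSV, lossless
# round-trip at full double precision.

#' Write an event table
#'
#' Writes spindle or slow-oscillation events (any tibble) as TSV with full
#' numeric precision, so a write-read round trip preserves onsets well
#' below the 1 ms documentation precision.
#'
#' @param events A tibble of events (may be empty; the header is still
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(tibble::as_tibble(events), path, progress = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path Path to the TSV file.
#' @return A tibble; numeric-looking columns are parsed as doubles.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
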