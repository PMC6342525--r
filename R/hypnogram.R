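# Hypnogram (epoch-wise vigilance states), consolidated-bout extraction and
# state-restricted signal slicing.

#' Construct a hypnogram
#'
#' An epoch-by-epoch sequence of vigilance states. Epochs are fixed length
#' (4 s by default, the scoring granularity used throughout) and each epoch
#' carries exactly one state.
#'
#' @param states Character vector of state codes, each one of
#'   `"WAKE"`, `"NREMS"`, `"REMS"`, `"ARTIFACT"`.
#' @param epoch_len_s Epoch length in seconds (default 4).
#' @return A tibble of class `hypnogram` with columns `epoch` (0-based
#'   index) and `state`, and an `epoch_len_s` attribute.
#' @export
hypnogram <- function(states, epoch_len_s = 4) {
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0) {
    abort("`epoch_len_s` must be positive.")
  }
  states <- as.character(states)
  bad <- setdiff(unique(states), .states)
  if (length(bad) > 0L) {
    abort(sprintf("unknown state code(s): %s", paste(bad, collapse = ", ")))
  }
  out <- tibble(epoch = seq_along(states) - 1L, state = states)
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("hypnogram", class(out))
  out
}

#' Epoch length of a hypnogram in seconds
#' @param hyp A `hypnogram`.
#' @return Epoch length in seconds.
#' @export
epoch_length <- function(hyp) {
  el <- attr(hyp, "epoch_len_s")
  if (is.null(el)) abort("object has no `epoch_len_s` attribute.")
  el
}

#' Read a hypnogram from delimited text
#'
#' Expects a TSV with columns `epoch_index` (contiguous integers starting
#' at 0) and `state`. Unknown state strings are mapped to `ARTIFACT` with a
#' warning, so that unscorable labels break bouts rather than extend them.
#'
#' @param path Path to the TSV file.
#' @param epoch_len_s Epoch length in seconds (default 4).
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path, epoch_len_s = 4) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  dat <- readr::read_tsv(path, col_types = readr::cols(
    epoch_index = readr::col_integer(),
    state = readr::col_character()), progress = FALSE)
  if (!all(c("epoch_index", "state") %in% names(dat))) {
    abort("hypnogram file must have columns `epoch_index` and `state`.")
  }
  idx <- dat$epoch_index
  if (anyDuplicated(idx)) abort("duplicated epoch indices in hypnogram.")
  if (!identical(sort(idx), seq_along(idx) - 1L)) {
    abort("hypnogram epochs must be contiguous and start at index 0.")
  }
  dat <- dat[order(idx), ]
  st <- dat$state
  unknown <- !(st %in% .states)
  if (any(unknown)) {
    warn(sprintf(
      "%d epoch(s) with unknown state (%s) relabeled as ARTIFACT.",
      sum(unknown), paste(unique(st[unknown]), collapse = ", ")))
    st[unknown] <- "ARTIFACT"
  }
  hypnogram(st, epoch_len_s = epoch_len_s)
}

#' Write a hypnogram to delimited text
#' @param hyp A `hypnogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  readr::write_tsv(tibble(epoch_index = hyp$epoch, state = hyp$state),
                   path, progress = FALSE)
  invisible(path)
}

#' Extract consolidated state bouts
#'
#' Maximal runs of consecutive epochs in a given state, kept only when
#' strictly longer than `min_duration_s`. The default threshold of 20 s with
#' the strict inequality implements the "consolidated NREMS (>20 s)"
#' convention: a 20 s run (five 4 s epochs) is excluded, 24 s is included.
#'
#' @param hyp A `hypnogram`.
#' @param state State code to extract (default `"NREMS"`).
#' @param min_duration_s Keep bouts with duration strictly greater than
#'   this (seconds; default 20).
#' @return Tibble with columns `bout_id`, `state`, `start_s`, `end_s`
#'   (half-open), `duration_s`, sorted by start.
#' @export
extract_bouts <- function(hyp, state = "NREMS", min_duration_s = 20) {
  if (!state %in% .states) abort(sprintf("unknown state '%s'.", state))
  if (min_duration_s < 0) abort("`min_duration_s` must be >= 0.")
  el <- epoch_length(hyp)
  r <- rle(hyp$state == state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * el > min_duration_s)
  out <- tibble(
    state = state,
    start_s = (starts[keep] - 1L) * el,
    end_s = ends[keep] * el) |>
    mutate(duration_s = .data$end_s - .data$start_s) |>
    arrange(.data$start_s) |>
    mutate(bout_id = dplyr::row_number(), .before = 1L)
  out
}

#' Slice a recording into per-bout segments
#'
#' Cuts one channel of a recording into the signal stretches covered by the
#' given bouts, preserving order. Segments never span bout boundaries, so
#' downstream windowing cannot mix signal across bouts.
#'
#' @param rec An `lfp_recording`.
#' @param bouts Tibble from [extract_bouts()].
#' @param channel Channel index or label (default 1).
#' @return Tibble with columns `bout_id`, `start_s`, `end_s`, `n_samples`
#'   and a list-column `samples` holding the numeric signal of each bout.
#' @export
concatenate_state_segments <- function(rec, bouts, channel = 1L) {
  ch <- resolve_channel(rec, channel)
  n <- ncol(rec$samples)
  fs <- rec$fs
  segs <- pmap(list(bouts$bout_id, bouts$start_s, bouts$end_s),
    function(id, s, e) {
      i0 <- round((s - rec$start_time_s) * fs) + 1
      i1 <- round((e - rec$start_time_s) * fs)
      if (i0 < 1 || i1 > n) {
        abort(sprintf(
          "bout %d [%g, %g) s lies outside the recording extent.", id, s, e))
      }
      rec$samples[ch, i0:i1]
    })
  tibble(bout_id = bouts$bout_id, start_s = bouts$start_s,
         end_s = bouts$end_s,
         n_samples = vapply(segs, length, integer(1)),
         samples = segs)
}

resolve_channel <- function(rec, channel) {
  if (is.character(channel)) {
    ch <- match(channel, rec$channel_labels)
    if (is.na(ch)) abort(sprintf("no channel labeled '%s'.", channel))
    return(ch)
  }
  ch <- as.integer(channel)
  if (ch < 1L || ch > nrow(rec$samples)) {
    abort(sprintf("channel index %d out of range.", ch))
  }
  ch
}

# sample-index ranges of bouts relative to a trace aligned with the
# recording (1-based, inclusive); used by the detectors
bout_sample_ranges <- function(bouts, fs, start_time_s = 0, n = NULL) {
  i0 <- round((bouts$start_s - start_time_s) * fs) + 1
  i1 <- round((bouts$end_s - start_time_s) * fs)
  if (!is.null(n) && (any(i0 < 1) || any(i1 > n))) {
    abort("bout lies outside the trace extent.")
  }
  data.frame(bout_id = bouts$bout_id, i0 = as.integer(i0),
             i1 = as.integer(i1))
}
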