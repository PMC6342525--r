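# Slow-oscillation (SO) cycle detection on the 2 Hz low-passed signal:
# trough-then-peak half-wave pairs delimited by zero crossings, selected by
# the three criteria (trough-to-peak time 0.5-2 s, trough below 2/3 of the
# mean trough, peak-to-peak above 2/3 of the mean peak-to-peak).

#' 2 Hz low-pass filter
#'
#' Zero-phase FIR low-pass used to isolate the slow oscillation.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate in Hz (> 4).
#' @param cutoff Cutoff in Hz (default 2).
#' @param transition Transition width in Hz (default 1).
#' @return Filtered trace, same length.
#' @export
lowpass_2hz <- function(x, fs, cutoff = 2, transition = 1) {
  if (fs <= 2 * cutoff) abort(sprintf("fs = %g Hz too low.", fs))
  b <- design_fir(fs, high = cutoff, transition = transition)
  fir_filtfilt(x, b)
}

#' Slow-oscillation candidates from half-wave pairs
#'
#' Scans the low-passed trace of each bout for consecutive
#' (negative half-wave, positive half-wave) pairs delimited by zero
#' crossings. For each pair: `x1`/`y1` are the time and value of the
#' negative half-wave minimum (trough), `x2`/`y2` of the following positive
#' half-wave maximum (peak); `zc_pre`/`zc_post` are the bounding
#' zero-crossing times (linearly interpolated). Candidates never span bout
#' boundaries; leading/trailing partial half-waves are ignored.
#'
#' @param filtered Low-passed trace aligned with the recording.
#' @param fs Sampling rate in Hz.
#' @param bouts Bout tibble from [extract_bouts()].
#' @param start_time_s Time of the first trace sample.
#' @return Tibble with columns `bout_id`, `zc_pre_s`, `x1_s`, `y1_uv`,
#'   `x2_s`, `y2_uv`, `zc_post_s`.
#' @export
find_so_candidates <- function(filtered, fs, bouts, start_time_s = 0) {
  rng <- bout_sample_ranges(bouts, fs, start_time_s, n = length(filtered))
  out <- list()
  for (k in seq_len(nrow(rng))) {
    i0 <- rng$i0[k]
    i1 <- rng$i1[k]
    f <- filtered[i0:i1]
    zc <- zero_crossings(f)
    if (nrow(zc) < 3L) next
    t0 <- start_time_s + (i0 - 2) / fs  # sample j maps to t0 + j/fs
    for (j in seq_len(nrow(zc) - 2L)) {
      if (zc$direction[j] != -1L) next       # negative half-wave starts
      if (zc$direction[j + 1L] != 1L) next
      a <- zc$idx[j] + 1L
      b <- zc$idx[j + 1L]
      cpos <- zc$idx[j + 1L] + 1L
      d <- zc$idx[j + 2L]
      if (b < a || d < cpos) next
      imin <- a - 1L + which.min(f[a:b])
      imax <- cpos - 1L + which.max(f[cpos:d])
      out[[length(out) + 1L]] <- tibble(
        bout_id = bouts$bout_id[k],
        zc_pre_s = t0 + (zc$idx[j] + zc$frac[j]) / fs,
        x1_s = t0 + imin / fs, y1_uv = f[imin],
        x2_s = t0 + imax / fs, y2_uv = f[imax],
        zc_post_s = t0 + (zc$idx[j + 2L] + zc$frac[j + 2L]) / fs)
    }
  }
  if (length(out) == 0L) {
    return(tibble(bout_id = integer(), zc_pre_s = numeric(),
                  x1_s = numeric(), y1_uv = numeric(), x2_s = numeric(),
                  y2_uv = numeric(), zc_post_s = numeric()))
  }
  bind_rows(out)
}

#' Select slow-oscillation events from candidates
#'
#' Computes the recording-level mean trough `Y1` and mean peak `Y2` over
#' all candidates, then keeps candidates satisfying all three constraints:
#' (1) trough-to-peak time `x2 - x1` within \[0.5, 2\] s (inclusive);
#' (2) `y1` lower (more negative) than `2/3 * Y1`;
#' (3) `y2 - y1` at least `2/3 * (Y2 - Y1)`.
#' The SO period used downstream for spindle overlap and phase is
#' `[zc_pre, zc_post]`. All three criteria are ratios or time-based, so the
#' selection is invariant under amplitude scaling.
#'
#' @param candidates Tibble from [find_so_candidates()].
#' @return A tibble of class `so_events` with the candidate columns plus
#'   `period_start_s`, `period_end_s`; attributes `Y1`, `Y2`,
#'   `n_candidates`. An empty candidate set yields an empty result with
#'   `NA` summary values and a warning.
#' @export
select_so <- function(candidates) {
  if (nrow(candidates) == 0L) {
    warn("no SO candidates; Y1/Y2 undefined.")
    out <- mutate(candidates, period_start_s = numeric(0),
                  period_end_s = numeric(0))
    attr(out, "Y1") <- NA_real_
    attr(out, "Y2") <- NA_real_
    attr(out, "n_candidates") <- 0L
    class(out) <- unique(c("so_events", class(out)))
    return(out)
  }
  y1m <- mean(candidates$y1_uv)
  y2m <- mean(candidates$y2_uv)
  dt <- candidates$x2_s - candidates$x1_s
  keep <- dt >= 0.5 & dt <= 2 &
    candidates$y1_uv < (2 / 3) * y1m &
    (candidates$y2_uv - candidates$y1_uv) >= (2 / 3) * (y2m - y1m)
  out <- candidates[keep, , drop = FALSE] |>
    mutate(period_start_s = .data$zc_pre_s, period_end_s = .data$zc_post_s)
  attr(out, "Y1") <- y1m
  attr(out, "Y2") <- y2m
  attr(out, "n_candidates") <- nrow(candidates)
  class(out) <- unique(c("so_events", class(out)))
  out
}

#' Detect slow oscillations in a recording
#'
#' High-level wrapper: 2 Hz low-pass of one channel, candidate half-wave
#' pairs within consolidated NREMS bouts, then the three-criteria
#' selection.
#'
#' @param rec An `lfp_recording`.
#' @param hyp A `hypnogram`.
#' @param channel Channel index or label.
#' @param min_bout_s Consolidation threshold (default 20, strict).
#' @param cutoff,transition Passed to [lowpass_2hz()].
#' @return An `so_events` tibble (see [select_so()]); the low-passed trace
#'   is attached as attribute `filtered` for downstream phase extraction.
#' @export
detect_so <- function(rec, hyp, channel = 1L, min_bout_s = 20,
                      cutoff = 2, transition = 1) {
  ch <- resolve_channel(rec, channel)
  bouts <- extract_bouts(hyp, "NREMS", min_bout_s)
  if (nrow(bouts) == 0L) abort("no NREMS bouts.")
  filt <- lowpass_2hz(rec$samples[ch, ], rec$fs, cutoff = cutoff,
                      transition = transition)
  cand <- find_so_candidates(filt, rec$fs, bouts, rec$start_time_s)
  out <- select_so(cand)
  attr(out, "filtered") <- filt
  attr(out, "bouts") <- bouts
  out
}
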