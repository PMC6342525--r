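# Spindle-onset phase-locking to the slow oscillation.
#
# Phase convention: Hilbert phase of the 2 Hz low-passed trace, 0 deg at
# the SO positive peak, +/-180 deg at the trough, so the rising
# trough-to-peak flank spans (-180, 0) — the active state (AS) — and
# [0, 180] is the silent state (SS). Boundary phases (exactly 0 or 180)
# count as SS.

#' Pair spindles with slow-oscillation periods (overlap filter)
#'
#' A spindle is included when at least `min_overlap` (default 95%) of its
#' duration falls inside some SO period; it is paired with the SO of
#' maximal overlap (ties to the earlier SO).
#'
#' @param spindles Spindle tibble with `onset_s`, `offset_s`.
#' @param so_events `so_events` tibble with `period_start_s`,
#'   `period_end_s`.
#' @param min_overlap Minimum overlap fraction of the spindle duration
#'   (default 0.95).
#' @return The included spindles with added columns `so_x1_s`
#'   (paired trough time), `so_period_start_s`, `so_period_end_s`,
#'   `overlap_frac`; attribute `n_excluded`.
#' @export
overlap_filter <- function(spindles, so_events, min_overlap = 0.95) {
  n <- nrow(spindles)
  if (n == 0L || nrow(so_events) == 0L) {
    out <- spindles[integer(0), , drop = FALSE]
    out$so_x1_s <- numeric(0)
    out$so_period_start_s <- numeric(0)
    out$so_period_end_s <- numeric(0)
    out$overlap_frac <- numeric(0)
    attr(out, "n_excluded") <- n
    return(out)
  }
  ps <- so_events$period_start_s
  pe <- so_events$period_end_s
  rows <- map(seq_len(n), function(i) {
    on <- spindles$onset_s[i]
    off <- spindles$offset_s[i]
    ov <- pmax(0, pmin(off, pe) - pmax(on, ps)) / (off - on)
    j <- which.max(ov)               # which.max takes the first maximum
    if (ov[j] >= min_overlap) {
      cbind(spindles[i, , drop = FALSE],
            tibble(so_x1_s = so_events$x1_s[j],
                   so_period_start_s = ps[j], so_period_end_s = pe[j],
                   overlap_frac = ov[j]))
    } else {
      NULL
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) as_tibble(bind_rows(rows)) else {
    o <- spindles[integer(0), , drop = FALSE]
    o$so_x1_s <- numeric(0)
    o$so_period_start_s <- numeric(0)
    o$so_period_end_s <- numeric(0)
    o$overlap_frac <- numeric(0)
    o
  }
  attr(out, "n_excluded") <- n - nrow(out)
  out
}

#' Slow-oscillation Hilbert phase at given times
#'
#' Instantaneous phase of the analytic signal of the low-passed trace,
#' in degrees (-180, 180], 0 at the positive peak.
#'
#' @param filtered Low-passed trace.
#' @param fs Sampling rate in Hz.
#' @param time_s Time(s) to evaluate, seconds.
#' @param period Optional `c(start, end)`; times outside it raise an
#'   error.
#' @param start_time_s Time of the first sample.
#' @param invert_polarity Flip the trace sign before phase extraction (for
#'   recordings with opposite referencing).
#' @return Phase(s) in degrees.
#' @export
so_phase_at <- function(filtered, fs, time_s, period = NULL,
                        start_time_s = 0, invert_polarity = FALSE) {
  if (!is.null(period)) {
    if (any(time_s < period[1L] | time_s > period[2L])) {
      abort("time outside the SO period.")
    }
  }
  idx <- round((time_s - start_time_s) * fs) + 1
  if (any(idx < 1 | idx > length(filtered))) {
    abort("time outside the filtered trace.")
  }
  x <- if (invert_polarity) -filtered else filtered
  ph <- Arg(analytic_signal(x))[idx] * 180 / pi
  wrap_deg(ph)
}

#' Phase histogram of spindle occurrence
#'
#' Counts phases in half-open bins tiling (-180, 180] and expresses them
#' as percent of all phases.
#'
#' @param phases Phases in degrees (-180, 180].
#' @param bin_deg Bin width in degrees; must divide 360 (default 30).
#' @return Tibble with `bin_lo`, `bin_hi`, `bin_mid`, `count`,
#'   `occurrence_pct`. Empty input gives an empty histogram.
#' @export
phase_histogram <- function(phases, bin_deg = 30) {
  if (360 %% bin_deg != 0) abort("`bin_deg` must divide 360.")
  edges <- seq(-180, 180, by = bin_deg)
  if (length(phases) == 0L) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(),
                  bin_mid = numeric(), count = integer(),
                  occurrence_pct = numeric()))
  }
  if (any(phases <= -180 | phases > 180)) {
    abort("phases must lie in (-180, 180].")
  }
  bin <- findInterval(phases, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  bin[bin == 0L] <- 1L     # exact -180 would be invalid anyway
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
         bin_mid = (edges[-length(edges)] + edges[-1L]) / 2,
         count = counts,
         occurrence_pct = counts / sum(counts) * 100)
}

#' Active/silent-state fractions of spindle onsets
#'
#' AS is the rising trough-to-peak flank, phases in (-180, 0); SS is
#' \[0, 180\] (boundaries 0 and 180 assigned to SS). Fractions sum to 1.
#'
#' @param phases Phases in degrees (-180, 180].
#' @return Named list `as_fraction`, `ss_fraction`.
#' @export
as_ss_fractions <- function(phases) {
  if (length(phases) == 0L) abort("no phases given.")
  as_frac <- mean(phases < 0)
  list(as_fraction = as_frac, ss_fraction = 1 - as_frac)
}

#' Spindle-onset phase locking to the slow oscillation
#'
#' End-to-end coupling stage: pairs detected spindles with detected SO
#' periods (>= 95% overlap), extracts the Hilbert phase of the 2 Hz
#' low-passed signal at each included spindle onset (computed per NREMS
#' bout so edge effects stay at bout margins), and summarizes occurrence
#' by phase bin and by active/silent state.
#'
#' @param rec An `lfp_recording`.
#' @param spindles `spindle_events` from [detect_spindles()].
#' @param so `so_events` from [detect_so()] (carrying the low-passed
#'   trace).
#' @param hyp A `hypnogram` (used for per-bout Hilbert windows).
#' @param channel Channel index or label.
#' @param min_overlap Overlap threshold (default 0.95).
#' @param bin_deg Histogram bin width in degrees (default 30).
#' @param invert_polarity Flip polarity before phase extraction.
#' @param min_bout_s Consolidation threshold (default 20).
#' @return A list of class `so_coupling`: `spindles` (included events with
#'   `phase_deg` and pairing columns), `histogram`, `as_fraction`,
#'   `ss_fraction`, `n_included`, `n_excluded`.
#' @export
spindle_so_coupling <- function(rec, spindles, so, hyp, channel = 1L,
                                min_overlap = 0.95, bin_deg = 30,
                                invert_polarity = FALSE, min_bout_s = 20) {
  ch <- resolve_channel(rec, channel)
  filt <- attr(so, "filtered")
  if (is.null(filt)) {
    filt <- lowpass_2hz(rec$samples[ch, ], rec$fs)
  }
  bouts <- attr(so, "bouts") %||% extract_bouts(hyp, "NREMS", min_bout_s)
  inc <- overlap_filter(spindles, so, min_overlap = min_overlap)
  n_excluded <- attr(inc, "n_excluded")
  phase <- rep(NA_real_, nrow(inc))
  if (nrow(inc) > 0L) {
    rng <- bout_sample_ranges(bouts, rec$fs, rec$start_time_s,
                              n = length(filt))
    for (k in seq_len(nrow(rng))) {
      seg <- filt[rng$i0[k]:rng$i1[k]]
      t0 <- rec$start_time_s + (rng$i0[k] - 1) / rec$fs
      in_bout <- which(inc$onset_s >= bouts$start_s[k] &
                         inc$onset_s < bouts$end_s[k])
      if (length(in_bout) == 0L) next
      phase[in_bout] <- so_phase_at(seg, rec$fs, inc$onset_s[in_bout],
                                    start_time_s = t0,
                                    invert_polarity = invert_polarity)
    }
  }
  inc$phase_deg <- phase
  inc <- inc[!is.na(inc$phase_deg), , drop = FALSE]
  n_excluded <- nrow(spindles) - nrow(inc)
  fr <- if (nrow(inc) > 0L) as_ss_fractions(inc$phase_deg) else
    list(as_fraction = NA_real_, ss_fraction = NA_real_)
  structure(
    list(spindles = inc,
         histogram = phase_histogram(inc$phase_deg, bin_deg = bin_deg),
         as_fraction = fr$as_fraction, ss_fraction = fr$ss_fraction,
         n_included = nrow(inc), n_excluded = n_excluded),
    class = "so_coupling")
}

#' @export
print.so_coupling <- function(x, ...) {
  cat(sprintf(
    "<so_coupling> %d spindles included, %d excluded (<95%% SO overlap)\n",
    x$n_included, x$n_excluded))
  if (!is.na(x$as_fraction)) {
    cat(sprintf("  active state: %.1f%%, silent state: %.1f%%\n",
                100 * x$as_fraction, 100 * x$ss_fraction))
  }
  invisible(x)
}
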