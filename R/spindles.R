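# Discrete sleep-spindle detection from the squared 9-16 Hz envelope.
#
# Pipeline per channel: zero-phase FIR band-pass (9-16 Hz) -> point-wise
# square -> 100 ms moving average (the "sigma power" envelope) ->
# threshold at mean + 1.5 SD of the NREMS-restricted envelope -> per-bout
# supra-threshold runs with >= 3 band-pass cycles -> extension to the
# nearest zero crossings -> fusion of events separated by < 10 ms ->
# discard of events touching a bout edge.

#' Sigma-band squared-power envelope
#'
#' Band-passes the trace in the enlarged sigma band with a zero-phase FIR
#' filter, squares it and smooths with a centered moving average. The raw
#' squared signal oscillates at twice the spindle frequency; without the
#' smoothing (default 100 ms) a single burst would fragment into many
#' sub-threshold dips.
#'
#' @param x Numeric trace in microvolts.
#' @param fs Sampling rate in Hz; must exceed twice the upper band edge.
#' @param band Length-2 band edges in Hz (default `c(9, 16)`).
#' @param smooth_s Moving-average length in seconds (default 0.1).
#' @param transition FIR transition width in Hz (default 2).
#' @return A list of class `sigma_envelope`: `filtered` (band-passed
#'   trace), `envelope` (uV^2, same length as `x`), `fs`, `band`,
#'   `smooth_s`.
#' @export
sigma_envelope <- function(x, fs, band = c(9, 16), smooth_s = 0.1,
                           transition = 2) {
  if (fs <= 2 * band[2L]) {
    abort(sprintf("fs = %g Hz is too low for a %g-%g Hz band.", fs,
                  band[1L], band[2L]))
  }
  b <- design_fir(fs, band[1L], band[2L], transition = transition)
  filt <- fir_filtfilt(x, b)
  env <- filt^2
  if (smooth_s > 0) env <- moving_average(env, round(smooth_s * fs))
  structure(list(filtered = filt, envelope = env, fs = fs, band = band,
                 smooth_s = smooth_s),
            class = "sigma_envelope")
}

#' Spindle detection threshold
#'
#' `mean + 1.5 x SD` (population SD) of the NREMS-restricted sigma-power
#' envelope. No normalization is applied.
#'
#' @param env_values Envelope samples restricted to NREMS (uV^2).
#' @return Threshold in uV^2.
#' @export
compute_threshold <- function(env_values) {
  env_values <- env_values[!is.na(env_values)]
  if (length(env_values) == 0L) {
    abort("no NREMS envelope samples; cannot compute a threshold.")
  }
  m <- mean(env_values)
  m + 1.5 * sqrt(mean((env_values - m)^2))
}

# count full band-pass cycles in a filtered stretch: number of complete
# half-cycles between the first and last zero crossing, halved
count_cycles <- function(f_seg) {
  zc <- zero_crossings(f_seg)
  if (nrow(zc) < 2L) return(0)
  floor((nrow(zc) - 1L) / 2L)
}

#' Detect spindle events from an envelope and threshold
#'
#' Core detector, run independently per bout: (1) maximal supra-threshold
#' runs of the envelope; (2) runs whose band-pass signal contains fewer
#' than `min_cycles` full cycles (counted from zero crossings inside the
#' run) are rejected — alternatively a fixed minimum duration via
#' `min_cycles_mode = "fixed"`; (3) onsets extend back and offsets forward
#' to the nearest zero crossing of the filtered trace; (4) events that
#' overlap or are separated by less than `fuse_s` are fused (transitively;
#' fusion is final, the cycle criterion is not reapplied); (5) events
#' touching the first or last sample of their bout are discarded.
#'
#' @param filtered Band-pass filtered trace.
#' @param envelope Sigma-power envelope, same length.
#' @param fs Sampling rate in Hz.
#' @param threshold Detection threshold in uV^2 (see
#'   [compute_threshold()]).
#' @param bouts Bout tibble from [extract_bouts()].
#' @param min_cycles Minimum number of band-pass cycles (default 3).
#' @param fuse_s Fusion gap in seconds (default 0.010).
#' @param min_cycles_mode `"cycles"` (count zero crossings) or `"fixed"`
#'   (duration >= `fixed_min_s`).
#' @param fixed_min_s Fixed minimum core duration for `"fixed"` mode
#'   (default 0.24 s, i.e. 3 cycles at 12.5 Hz).
#' @param start_time_s Time of the first trace sample (default 0).
#' @return Tibble with columns `bout_id`, `onset_s`, `offset_s`,
#'   `duration_s` (half-open intervals, zero-crossing interpolated times).
#' @export
detect_events <- function(filtered, envelope, fs, threshold, bouts,
                          min_cycles = 3, fuse_s = 0.010,
                          min_cycles_mode = c("cycles", "fixed"),
                          fixed_min_s = 0.24, start_time_s = 0) {
  min_cycles_mode <- match.arg(min_cycles_mode)
  rng <- bout_sample_ranges(bouts, fs, start_time_s, n = length(filtered))
  out <- list()
  for (k in seq_len(nrow(rng))) {
    i0 <- rng$i0[k]
    i1 <- rng$i1[k]
    f <- filtered[i0:i1]
    e <- envelope[i0:i1]
    above <- e > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    zc <- zero_crossings(f)
    zt <- zc$idx + zc$frac          # fractional sample position of crossing
    ev <- list()
    for (q in seq_len(nrow(runs))) {
      a <- runs[q, 1L]
      b <- runs[q, 2L]
      keep <- if (min_cycles_mode == "cycles") {
        count_cycles(f[a:b]) >= min_cycles
      } else {
        (b - a + 1L) / fs >= fixed_min_s
      }
      if (!keep) next
      pre <- zt[zt <= a]
      post <- zt[zt >= b]
      on_pos <- if (length(pre)) max(pre) else 1
      off_pos <- if (length(post)) min(post) else (i1 - i0 + 1L)
      ev[[length(ev) + 1L]] <- c(on_pos, off_pos)
    }
    if (length(ev) == 0L) next
    ev <- do.call(rbind, ev)
    ev <- ev[order(ev[, 1L]), , drop = FALSE]
    # transitive fusion of overlapping / near events
    fused <- list()
    cur <- ev[1L, ]
    for (q in seq_len(nrow(ev))[-1L]) {
      if (ev[q, 1L] - cur[2L] < fuse_s * fs) {
        cur[2L] <- max(cur[2L], ev[q, 2L])
      } else {
        fused[[length(fused) + 1L]] <- cur
        cur <- ev[q, ]
      }
    }
    fused[[length(fused) + 1L]] <- cur
    fused <- do.call(rbind, fused)
    # discard events touching the bout edges
    len <- i1 - i0 + 1L
    edge <- fused[, 1L] <= 1 + 1e-9 | fused[, 2L] >= len - 1e-9
    fused <- fused[!edge, , drop = FALSE]
    if (nrow(fused) == 0L) next
    out[[length(out) + 1L]] <- tibble(
      bout_id = bouts$bout_id[k],
      onset_s = start_time_s + (i0 - 1 + fused[, 1L] - 1) / fs,
      offset_s = start_time_s + (i0 - 1 + fused[, 2L] - 1) / fs)
  }
  if (length(out) == 0L) {
    return(tibble(bout_id = integer(), onset_s = numeric(),
                  offset_s = numeric(), duration_s = numeric()))
  }
  bind_rows(out) |> mutate(duration_s = .data$offset_s - .data$onset_s)
}

#' Mean sigma power of a spindle event
#'
#' Arithmetic mean of the envelope over the half-open event interval.
#'
#' @param onset_s,offset_s Event boundaries in seconds.
#' @param envelope Sigma-power envelope aligned to the trace.
#' @param fs Sampling rate in Hz.
#' @param start_time_s Time of the first envelope sample.
#' @return Amplitude in uV^2.
#' @export
spindle_amplitude <- function(onset_s, offset_s, envelope, fs,
                              start_time_s = 0) {
  i0 <- max(1L, floor((onset_s - start_time_s) * fs) + 1L)
  i1 <- min(length(envelope), ceiling((offset_s - start_time_s) * fs))
  if (i1 < i0) abort("event interval is empty.")
  mean(envelope[i0:i1])
}

#' Intra-spindle peak frequency
#'
#' Magnitude FFT of the (mean-removed) event segment, zero-padded to a
#' frequency resolution of `resolution` Hz. Returns the frequency of the
#' in-band maximum if it is a distinguishable peak — a local maximum whose
#' magnitude is at least `prominence_factor` times the median magnitude of
#' the in-band bins lying more than `exclude_hz` from it (the reference
#' level excludes the peak's own spectral mainlobe) — otherwise `NA`
#' (events without a distinguishable peak carry no frequency).
#'
#' @param segment Numeric signal of the event (band-pass filtered by
#'   default in [detect_spindles()]).
#' @param fs Sampling rate in Hz.
#' @param band Search band in Hz (default `c(9, 16)`).
#' @param resolution Target frequency resolution in Hz (default 0.25).
#' @param prominence_factor Peak/reference magnitude ratio required
#'   (default 2).
#' @param exclude_hz Half-width of the zone around the peak excluded from
#'   the reference median (default 2 Hz).
#' @return Peak frequency in Hz, or `NA_real_`.
#' @export
intra_spindle_frequency <- function(segment, fs, band = c(9, 16),
                                    resolution = 0.25,
                                    prominence_factor = 2,
                                    exclude_hz = 2) {
  x <- segment - mean(segment)
  nfft <- max(length(x), ceiling(fs / resolution))
  mag <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))
  nb <- nfft %/% 2L + 1L
  mag <- mag[seq_len(nb)]
  freq <- (seq_len(nb) - 1L) * fs / nfft
  inband <- which(freq >= band[1L] & freq <= band[2L])
  if (length(inband) < 3L) return(NA_real_)
  i <- inband[which.max(mag[inband])]
  is_local_max <- mag[i] >= mag[max(i - 1L, 1L)] &&
    mag[i] >= mag[min(i + 1L, nb)]
  if (!is_local_max) return(NA_real_)
  ref <- inband[abs(freq[inband] - freq[i]) > exclude_hz]
  if (length(ref) < 2L) return(NA_real_)
  if (mag[i] < prominence_factor * stats::median(mag[ref])) {
    return(NA_real_)
  }
  freq[i]
}

#' Detect sleep spindles in a recording
#'
#' High-level detector: builds the sigma envelope of one channel, takes the
#' threshold over the envelope restricted to all consolidated-NREMS samples
#' of the recording (a single per-signal threshold, not per bout), runs
#' [detect_events()] per bout, and characterizes each event by its mean
#' sigma power and intra-spindle peak frequency.
#'
#' @param rec An `lfp_recording`.
#' @param hyp A `hypnogram`.
#' @param channel Channel index or label (default 1).
#' @param band,smooth_s,transition Passed to [sigma_envelope()].
#' @param min_cycles,fuse_s,min_cycles_mode,fixed_min_s Passed to
#'   [detect_events()].
#' @param min_bout_s Consolidation threshold for NREMS bouts (default 20,
#'   strict).
#' @param threshold Optional fixed threshold in uV^2; by default computed
#'   with [compute_threshold()].
#' @param intra_freq_on `"filtered"` (default; reduces slow-wave leakage)
#'   or `"raw"` segment for the intra-frequency FFT.
#' @return A tibble of class `spindle_events` with columns `channel`,
#'   `bout_id`, `onset_s`, `offset_s`, `duration_s`, `amplitude_uv2`,
#'   `intra_freq_hz`; attributes `threshold`, `band`, `n_bouts`.
#' @export
detect_spindles <- function(rec, hyp, channel = 1L, band = c(9, 16),
                            smooth_s = 0.1, transition = 2,
                            min_cycles = 3, fuse_s = 0.010,
                            min_cycles_mode = c("cycles", "fixed"),
                            fixed_min_s = 0.24, min_bout_s = 20,
                            threshold = NULL,
                            intra_freq_on = c("filtered", "raw")) {
  min_cycles_mode <- match.arg(min_cycles_mode)
  intra_freq_on <- match.arg(intra_freq_on)
  ch <- resolve_channel(rec, channel)
  bouts <- extract_bouts(hyp, "NREMS", min_bout_s)
  if (nrow(bouts) == 0L) abort("no NREMS bouts.")
  trace <- rec$samples[ch, ]
  se <- sigma_envelope(trace, rec$fs, band = band, smooth_s = smooth_s,
                       transition = transition)
  rng <- bout_sample_ranges(bouts, rec$fs, rec$start_time_s,
                            n = length(trace))
  nrems_idx <- unlist(map2(rng$i0, rng$i1, seq))
  if (is.null(threshold)) threshold <- compute_threshold(se$envelope[nrems_idx])
  ev <- detect_events(se$filtered, se$envelope, rec$fs, threshold, bouts,
                      min_cycles = min_cycles, fuse_s = fuse_s,
                      min_cycles_mode = min_cycles_mode,
                      fixed_min_s = fixed_min_s,
                      start_time_s = rec$start_time_s)
  src <- if (intra_freq_on == "filtered") se$filtered else trace
  if (nrow(ev) > 0L) {
    ev$amplitude_uv2 <- map_dbl(seq_len(nrow(ev)), function(i) {
      spindle_amplitude(ev$onset_s[i], ev$offset_s[i], se$envelope,
                        rec$fs, rec$start_time_s)
    })
    ev$intra_freq_hz <- map_dbl(seq_len(nrow(ev)), function(i) {
      i0 <- max(1L, floor((ev$onset_s[i] - rec$start_time_s) * rec$fs) + 1L)
      i1 <- min(length(src),
                ceiling((ev$offset_s[i] - rec$start_time_s) * rec$fs))
      intra_spindle_frequency(src[i0:i1], rec$fs, band = band)
    })
  } else {
    ev$amplitude_uv2 <- numeric(0)
    ev$intra_freq_hz <- numeric(0)
  }
  out <- mutate(ev, channel = rec$channel_labels[ch], .before = 1L)
  attr(out, "threshold") <- threshold
  attr(out, "band") <- band
  attr(out, "n_bouts") <- nrow(bouts)
  class(out) <- unique(c("spindle_events", class(out)))
  out
}
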