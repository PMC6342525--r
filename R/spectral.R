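# Spectral quantification: windowed squared-FFT power spectra of
# state-restricted signal, normalization to the 0-35 Hz sum, band powers,
# and the delta-power time course in equal-epoch quantile bins.

#' Windowed power spectrum of state-restricted signal
#'
#' Tiles each segment with consecutive non-overlapping rectangular windows
#' (default 4 s; remainder samples of a segment are dropped and windows
#' never span segment boundaries). Each window is offset-corrected (its
#' mean subtracted) and transformed with a squared-magnitude FFT; the
#' spectrum is the average over all windows. With 4 s windows the frequency
#' resolution is 0.25 Hz.
#'
#' @param segments Output of [concatenate_state_segments()], a list of
#'   numeric vectors, or a single numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 4).
#' @return A tibble of class `lfp_spectrum` with columns `freq` (Hz, 0 to
#'   Nyquist) and `power` (unnormalized, uV^2 per FFT bin scaled by the
#'   squared-FFT convention |X_k|^2), with attributes `n_windows`, `fs`,
#'   `window_s`, `normalized = FALSE`.
#' @export
power_spectrum <- function(segments, fs, window_s = 4) {
  segs <- as_segment_list(segments)
  nwin <- as.integer(round(window_s * fs))
  if (nwin < 2L) abort("window too short.")
  nb <- nwin %/% 2L + 1L
  acc <- numeric(nb)
  n_windows <- 0L
  for (seg in segs) {
    m <- floor(length(seg) / nwin)
    if (m < 1L) next
    for (w in seq_len(m)) {
      win <- seg[((w - 1L) * nwin + 1L):(w * nwin)]
      win <- win - mean(win)
      acc <- acc + Mod(stats::fft(win))[seq_len(nb)]^2
      n_windows <- n_windows + 1L
    }
  }
  if (n_windows == 0L) {
    abort(sprintf(
      "no segment contains a complete %g s window.", window_s))
  }
  out <- tibble(freq = (seq_len(nb) - 1L) / window_s,
                power = acc / n_windows)
  new_spectrum(out, fs = fs, window_s = window_s, n_windows = n_windows,
               normalized = FALSE)
}

new_spectrum <- function(tbl, fs, window_s, n_windows, normalized) {
  attr(tbl, "fs") <- fs
  attr(tbl, "window_s") <- window_s
  attr(tbl, "n_windows") <- n_windows
  attr(tbl, "normalized") <- normalized
  class(tbl) <- unique(c("lfp_spectrum", class(tbl)))
  tbl
}

as_segment_list <- function(segments) {
  if (is.numeric(segments)) return(list(segments))
  if (is.data.frame(segments) && "samples" %in% names(segments)) {
    return(segments$samples)
  }
  if (is.list(segments)) return(segments)
  abort("`segments` must be a segments tibble, list, or numeric vector.")
}

#' Normalize a power spectrum to its 0-35 Hz sum
#'
#' Divides the density by its sum over 0-35 Hz (35.00 Hz bin included) and
#' expresses it in percent, so the normalized density sums to exactly 100
#' over that range and spectra are comparable across animals and
#' amplitudes.
#'
#' @param ps An unnormalized `lfp_spectrum`.
#' @param f_max Upper normalization bound in Hz (default 35, inclusive).
#' @return A normalized `lfp_spectrum` (density in % of the 0-`f_max` sum).
#' @export
normalize_spectrum <- function(ps, f_max = 35) {
  tot <- sum(ps$power[ps$freq <= f_max + 1e-9])
  if (tot <= 0) {
    abort("total 0-35 Hz power is zero; cannot normalize a degenerate
           spectrum.")
  }
  out <- ps
  out$power <- ps$power / tot * 100
  attr(out, "normalized") <- TRUE
  out
}

#' Band power from a normalized spectrum
#'
#' Sums the density bins inside a band. Bins are assigned half-open,
#' `(lo, hi]`, so an edge shared by two adjacent bands (e.g. 1.5 Hz for SO
#' and delta) counts toward the lower band only and adjacent bands
#' partition the axis; the 0 Hz bin belongs to a band starting at 0.
#'
#' @param ps An `lfp_spectrum` (normalized for interpretable % units).
#' @param lo,hi Band edges in Hz (`lo < hi`).
#' @return Band power (sum of bins), in % units for a normalized spectrum.
#' @export
band_power <- function(ps, lo, hi) {
  if (!(lo < hi)) abort("band edges must satisfy lo < hi.")
  eps <- 1e-9
  keep <- ps$freq > lo + eps & ps$freq <= hi + eps
  if (lo == 0) keep <- keep | abs(ps$freq) < eps
  sum(ps$power[keep])
}

#' Canonical NREMS bands
#'
#' SO 0.5-1.5 Hz, delta 1.5-4 Hz, sigma 10-15 Hz.
#'
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
default_bands <- function() {
  tibble(band = c("SO", "delta", "sigma"),
         lo = c(0.5, 1.5, 10), hi = c(1.5, 4, 15))
}

#' Band powers for a set of bands
#'
#' @param ps An `lfp_spectrum`.
#' @param bands Tibble with columns `band`, `lo`, `hi`
#'   (default [default_bands()]).
#' @return The `bands` tibble with an added `power` column.
#' @export
band_powers <- function(ps, bands = default_bands()) {
  bands |>
    mutate(power = map_dbl(seq_len(nrow(bands)),
                           function(i) band_power(ps, bands$lo[i],
                                                  bands$hi[i])))
}

#' Per-epoch band power within consolidated NREMS
#'
#' Computes, for every whole scoring epoch inside the given bouts, the area
#' under the (unnormalized) power spectrum of that single epoch-length
#' window in a band — the delta band by default. This is the input series
#' for [delta_timecourse()].
#'
#' @param rec An `lfp_recording`.
#' @param hyp A `hypnogram`.
#' @param channel Channel index or label.
#' @param band Length-2 numeric band edges in Hz (default `c(1.5, 4)`).
#' @param min_bout_s Consolidation threshold passed to [extract_bouts()]
#'   (strictly greater; default 20).
#' @return Tibble with columns `epoch`, `start_s`, `power`.
#' @export
per_epoch_band_power <- function(rec, hyp, channel = 1L,
                                 band = c(1.5, 4), min_bout_s = 20) {
  el <- epoch_length(hyp)
  bouts <- extract_bouts(hyp, "NREMS", min_bout_s)
  if (nrow(bouts) == 0L) abort("no NREMS bouts.")
  nwin <- as.integer(round(el * rec$fs))
  ch <- resolve_channel(rec, channel)
  rows <- list()
  for (k in seq_len(nrow(bouts))) {
    ep0 <- bouts$start_s[k] / el
    n_ep <- (bouts$end_s[k] - bouts$start_s[k]) / el
    for (j in seq_len(n_ep)) {
      start_s <- (ep0 + j - 1) * el
      i0 <- round((start_s - rec$start_time_s) * rec$fs) + 1L
      win <- rec$samples[ch, i0:(i0 + nwin - 1L)]
      win <- win - mean(win)
      nb <- nwin %/% 2L + 1L
      pw <- Mod(stats::fft(win))[seq_len(nb)]^2
      freq <- (seq_len(nb) - 1L) / el
      eps <- 1e-9
      keep <- freq > band[1L] + eps & freq <= band[2L] + eps
      rows[[length(rows) + 1L]] <- tibble(
        epoch = as.integer(ep0 + j - 1), start_s = start_s,
        power = sum(pw[keep]))
    }
  }
  bind_rows(rows)
}

#' Delta-power time course in equal-epoch quantile bins
#'
#' Partitions the baseline and post-injection per-epoch delta-power series,
#' in temporal order, into bins holding identical numbers of NREMS epochs
#' (12 baseline and 36 post bins by default; when the epoch count is not
#' divisible the remainder epochs go to the earliest bins). Each bin is the
#' mean of its epochs and all bins are normalized by the mean of the first
#' two baseline bins.
#'
#' @param baseline,post Numeric vectors of per-epoch delta power, in
#'   temporal order (see [per_epoch_band_power()]).
#' @param n_baseline_bins,n_post_bins Bin counts (defaults 12 and 36).
#' @return Tibble of class `delta_timecourse` with columns `segment`
#'   (`"baseline"`/`"post"`), `bin`, `n_epochs`, `value` (normalized,
#'   unitless).
#' @export
delta_timecourse <- function(baseline, post, n_baseline_bins = 12,
                             n_post_bins = 36) {
  bin_means <- function(x, nb, label) {
    if (length(x) < nb) {
      abort(sprintf(
        "%s has %d epochs, fewer than %d bins.", label, length(x), nb))
    }
    q <- length(x) %/% nb
    r <- length(x) %% nb
    sizes <- rep(q, nb) + c(rep(1L, r), rep(0L, nb - r))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    tibble(bin = seq_len(nb), n_epochs = sizes,
           value = map_dbl(seq_len(nb),
                           function(i) mean(x[starts[i]:ends[i]])))
  }
  b <- bin_means(baseline, n_baseline_bins, "baseline")
  p <- bin_means(post, n_post_bins, "post")
  norm <- mean(b$value[1:2])
  if (norm <= 0) abort("mean of the first two baseline bins is not > 0.")
  out <- bind_rows(mutate(b, segment = "baseline", .before = 1L),
                   mutate(p, segment = "post", .before = 1L)) |>
    mutate(value = .data$value / norm)
  class(out) <- c("delta_timecourse", class(out))
  out
}
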