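# broom-style tidiers for result objects.

#' Per-spindle coupling table
#' @param x An `so_coupling` object.
#' @param ... Unused.
#' @return Tibble of included spindles with `phase_deg` and pairing
#'   columns.
#' @export
tidy.so_coupling <- function(x, ...) tibble::as_tibble(x$spindles)

#' One-row coupling summary
#' @param x An `so_coupling` object.
#' @param ... Unused.
#' @return One-row tibble: `n_included`, `n_excluded`, `as_fraction`,
#'   `ss_fraction`, `circ_mean_deg`, `resultant_length`.
#' @export
glance.so_coupling <- function(x, ...) {
  ph <- x$spindles$phase_deg
  cm <- if (length(ph) > 0L) circular_mean_deg(ph) else NA_real_
  rl <- if (length(ph) > 0L) resultant_length(ph) else NA_real_
  tibble(n_included = x$n_included, n_excluded = x$n_excluded,
         as_fraction = x$as_fraction, ss_fraction = x$ss_fraction,
         circ_mean_deg = cm, resultant_length = rl)
}

#' Circular mean of phases in degrees
#' @param phases_deg Phases in degrees.
#' @return Circular mean in (-180, 180].
#' @export
circular_mean_deg <- function(phases_deg) {
  r <- phases_deg * pi / 180
  wrap_deg(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Mean resultant length of phases
#' @param phases_deg Phases in degrees.
#' @return Resultant length in \[0, 1\] (0 = uniform, 1 = concentrated).
#' @export
resultant_length <- function(phases_deg) {
  r <- phases_deg * pi / 180
  sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

#' Summary of detected slow oscillations
#' @param x An `so_events` tibble.
#' @param ... Unused.
#' @return One-row tibble: `n_events`, `n_candidates`, `Y1` (mean
#'   candidate trough, uV), `Y2` (mean candidate peak, uV), mean selected
#'   trough/peak.
#' @export
glance.so_events <- function(x, ...) {
  tibble(n_events = nrow(x),
         n_candidates = attr(x, "n_candidates") %||% NA_integer_,
         Y1 = attr(x, "Y1") %||% NA_real_,
         Y2 = attr(x, "Y2") %||% NA_real_,
         mean_y1 = if (nrow(x)) mean(x$y1_uv) else NA_real_,
         mean_y2 = if (nrow(x)) mean(x$y2_uv) else NA_real_)
}

#' Summary of detected spindles
#' @param x A `spindle_events` tibble.
#' @param ... Unused.
#' @return One-row tibble with event count, threshold, mean duration,
#'   amplitude, intra-frequency and the share of events with a
#'   distinguishable frequency peak.
#' @export
glance.spindle_events <- function(x, ...) {
  tibble(n_events = nrow(x),
         threshold_uv2 = attr(x, "threshold") %||% NA_real_,
         mean_duration_s = if (nrow(x)) mean(x$duration_s) else NA_real_,
         mean_amplitude_uv2 = if (nrow(x)) mean(x$amplitude_uv2)
           else NA_real_,
         mean_intra_freq_hz = if (any(!is.na(x$intra_freq_hz)))
           mean(x$intra_freq_hz, na.rm = TRUE) else NA_real_,
         freq_peak_share = if (nrow(x)) mean(!is.na(x$intra_freq_hz))
           else NA_real_)
}
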