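# ggplot2 displays for the main result types.

#' Plot a power spectrum
#'
#' Line plot of the (normalized) density with the canonical SO, delta and
#' sigma bands shaded.
#'
#' @param object An `lfp_spectrum`.
#' @param f_max Upper frequency limit in Hz (default 35).
#' @param bands Band tibble to shade (default [default_bands()]; `NULL`
#'   for none).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lfp_spectrum <- function(object, f_max = 35,
                                  bands = default_bands(), ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$freq <= f_max)
  ylab <- if (isTRUE(attr(object, "normalized"))) {
    "power (% of 0-35 Hz sum)"
  } else {
    "power (a.u.)"
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$freq, y = .data$power))
  if (!is.null(bands)) {
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf,
                   ymax = Inf, fill = .data$band),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = ylab, fill = "band") +
    ggplot2::theme_minimal()
}

#' Plot spindle occurrence by slow-oscillation phase
#'
#' Bar histogram of spindle-onset phases; the active state (-180, 0) is
#' the rising trough-to-peak flank.
#'
#' @param object An `so_coupling` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.so_coupling <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid,
                               y = .data$occurrence_pct)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_lo[1:2] %||%
                                     c(0, 30))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "SO phase at spindle onset (deg)",
                  y = "occurrence (% of spindles)") +
    ggplot2::theme_minimal()
}

#' Plot a delta-power time course
#'
#' Normalized delta power over the equal-epoch quantile bins, baseline and
#' post segments side by side.
#'
#' @param object A `delta_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.delta_timecourse <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    group_by(.data$segment) |>
    mutate(i = dplyr::row_number()) |>
    ungroup() |>
    mutate(i = ifelse(.data$segment == "post",
                      .data$i + max(.data$i[.data$segment == "baseline"]),
                      .data$i))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$i, y = .data$value,
                                    colour = .data$segment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "NREMS quantile bin",
                  y = "delta power (norm.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram
#'
#' Step display of the vigilance-state sequence.
#'
#' @param hyp A `hypnogram`.
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(hyp) {
  el <- epoch_length(hyp)
  dat <- tibble(t_min = hyp$epoch * el / 60,
                state = factor(hyp$state,
                               levels = c("ARTIFACT", "REMS", "NREMS",
                                          "WAKE")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_min,
                                    y = as.integer(.data$state))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = seq_len(nlevels(dat$state)),
                                labels = levels(dat$state)) +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
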