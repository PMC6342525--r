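# End-to-end orchestration per recording, plus the group-comparison
# reporting stage (normality-screened t / rank tests with Bonferroni
# adjustment when more than two comparisons share a data set).

.config_keys <- c("recording", "hypnogram", "channel", "out_dir", "bands",
                  "min_bout_s", "spindle", "so", "coupling", "group",
                  "seed", "schema_version")
.spindle_keys <- c("band", "smooth_s", "transition", "min_cycles",
                   "fuse_s", "min_cycles_mode", "fixed_min_s", "threshold",
                   "intra_freq_on")
.so_keys <- c("cutoff", "transition")
.coupling_keys <- c("min_overlap", "bin_deg", "invert_polarity")

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Stage parameter lists are
#' validated against the known keys, so a typo in e.g. a band edge name is
#' an error rather than a silently ignored setting.
#'
#' @param recording An `lfp_recording` or a path readable by
#'   [read_recording()].
#' @param hypnogram A `hypnogram` or a path readable by
#'   [read_hypnogram()].
#' @param channel Channel index or label (default 1).
#' @param out_dir Optional output directory; when given, all stage tables
#'   and a summary JSON are written there.
#' @param bands Band tibble as in [default_bands()].
#' @param min_bout_s NREMS consolidation threshold (default 20, strict).
#' @param spindle,so,coupling Named lists of stage parameter overrides
#'   (see [detect_spindles()], [detect_so()],
#'   [spindle_so_coupling()]).
#' @param group Optional group label (e.g. `"WT"` / `"KO"`).
#' @param seed Optional seed recorded in the config (the pipeline itself
#'   is deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(recording, hypnogram, channel = 1L,
                            out_dir = NULL, bands = default_bands(),
                            min_bout_s = 20, spindle = list(),
                            so = list(), coupling = list(),
                            group = NA_character_, seed = NULL) {
  check_keys <- function(lst, keys, what) {
    bad <- setdiff(names(lst), keys)
    if (length(bad) > 0L) {
      abort(sprintf("unknown %s parameter(s): %s", what,
                    paste(bad, collapse = ", ")))
    }
  }
  check_keys(spindle, .spindle_keys, "spindle")
  check_keys(so, .so_keys, "so")
  check_keys(coupling, .coupling_keys, "coupling")
  structure(
    list(recording = recording, hypnogram = hypnogram,
         channel = channel, out_dir = out_dir,
         bands = tibble::as_tibble(bands), min_bout_s = min_bout_s,
         spindle = spindle, so = so, coupling = coupling, group = group,
         seed = seed, schema_version = 1L),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' YAML round trip for path-based configurations (the recording and
#' hypnogram entries must be file paths). Unknown keys in a read file are
#' errors.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly ([write_pipeline_config()]); a
#'   `pipeline_config` ([read_pipeline_config()]).
#' @export
write_pipeline_config <- function(config, path) {
  if (!is.character(config$recording) || !is.character(config$hypnogram)) {
    abort("only path-based configurations can be written to file.")
  }
  x <- unclass(config)
  x$bands <- as.list(as.data.frame(config$bands))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  bad <- setdiff(names(x), .config_keys)
  if (length(bad) > 0L) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!identical(as.integer(x$schema_version), 1L)) {
    abort("unsupported configuration schema version.")
  }
  pipeline_config(
    recording = x$recording, hypnogram = x$hypnogram,
    channel = x$channel %||% 1L, out_dir = x$out_dir,
    bands = tibble::as_tibble(x$bands), min_bout_s = x$min_bout_s %||% 20,
    spindle = x$spindle %||% list(), so = x$so %||% list(),
    coupling = x$coupling %||% list(),
    group = x$group %||% NA_character_, seed = x$seed)
}

#' Run the full NREMS analysis pipeline
#'
#' Stages: NREMS bout extraction -> state-restricted normalized power
#' spectrum and band powers -> spindle detection -> slow-oscillation
#' detection -> spindle-SO phase coupling -> summary metrics. The result
#' is a pure function of the inputs and configuration; each stage logs its
#' event counts, and a stage failure aborts with a stage-tagged message.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress stage messages (default `FALSE`).
#' @return A list of class `sleep_pipeline` with elements `config`,
#'   `bouts`, `spectrum` (normalized), `band_powers`, `spindles`, `so`,
#'   `coupling` and `summary` (one-row tibble, see
#'   [glance.sleep_pipeline()]).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  rec <- stage("input", {
    if (is.character(config$recording)) read_recording(config$recording)
    else config$recording
  })
  hyp <- stage("input", {
    if (is.character(config$hypnogram)) read_hypnogram(config$hypnogram)
    else config$hypnogram
  })
  bouts <- stage("bouts", {
    b <- extract_bouts(hyp, "NREMS", config$min_bout_s)
    if (nrow(b) == 0L) abort("no NREMS bouts.")
    b
  })
  say("bouts: %d consolidated NREMS bouts (%.1f min)", nrow(bouts),
      sum(bouts$duration_s) / 60)
  spectrum <- stage("spectrum", {
    segs <- concatenate_state_segments(rec, bouts, config$channel)
    normalize_spectrum(power_spectrum(segs, rec$fs))
  })
  bp <- stage("spectrum", band_powers(spectrum, config$bands))
  say("spectrum: %d windows; band powers %s", attr(spectrum, "n_windows"),
      paste(sprintf("%s=%.2f%%", bp$band, bp$power), collapse = ", "))
  spindles <- stage("spindles", {
    do.call(detect_spindles,
            c(list(rec = rec, hyp = hyp, channel = config$channel,
                   min_bout_s = config$min_bout_s), config$spindle))
  })
  say("spindles: %d events (threshold %.1f uV^2)", nrow(spindles),
      attr(spindles, "threshold"))
  so <- stage("so", {
    do.call(detect_so,
            c(list(rec = rec, hyp = hyp, channel = config$channel,
                   min_bout_s = config$min_bout_s), config$so))
  })
  say("so: %d events from %d candidates", nrow(so),
      attr(so, "n_candidates"))
  coupling <- stage("coupling", {
    do.call(spindle_so_coupling,
            c(list(rec = rec, spindles = spindles, so = so, hyp = hyp,
                   channel = config$channel,
                   min_bout_s = config$min_bout_s), config$coupling))
  })
  say("coupling: %d included / %d excluded spindles",
      coupling$n_included, coupling$n_excluded)
  nrems_min <- sum(bouts$duration_s) / 60
  summary <- tibble(
    group = config$group,
    channel = rec$channel_labels[resolve_channel(rec, config$channel)],
    n_bouts = nrow(bouts), nrems_min = nrems_min,
    so_power_pct = bp$power[match("SO", bp$band)],
    delta_power_pct = bp$power[match("delta", bp$band)],
    sigma_power_pct = bp$power[match("sigma", bp$band)],
    n_spindles = nrow(spindles),
    spindle_density_per_min = nrow(spindles) / nrems_min,
    spindle_amp_uv2 = if (nrow(spindles)) mean(spindles$amplitude_uv2)
      else NA_real_,
    spindle_freq_hz = if (any(!is.na(spindles$intra_freq_hz)))
      mean(spindles$intra_freq_hz, na.rm = TRUE) else NA_real_,
    freq_peak_share = if (nrow(spindles))
      mean(!is.na(spindles$intra_freq_hz)) else NA_real_,
    n_so = nrow(so),
    as_fraction = coupling$as_fraction,
    n_coupled = coupling$n_included)
  out <- structure(
    list(config = config, bouts = bouts, spectrum = spectrum,
         band_powers = bp, spindles = spindles, so = so,
         coupling = coupling, summary = summary),
    class = "sleep_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(result$spectrum),
                   file.path(dir, "spectrum.tsv"), progress = FALSE)
  write_events(result$spindles, file.path(dir, "spindles.tsv"))
  write_events(tibble::as_tibble(result$so),
               file.path(dir, "so_events.tsv"))
  write_events(result$coupling$spindles, file.path(dir, "coupling.tsv"))
  jsonlite::write_json(
    c(as.list(result$summary),
      list(histogram = result$coupling$histogram)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' @export
print.sleep_pipeline <- function(x, ...) {
  cat("<sleep_pipeline>\n")
  print(glance(x))
  invisible(x)
}

#' One-row pipeline summary
#' @param x A `sleep_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble of recording-level metrics.
#' @export
glance.sleep_pipeline <- function(x, ...) x$summary

#' Tidy pipeline results
#' @param x A `sleep_pipeline`.
#' @param what One of `"spindles"`, `"so"`, `"spectrum"`, `"bands"`,
#'   `"coupling"`, `"bouts"`.
#' @param ... Unused.
#' @return The requested stage table as a tibble.
#' @export
tidy.sleep_pipeline <- function(x, what = c("spindles", "so", "spectrum",
                                            "bands", "coupling", "bouts"),
                                ...) {
  what <- match.arg(what)
  tibble::as_tibble(switch(what,
    spindles = x$spindles, so = x$so, spectrum = x$spectrum,
    bands = x$band_powers, coupling = x$coupling$spindles,
    bouts = x$bouts))
}

#' Compare a metric between groups
#'
#' Test-selection rule used for genotype/site comparisons: Shapiro-Wilk
#' normality screen on each group (or on the paired differences), then
#' Student's t-test for normal data or the Mann-Whitney / Wilcoxon
#' signed-rank test otherwise. When more than two comparisons share a data
#' set, report the Bonferroni-adjusted alpha (e.g. 0.05/3 ~ 0.017 for the
#' three frequency bands).
#'
#' @param data Data frame with one row per animal (x area).
#' @param metric Column name (string) of the metric to compare.
#' @param group Column name (string) of the two-level group factor.
#' @param paired Paired design (default `FALSE`); rows must be aligned
#'   within group.
#' @param n_comparisons Number of comparisons sharing the data set
#'   (default 1); the adjusted alpha is `alpha / n_comparisons` when
#'   `n_comparisons > 2`, else `alpha`.
#' @param alpha Nominal alpha (default 0.05).
#' @param shapiro_alpha Normality-screen alpha (default 0.05).
#' @return One-row tibble: `metric`, `test`, `statistic`, `p_value`,
#'   `n1`, `n2`, `normal`, `alpha_adjusted`, `significant`.
#' @export
group_compare <- function(data, metric, group, paired = FALSE,
                          n_comparisons = 1, alpha = 0.05,
                          shapiro_alpha = 0.05) {
  if (!metric %in% names(data)) {
    abort(sprintf("no column '%s' in `data`.", metric))
  }
  if (!group %in% names(data)) {
    abort(sprintf("no column '%s' in `data`.", group))
  }
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2L) abort("`group` must have exactly two levels.")
  x <- data[[metric]][g == levels(g)[1L]]
  y <- data[[metric]][g == levels(g)[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    abort("need at least two animals per group.")
  }
  normal <- if (paired) {
    if (length(x) != length(y)) abort("paired design needs equal n.")
    d <- x - y
    length(d) >= 3L && stats::sd(d) > 0 &&
      shapiro.test(d)$p.value >= shapiro_alpha
  } else {
    ok <- function(v) length(v) >= 3L && stats::sd(v) > 0 &&
      shapiro.test(v)$p.value >= shapiro_alpha
    ok(x) && ok(y)
  }
  res <- if (normal) {
    t.test(x, y, paired = paired)
  } else if (paired) {
    suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
  } else {
    suppressWarnings(wilcox.test(x, y, exact = FALSE))
  }
  alpha_adj <- if (n_comparisons > 2) alpha / n_comparisons else alpha
  tibble(metric = metric,
         test = res$method,
         statistic = unname(res$statistic),
         p_value = res$p.value,
         n1 = length(x), n2 = length(y),
         normal = normal,
         alpha_adjusted = alpha_adj,
         significant = res$p.value < alpha_adj)
}

#' Compare several metrics between two groups
#'
#' Runs [group_compare()] for each metric with
#' `n_comparisons = length(metrics)`, i.e. Bonferroni adjustment across the
#' metrics when there are more than two.
#'
#' @param data Data frame with one row per animal (x area).
#' @param metrics Character vector of metric column names.
#' @param group Group column name.
#' @param ... Passed to [group_compare()].
#' @return Tibble with one row per metric.
#' @export
compare_metrics <- function(data, metrics, group, ...) {
  bind_rows(map(metrics, function(m) {
    group_compare(data, m, group, n_comparisons = length(metrics), ...)
  }))
}
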