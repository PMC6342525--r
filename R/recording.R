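# Recording container and readers/writers.
#
# A recording is a channels x time matrix of local field potential / EEG
# samples in microvolts with a single sampling rate. Sample index i (1-based
# in R) maps to time start_time_s + (i - 1) / fs; all intervals in the
# package are half-open [start, end).

#' Construct a recording
#'
#' @param samples Numeric matrix (channels x time) in microvolts, or a
#'   numeric vector for a single channel.
#' @param fs Sampling rate in Hz (> 0), shared by all channels.
#' @param channel_labels Character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param start_time_s Time of the first sample in seconds (default 0).
#' @return An object of class `lfp_recording`.
#' @export
recording <- function(samples, fs, channel_labels = NULL, start_time_s = 0) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (channels x time).")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  nch <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch) {
    abort("`channel_labels` must have one entry per channel.")
  }
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         start_time_s = start_time_s),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `lfp_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Read a continuous recording
#'
#' Supported formats: `edf` (European Data Format, 16-bit), `tsv`
#' (one column per channel, header row of channel labels, with a JSON
#' sidecar `<path>.json` holding at least `fs`), and `binary_matrix`
#' (raw little-endian doubles, channel-major, with the same JSON sidecar
#' additionally holding `n_channels`). Values are returned in microvolts.
#'
#' @param path Path to the data file.
#' @param format One of `"auto"`, `"edf"`, `"tsv"`, `"binary_matrix"`.
#'   `"auto"` picks by file extension (.edf / .tsv / .bin).
#' @return An `lfp_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "tsv",
                                            "binary_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf", tsv = "tsv", txt = "tsv", bin = "binary_matrix",
      abort(sprintf("cannot infer recording format from extension '.%s'.",
                    ext)))
  }
  switch(format,
    edf = read_edf(path),
    tsv = read_recording_tsv(path),
    binary_matrix = read_recording_bin(path))
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) {
    abort(sprintf("missing sidecar metadata file: %s (need at least `fs`).",
                  sc))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs)) {
    abort(sprintf("sidecar %s does not declare a sampling rate `fs`.", sc))
  }
  meta
}

read_recording_tsv <- function(path) {
  meta <- read_sidecar(path)
  dat <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE)
  if (nrow(dat) == 0L) abort(sprintf("recording file %s has no samples.",
                                     path))
  labels <- meta$channel_labels %||% names(dat)
  m <- t(as.matrix(dat))
  dimnames(m) <- NULL
  recording(m, fs = meta$fs, channel_labels = labels,
            start_time_s = meta$start_time_s %||% 0)
}

read_recording_bin <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta$n_channels)) {
    abort("binary_matrix sidecar must declare `n_channels`.")
  }
  nbytes <- file.info(path)$size
  n <- nbytes / 8L
  vals <- readBin(path, what = "double", n = n, size = 8L,
                  endian = "little")
  nch <- meta$n_channels
  if (length(vals) %% nch != 0L) {
    abort("binary_matrix length is not a multiple of `n_channels`.")
  }
  recording(matrix(vals, nrow = nch, byrow = TRUE), fs = meta$fs,
            channel_labels = meta$channel_labels %||% NULL,
            start_time_s = meta$start_time_s %||% 0)
}

#' Write a recording
#'
#' Inverse of [read_recording()]. For `tsv` and `binary_matrix` a JSON
#' sidecar `<path>.json` is written alongside the data file. EDF output is
#' 16-bit and therefore quantized to the physical range of each channel.
#'
#' @param rec An `lfp_recording`.
#' @param path Output path.
#' @param format `"tsv"`, `"binary_matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            format = c("tsv", "binary_matrix", "edf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dat <- as.data.frame(t(rec$samples))
    names(dat) <- rec$channel_labels
    readr::write_tsv(tibble::as_tibble(dat), path, progress = FALSE)
    jsonlite::write_json(
      list(fs = rec$fs, channel_labels = rec$channel_labels,
           start_time_s = rec$start_time_s),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else if (format == "binary_matrix") {
    writeBin(as.numeric(t(rec$samples)), path, size = 8L,
             endian = "little")
    jsonlite::write_json(
      list(fs = rec$fs, n_channels = nrow(rec$samples),
           channel_labels = rec$channel_labels,
           start_time_s = rec$start_time_s),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

# ---- minimal EDF (European Data Format) support ----------------------------
# Fixed-width ASCII header (256 bytes + 256 per signal), then data records of
# little-endian int16 scaled linearly from digital to physical range.

edf_field <- function(s, offset, len) trimws(substr(s, offset + 1L,
                                                    offset + len))

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- rawToChar(readBin(con, "raw", 256L))
  if (nchar(hdr, type = "bytes") < 256L) abort("truncated EDF header.")
  n_records <- suppressWarnings(as.integer(edf_field(hdr, 236L, 8L)))
  rec_dur <- suppressWarnings(as.numeric(edf_field(hdr, 244L, 8L)))
  ns <- suppressWarnings(as.integer(edf_field(hdr, 252L, 4L)))
  if (is.na(ns) || ns < 1L || is.na(rec_dur) || rec_dur <= 0) {
    abort(sprintf("%s does not parse as EDF.", path))
  }
  sh <- rawToChar(readBin(con, "raw", 256L * ns))
  per <- function(offset, len) {
    vapply(seq_len(ns) - 1L,
           function(k) edf_field(sh, offset * ns + k * len, len), "")
  }
  labels <- per(0L, 16L)
  dims <- per(96L, 8L)
  pmin_ <- as.numeric(per(104L, 8L))
  pmax_ <- as.numeric(per(112L, 8L))
  dmin_ <- as.numeric(per(120L, 8L))
  dmax_ <- as.numeric(per(128L, 8L))
  nsamp <- as.integer(per(216L, 8L))
  if (length(unique(nsamp)) != 1L) {
    abort("EDF channels with differing sampling rates are not supported.")
  }
  fs <- nsamp[1L] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  # convert to microvolts if the dimension field says millivolts
  unit_mult <- ifelse(tolower(dims) %in% c("mv"), 1000,
                      ifelse(tolower(dims) %in% c("v"), 1e6, 1))
  total <- n_records * sum(nsamp)
  raw16 <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                   endian = "little")
  if (length(raw16) < total) abort("truncated EDF data section.")
  out <- matrix(0, nrow = ns, ncol = n_records * nsamp[1L])
  per_rec <- sum(nsamp)
  offs <- cumsum(c(0L, nsamp))[seq_len(ns)]
  for (r in seq_len(n_records)) {
    block <- raw16[((r - 1L) * per_rec + 1L):(r * per_rec)]
    for (ch in seq_len(ns)) {
      seg <- block[(offs[ch] + 1L):(offs[ch] + nsamp[ch])]
      out[ch, ((r - 1L) * nsamp[ch] + 1L):(r * nsamp[ch])] <-
        (seg - dmin_[ch]) * scale[ch] + pmin_[ch]
    }
  }
  out <- out * unit_mult
  recording(out, fs = fs, channel_labels = labels)
}

fmt_fixed <- function(x, width) {
  s <- if (is.numeric(x)) {
    format(x, scientific = FALSE, trim = TRUE, digits = 15)
  } else {
    as.character(x)
  }
  if (nchar(s, type = "bytes") > width && is.numeric(x)) {
    s <- format(signif(x, max(2L, width - 3L)), scientific = FALSE,
                trim = TRUE)
  }
  if (nchar(s, type = "bytes") > width) {
    abort(sprintf("EDF header field '%s' exceeds %d bytes.", s, width))
  }
  sprintf(paste0("%-", width, "s"), s)
}

write_edf <- function(rec, path, record_dur_s = 1) {
  ns <- nrow(rec$samples)
  nsamp <- as.integer(round(rec$fs * record_dur_s))
  n_records <- floor(ncol(rec$samples) / nsamp)
  if (n_records < 1L) abort("recording shorter than one EDF data record.")
  pmax_ <- apply(rec$samples, 1L, function(v) max(abs(range(v)), 1))
  pmin_ <- -pmax_
  dmax_ <- 32767
  dmin_ <- -32768
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    fmt_fixed("0", 8L), fmt_fixed("synthetic", 80L),
    fmt_fixed("sleeplfp", 80L), fmt_fixed("01.01.26", 8L),
    fmt_fixed("00.00.00", 8L), fmt_fixed(256L * (1L + ns), 8L),
    fmt_fixed("", 44L), fmt_fixed(n_records, 8L),
    fmt_fixed(format(record_dur_s), 8L), fmt_fixed(ns, 4L))
  sig <- paste0(
    paste(vapply(rec$channel_labels, fmt_fixed, "", width = 16L),
          collapse = ""),
    paste(rep(fmt_fixed("", 80L), ns), collapse = ""),
    paste(rep(fmt_fixed("uV", 8L), ns), collapse = ""),
    paste(vapply(pmin_, fmt_fixed, "", width = 8L), collapse = ""),
    paste(vapply(pmax_, fmt_fixed, "", width = 8L), collapse = ""),
    paste(rep(fmt_fixed(dmin_, 8L), ns), collapse = ""),
    paste(rep(fmt_fixed(dmax_, 8L), ns), collapse = ""),
    paste(rep(fmt_fixed("", 80L), ns), collapse = ""),
    paste(rep(fmt_fixed(nsamp, 8L), ns), collapse = ""),
    paste(rep(fmt_fixed("", 32L), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  scale <- (dmax_ - dmin_) / (pmax_ - pmin_)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * nsamp + 1L):(r * nsamp)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, cols] - pmin_[ch]) * scale[ch] + dmin_)
      dig <- as.integer(pmin(pmax(dig, dmin_), dmax_))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
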