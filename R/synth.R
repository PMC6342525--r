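# Ground-truth synthetic LFP generator.
#
# NREMS stretches are built as: slow-oscillation (SO) sinusoid + delta-band
# filtered noise + 1/f background; discrete waxing-waning spindle bursts are
# added with onsets drawn at a preferred SO phase (von Mises). Wake and REMS
# stretches carry background noise only. Every injected event is returned as
# ground truth so detector recall, precision and phase recovery can be
# measured exactly.

#' Parameters of the synthetic LFP generator
#'
#' Defaults describe a spindle-rich somatosensory-cortex-like NREMS signal
#' sampled at 1 kHz: an SO at 0.6 Hz, delta-band noise, a 1/f background,
#' and 11 Hz spindles of about 0.7 s at 6 events per minute of NREMS whose
#' onsets prefer the early SO active state (-150 deg, i.e. shortly after
#' the trough on the rising flank).
#'
#' @param duration_s Total recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param spindle_rate Spindle events per minute of NREMS.
#' @param spindle_freq_mean,spindle_freq_sd Intra-spindle frequency draw
#'   (Hz); mean must lie in the 9-16 Hz detection band.
#' @param spindle_duration_mean,spindle_duration_sd Spindle duration draw
#'   (s, full waveform support).
#' @param spindle_amp Peak spindle amplitude in microvolts.
#' @param so_freq SO frequency in Hz (0.5-1.5).
#' @param so_amp SO amplitude in microvolts.
#' @param delta_amp RMS of the delta-band (1.5-4 Hz) component, microvolts.
#' @param noise_exponent Spectral slope of the 1/f^a background (a >= 0).
#' @param noise_amp RMS of the background noise, microvolts.
#' @param phase_pref_deg Preferred SO phase of spindle onsets, degrees in
#'   (-180, 180] with 0 = SO peak, +/-180 = trough.
#' @param phase_kappa von Mises concentration of onset phases (0 =
#'   uniform).
#' @param state_sequence Optional character vector of per-epoch states; by
#'   default a repeating wake / NREMS / REMS motif filling `duration_s`.
#' @param epoch_len_s Hypnogram epoch length in seconds.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(duration_s = 600, fs = 1000,
                         spindle_rate = 6,
                         spindle_freq_mean = 11, spindle_freq_sd = 0.5,
                         spindle_duration_mean = 0.7,
                         spindle_duration_sd = 0.08,
                         spindle_amp = 75,
                         so_freq = 0.6, so_amp = 150,
                         delta_amp = 50,
                         noise_exponent = 1, noise_amp = 30,
                         phase_pref_deg = -150, phase_kappa = 2,
                         state_sequence = NULL, epoch_len_s = 4) {
  p <- list(duration_s = duration_s, fs = fs, spindle_rate = spindle_rate,
            spindle_freq_mean = spindle_freq_mean,
            spindle_freq_sd = spindle_freq_sd,
            spindle_duration_mean = spindle_duration_mean,
            spindle_duration_sd = spindle_duration_sd,
            spindle_amp = spindle_amp, so_freq = so_freq, so_amp = so_amp,
            delta_amp = delta_amp, noise_exponent = noise_exponent,
            noise_amp = noise_amp, phase_pref_deg = phase_pref_deg,
            phase_kappa = phase_kappa, state_sequence = state_sequence,
            epoch_len_s = epoch_len_s)
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  amps <- c(p$spindle_amp, p$so_amp, p$delta_amp, p$noise_amp)
  if (any(amps < 0)) abort("all amplitudes must be >= 0.")
  if (p$spindle_freq_mean < 9 || p$spindle_freq_mean > 16) {
    abort("`spindle_freq_mean` must lie in [9, 16] Hz.")
  }
  if (p$so_freq < 0.5 || p$so_freq > 1.5) {
    abort("`so_freq` must lie in [0.5, 1.5] Hz.")
  }
  if (p$phase_pref_deg <= -180 || p$phase_pref_deg > 180) {
    abort("`phase_pref_deg` must lie in (-180, 180].")
  }
  if (p$phase_kappa < 0) abort("`phase_kappa` must be >= 0.")
  if (p$spindle_rate < 0) abort("`spindle_rate` must be >= 0.")
  if (p$duration_s < p$epoch_len_s) {
    abort("`duration_s` must cover at least one epoch.")
  }
  invisible(p)
}

#' Genotype/area presets for the generator
#'
#' `wt_s1`: spindle-rich, SO-dominated somatosensory signal. `ko_s1`:
#' spindle-poor with strongly reduced spindle rate and amplitude, reduced
#' SO and over-represented delta (the knockout-like contrast). `wt_pfc`:
#' prefrontal-like, SO-dominated with weak spindles.
#'
#' @param name One of `"wt_s1"`, `"ko_s1"`, `"wt_pfc"`.
#' @param ... Overrides passed on to [synth_params()].
#' @return A `synth_params` object.
#' @export
preset <- function(name = c("wt_s1", "ko_s1", "wt_pfc"), ...) {
  if (length(name) != 1L || !name %in% c("wt_s1", "ko_s1", "wt_pfc")) {
    abort(sprintf("unknown preset '%s'.", paste(name, collapse = ",")))
  }
  base <- switch(name,
    wt_s1 = list(spindle_rate = 6, spindle_amp = 75, so_amp = 150,
                 delta_amp = 50),
    ko_s1 = list(spindle_rate = 1.5, spindle_amp = 25, so_amp = 100,
                 delta_amp = 110),
    wt_pfc = list(spindle_rate = 2, spindle_amp = 30, so_amp = 180,
                  delta_amp = 60))
  do.call(synth_params, utils::modifyList(base, list(...)))
}

#' Waxing-waning spindle waveform
#'
#' A sinusoid at `freq_hz` under a symmetric Hann envelope: zero at both
#' ends, peak amplitude exactly `amp` at the center (the carrier phase is
#' aligned so the center sample sits on a carrier peak).
#'
#' @param duration_s Duration in seconds; must cover at least 3 cycles.
#' @param freq_hz Carrier frequency in Hz.
#' @param amp Peak amplitude in microvolts.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of odd length `~ duration_s * fs`.
#' @export
make_spindle_waveform <- function(duration_s, freq_hz, amp, fs) {
  if (duration_s < 3 / freq_hz) {
    abort(sprintf(
      "spindle duration %.3f s covers < 3 cycles at %.1f Hz.",
      duration_s, freq_hz))
  }
  n <- round(duration_s * fs)
  if (n %% 2L == 0L) n <- n + 1L
  k <- seq_len(n) - 1L
  env <- 0.5 * (1 - cos(2 * pi * k / (n - 1L)))
  tc <- (n - 1L) / 2L / fs
  phi <- pi / 2 - 2 * pi * freq_hz * tc
  amp * env * sin(2 * pi * freq_hz * k / fs + phi)
}

#' 1/f^a background noise
#'
#' Gaussian noise spectrally shaped to a power spectral density
#' proportional to `1/f^noise_exponent` (DC removed), rescaled to an exact
#' RMS of `noise_amp`.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param noise_exponent Spectral slope a >= 0 (0 = white).
#' @param noise_amp Target RMS in microvolts.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [generate_recording()]).
#' @return Numeric vector of length `duration_s * fs`.
#' @export
make_background <- function(duration_s, fs, noise_exponent = 1,
                            noise_amp = 30, seed = NULL) {
  if (noise_exponent < 0) abort("`noise_exponent` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  if (n < 2L) abort("background too short.")
  w <- stats::rnorm(n)
  if (noise_amp == 0) return(numeric(n))
  f <- c(0, seq_len(n - 1L)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror to physical frequency
  shape <- numeric(n)
  shape[-1L] <- f[-1L]^(-noise_exponent / 2)
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * noise_amp / sqrt(mean(x^2))
}

# von Mises sampler, Best & Fisher (1979); mu, output in radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      th <- mu + sign(u[3L] - 0.5) * acos(f)
      out[i] <- atan2(sin(th), cos(th))
      i <- i + 1L
    }
  }
  out
}

#' Draw spindle-onset SO phases
#'
#' von Mises draw of onset phases around the preferred phase;
#' `phase_kappa = 0` gives the circular uniform distribution.
#'
#' @param n Number of draws.
#' @param phase_pref_deg Preferred phase, degrees in (-180, 180].
#' @param phase_kappa Concentration (>= 0).
#' @return Phases in degrees, (-180, 180].
#' @export
sample_onset_phases <- function(n, phase_pref_deg, phase_kappa) {
  wrap_deg(rvonmises(n, phase_pref_deg * pi / 180, phase_kappa) * 180 / pi)
}

default_state_sequence <- function(duration_s, epoch_len_s = 4) {
  n_ep <- floor(duration_s / epoch_len_s)
  motif <- c(rep("WAKE", round(60 / epoch_len_s)),
             rep("NREMS", round(240 / epoch_len_s)),
             rep("REMS", round(40 / epoch_len_s)))
  rep(motif, length.out = n_ep)
}

#' Generate a ground-truth synthetic recording
#'
#' Deterministic given `seed`. NREMS bouts receive an SO sinusoid, a
#' delta-band noise component (both tapered over 1 s at bout edges) and
#' injected spindle bursts on top of the 1/f background; other states are
#' background only. The spindle count is Poisson with mean
#' `spindle_rate x NREMS minutes`; each onset phase is a von Mises draw and
#' the spindle is anchored so that its half-maximum onset falls at that
#' phase of the SO cycle. Spindles that cannot be placed (outside bout
#' margins or overlapping a previous spindle after 25 retries) are skipped
#' and counted in the `n_skipped` ground-truth field.
#'
#' @param params A `synth_params` object.
#' @param seed Integer seed; the single RNG stream for all draws.
#' @return A list with elements `recording` ([recording()]), `hypnogram`
#'   ([hypnogram()]) and `ground_truth` (list of tibbles `spindles`, `so`,
#'   plus `n_skipped`). Ground-truth spindle `onset_s`/`offset_s` are the
#'   half-maximum points of the injected envelope; the full zero-amplitude
#'   support is in `support_start_s`/`support_end_s`.
#' @export
generate_recording <- function(params, seed) {
  stopifnot(inherits(params, "synth_params"))
  validate_synth_params(params)
  set.seed(as.integer(seed))
  p <- params
  fs <- p$fs
  states <- p$state_sequence %||%
    default_state_sequence(p$duration_s, p$epoch_len_s)
  hyp <- hypnogram(states, p$epoch_len_s)
  n <- round(length(states) * p$epoch_len_s * fs)
  x <- make_background(length(states) * p$epoch_len_s, fs,
                       p$noise_exponent, p$noise_amp)
  bouts <- extract_bouts(hyp, "NREMS", min_duration_s = 0)
  ramp_s <- 1
  Tso <- 1 / p$so_freq
  so_peaks <- list()
  so_troughs <- list()
  cycle_tbl <- list()
  delta_b <- if (p$delta_amp > 0) design_fir(fs, 1.5, 4, transition = 1)
  for (k in seq_len(nrow(bouts))) {
    s <- bouts$start_s[k]
    e <- bouts$end_s[k]
    i0 <- round(s * fs) + 1L
    i1 <- round(e * fs)
    len <- i1 - i0 + 1L
    t_rel <- (seq_len(len) - 1L) / fs
    w <- rep(1, len)
    nr <- min(round(ramp_s * fs), floor(len / 2))
    if (nr > 0L) {
      ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1L) / nr))
      w[seq_len(nr)] <- ramp
      w[(len - nr + 1L):len] <- rev(ramp)
    }
    comp <- p$so_amp * sin(2 * pi * p$so_freq * t_rel)
    if (p$delta_amp > 0 && len > 3 * length(delta_b)) {
      d <- fir_filtfilt(stats::rnorm(len), delta_b)
      comp <- comp + d * p$delta_amp / sqrt(mean(d^2))
    }
    x[i0:i1] <- x[i0:i1] + comp * w
    # ground-truth SO cycles fully inside the untapered core of the bout
    kmax <- floor(((e - ramp_s) - (s + Tso / 4)) / Tso)
    if (kmax >= 1) {
      pk <- s + Tso / 4 + (seq_len(kmax) - 1L) * Tso
      full <- (pk - 0.75 * Tso) >= (s + ramp_s) &
        (pk + 0.25 * Tso) <= (e - ramp_s)
      pk <- pk[full]
      so_peaks[[k]] <- pk
      so_troughs[[k]] <- pk - Tso / 2  # trough preceding each peak
      if (length(pk) > 0L) {
        cycle_tbl[[k]] <- data.frame(bout_id = bouts$bout_id[k],
                                     peak_s = pk, bout_start = s,
                                     bout_end = e)
      }
    }
  }
  cycles <- if (length(cycle_tbl)) do.call(rbind, cycle_tbl) else
    data.frame(bout_id = integer(), peak_s = numeric(),
               bout_start = numeric(), bout_end = numeric())
  nrems_min <- sum(bouts$duration_s) / 60
  n_target <- if (p$spindle_rate > 0 && nrems_min > 0) {
    stats::rpois(1L, p$spindle_rate * nrems_min)
  } else 0L
  placed <- list()
  intervals <- matrix(numeric(0), ncol = 2L)
  n_skipped <- 0L
  if (n_target > 0L && nrow(cycles) == 0L) {
    warn("no SO cycles available for spindle placement; no spindles made.")
    n_target <- 0L
  }
  for (j in seq_len(n_target)) {
    freq <- min(max(stats::rnorm(1L, p$spindle_freq_mean,
                                 p$spindle_freq_sd), 9), 16)
    dur <- stats::rnorm(1L, p$spindle_duration_mean, p$spindle_duration_sd)
    dur <- min(max(dur, 3.5 / freq), 2)
    phase <- sample_onset_phases(1L, p$phase_pref_deg, p$phase_kappa)
    amp <- p$spindle_amp * stats::runif(1L, 0.9, 1.1)
    phi <- if (phase > 90) phase - 360 else phase
    ok <- FALSE
    for (try in seq_len(25L)) {
      cyc <- cycles[sample.int(nrow(cycles), 1L), ]
      t_on <- cyc$peak_s + phi / 360 * Tso   # half-max onset at drawn phase
      sup0 <- t_on - 0.25 * dur
      sup1 <- sup0 + dur
      if (sup0 < cyc$bout_start + ramp_s || sup1 > cyc$bout_end - ramp_s) {
        next
      }
      if (nrow(intervals) > 0L &&
          any(sup0 < intervals[, 2L] + 0.25 &
                sup1 > intervals[, 1L] - 0.25)) {
        next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    wave <- make_spindle_waveform(dur, freq, amp, fs)
    a0 <- round(sup0 * fs) + 1L
    a1 <- a0 + length(wave) - 1L
    x[a0:a1] <- x[a0:a1] + wave
    intervals <- rbind(intervals, c(sup0, sup1))
    placed[[length(placed) + 1L]] <- tibble(
      onset_s = t_on, offset_s = sup0 + 0.75 * dur,
      support_start_s = sup0, support_end_s = sup1,
      duration_s = dur, freq_hz = freq, amp_uv = amp,
      phase_deg = phase, so_peak_s = cyc$peak_s, bout_id = cyc$bout_id)
  }
  if (n_skipped > 0L) {
    warn(sprintf("%d spindle(s) could not be placed and were skipped.",
                 n_skipped))
  }
  gt_spindles <- if (length(placed)) {
    arrange(bind_rows(placed), .data$onset_s)
  } else {
    tibble(onset_s = numeric(), offset_s = numeric(),
           support_start_s = numeric(), support_end_s = numeric(),
           duration_s = numeric(), freq_hz = numeric(),
           amp_uv = numeric(), phase_deg = numeric(),
           so_peak_s = numeric(), bout_id = integer())
  }
  gt_so <- tibble(
    peak_s = unlist(so_peaks) %||% numeric(0),
    trough_s = unlist(so_troughs) %||% numeric(0))
  rec <- recording(matrix(x[seq_len(n)], nrow = 1L), fs = fs,
                   channel_labels = "LFP")
  list(recording = rec, hypnogram = hyp,
       ground_truth = list(spindles = gt_spindles, so = gt_so,
                           n_skipped = n_skipped))
}
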