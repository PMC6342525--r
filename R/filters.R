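# Low-level signal utilities: FIR design and zero-phase application,
# moving-average smoothing, analytic signal, zero crossings.
# All traces are plain numeric vectors sampled at `fs` Hz.

# full linear convolution via FFT; returns length(x) + length(b) - 1
conv_full <- function(x, b) {
  n <- length(x) + length(b) - 1L
  nf <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nf - length(x))))
  B <- stats::fft(c(b, numeric(nf - length(b))))
  Re(stats::fft(X * B, inverse = TRUE))[seq_len(n)] / nf
}

#' Design a linear-phase FIR filter
#'
#' Hamming-windowed FIR (via [signal::fir1()]) with an even order chosen for
#' the requested transition width (single-pass stop-band attenuation
#' about 53 dB; the zero-phase forward-backward application used throughout
#' the package doubles that).
#'
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz. Give both for a band-pass, only `high`
#'   for a low-pass, only `low` for a high-pass.
#' @param transition Transition width in Hz (sets the filter order,
#'   roughly `3.3 * fs / transition` taps).
#' @return Numeric vector of filter coefficients (odd length, symmetric).
#' @export
design_fir <- function(fs, low = NULL, high = NULL, transition = 2) {
  if (fs <= 0) abort("`fs` must be positive.")
  if (transition <= 0) abort("`transition` must be positive.")
  ord <- ceiling(3.3 * fs / transition)
  if (ord %% 2L == 1L) ord <- ord + 1L
  nyq <- fs / 2
  if (!is.null(low) && !is.null(high)) {
    if (!(0 < low && low < high && high < nyq)) {
      abort("band edges must satisfy 0 < low < high < fs/2.")
    }
    b <- signal::fir1(ord, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    if (!(0 < high && high < nyq)) abort("cutoff must lie in (0, fs/2).")
    b <- signal::fir1(ord, high / nyq, type = "low")
  } else if (!is.null(low)) {
    if (!(0 < low && low < nyq)) abort("cutoff must lie in (0, fs/2).")
    b <- signal::fir1(ord, low / nyq, type = "high")
  } else {
    abort("give at least one of `low`, `high`.")
  }
  as.numeric(b)
}

#' Zero-phase FIR filtering
#'
#' Applies a symmetric (linear-phase) FIR filter forward and backward with
#' odd-symmetric edge extension, so the output has exactly zero phase shift
#' and the same length as the input.
#'
#' @param x Numeric signal.
#' @param b FIR coefficients from [design_fir()] (odd length).
#' @return Filtered signal, same length as `x`.
#' @export
fir_filtfilt <- function(x, b) {
  L <- length(b)
  if (L %% 2L != 1L) abort("`b` must have odd length (even filter order).")
  n <- length(x)
  if (n <= L) {
    abort(sprintf(
      "signal too short for the filter: %d samples <= %d taps.", n, L))
  }
  d <- (L - 1L) / 2L
  pe <- min(n - 1L, L)
  left <- 2 * x[1L] - x[seq(pe + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pe)]
  xp <- c(left, x, right)
  one_pass <- function(z) conv_full(z, b)[(d + 1L):(d + length(z))]
  yp <- one_pass(xp)
  yp <- rev(one_pass(rev(yp)))
  yp[(pe + 1L):(pe + n)]
}

#' Centered moving average
#'
#' Boxcar smoothing with a centered window; at the edges the window shrinks
#' to the available samples (mean over what the window covers).
#'
#' @param x Numeric vector.
#' @param k Window length in samples; forced odd.
#' @return Smoothed vector, same length.
#' @export
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the analytic representation `x + i * H(x)` by zeroing negative
#' frequencies of the FFT and doubling positive ones.
#'
#' @param x Real numeric signal.
#' @return Complex vector, same length; `Arg()` of it is the instantaneous
#'   phase, `Mod()` the instantaneous amplitude.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) abort("signal too short for the Hilbert transform.")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero crossings of a trace. Returns a data frame with the sample index i of
# each crossing (sign change between samples i and i+1), its direction
# (+1 rising, -1 falling) and the linearly interpolated fractional position
# in (0, 1] between the two samples.
zero_crossings <- function(x) {
  n <- length(x)
  if (n < 2L) {
    return(data.frame(idx = integer(), direction = integer(),
                      frac = numeric()))
  }
  a <- x[-n]
  b <- x[-1L]
  up <- which(a <= 0 & b > 0)
  dn <- which(a >= 0 & b < 0)
  idx <- c(up, dn)
  dir <- c(rep(1L, length(up)), rep(-1L, length(dn)))
  o <- order(idx)
  idx <- idx[o]
  dir <- dir[o]
  den <- x[idx] - x[idx + 1L]
  frac <- ifelse(den == 0, 0.5, x[idx] / den)
  data.frame(idx = idx, direction = dir, frac = frac)
}

# wrap degrees to (-180, 180]
wrap_deg <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w <= -180] <- 180
  w
}
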