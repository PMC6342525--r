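# Independent oracle implementations used across tests. These deliberately
# avoid the package's own code paths (direct O(n^2) DFT, loop-based
# smoothing, explicit interval arithmetic).

# brute-force one-sided squared-magnitude DFT of a window
brute_dft_power <- function(x) {
  n <- length(x)
  nb <- n %/% 2L + 1L
  out <- numeric(nb)
  j <- seq_len(n) - 1L
  for (k in seq_len(nb) - 1L) {
    e <- exp(-2i * pi * k * j / n)
    out[k + 1L] <- Mod(sum(x * e))^2
  }
  out
}

# loop-based centered moving average with shrinking edges
brute_moving_average <- function(x, k) {
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# direct O(n * L) FIR convolution, centered (zero-phase for symmetric b),
# with the same odd edge extension as the package
brute_filtfilt <- function(x, b) {
  n <- length(x)
  L <- length(b)
  d <- (L - 1L) %/% 2L
  pe <- min(n - 1L, L)
  xp <- c(2 * x[1L] - x[seq(pe + 1L, 2L)], x,
          2 * x[n] - x[seq(n - 1L, n - pe)])
  one <- function(z) {
    m <- length(z)
    y <- numeric(m)
    zz <- c(numeric(d), z, numeric(d))
    for (i in seq_len(m)) y[i] <- sum(zz[i:(i + L - 1L)] * rev(b))
    y
  }
  y <- one(xp)
  y <- rev(one(rev(y)))
  y[(pe + 1L):(pe + n)]
}

# greedy interval matching: detected vs ground-truth events, matched when
# the overlap covers >= 50% of the shorter interval
match_intervals <- function(det_on, det_off, gt_on, gt_off,
                            min_frac = 0.5) {
  used <- rep(FALSE, length(det_on))
  hits <- 0L
  onset_err <- numeric(0)
  for (i in seq_along(gt_on)) {
    ov <- pmin(det_off, gt_off[i]) - pmax(det_on, gt_on[i])
    denom <- pmin(det_off - det_on, gt_off[i] - gt_on[i])
    f <- ov / denom
    f[used] <- -Inf
    if (length(f) == 0L) next
    j <- which.max(f)
    if (f[j] >= min_frac) {
      used[j] <- TRUE
      hits <- hits + 1L
      onset_err <- c(onset_err, det_on[j] - gt_on[i])
    }
  }
  list(recall = hits / length(gt_on),
       precision = if (length(det_on)) hits / length(det_on) else NA_real_,
       onset_err_s = onset_err)
}

# Rayleigh test p-value for circular uniformity
rayleigh_p <- function(phases_deg) {
  r <- phases_deg * pi / 180
  n <- length(r)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# von Mises concentration giving a target active-state (-180, 0) mass for a
# given preferred phase, by numerical inversion of the density integral
kappa_for_as_fraction <- function(target, mu_deg) {
  dens <- function(x, k) exp(k * cos(x - mu_deg * pi / 180)) /
    (2 * pi * besselI(k, 0))
  mass <- function(k) stats::integrate(dens, -pi, 0, k = k,
                                       subdivisions = 1000L)$value
  stats::uniroot(function(k) mass(k) - target, c(1e-3, 50))$root
}

# small all-NREMS synthetic scene used by several detector tests
nrems_scene <- function(minutes = 10, seed = 101, ...) {
  args <- list(...)
  if (is.null(args$state_sequence)) {
    args$state_sequence <- rep("NREMS", round(minutes * 60 / 4))
  }
  generate_recording(do.call(synth_params, args), seed = seed)
}

# rectangular-envelope, phase-coherent sine bursts
make_burst_trace <- function(fs, total_s, bursts, freq = 12, amp = 50) {
  # rectangular-envelope sine bursts (list of c(start, duration) in s),
  # all phase-coherent with one global carrier
  x <- numeric(round(total_s * fs))
  for (b in bursts) {
    i <- round(b[1] * fs) + seq_len(round(b[2] * fs))
    x[i] <- amp * sin(2 * pi * freq * (i - 1) / fs)
  }
  x
}
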