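# Windowed squared-FFT spectra, 0-35 Hz normalization, band integration
# and the quantile-binned delta time course.

test_that("offset correction zeroes a constant signal's spectrum", {
  ps <- power_spectrum(rep(3.7, 4000), fs = 1000)
  expect_true(all(ps$power == 0))
  expect_error(normalize_spectrum(ps), "zero")
})

test_that("a pure on-grid sine concentrates in a single bin", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  ps <- power_spectrum(sin(2 * pi * 12 * t), fs)
  expect_equal(ps$freq[2] - ps$freq[1], 0.25)
  i <- which.max(ps$power)
  expect_equal(ps$freq[i], 12)
  expect_lt(sum(ps$power[-i]) / ps$power[i], 1e-15)
})

test_that("windowed spectrum matches a brute-force DFT oracle bin-wise", {
  set.seed(11)
  fs <- 200
  seg <- rnorm(3 * 4 * fs)       # three 4 s windows
  ps <- power_spectrum(seg, fs)
  expect_equal(attr(ps, "n_windows"), 3L)
  acc <- 0
  for (w in 1:3) {
    win <- seg[((w - 1) * 4 * fs + 1):(w * 4 * fs)]
    acc <- acc + brute_dft_power(win - mean(win))
  }
  # relative error per bin; the offset-corrected DC bin is 0/0 and is
  # guarded by a floor well below any physical bin value
  floor_ <- 1e-9 * max(acc / 3)
  expect_lt(max(abs(ps$power - acc / 3) / pmax(acc / 3, floor_)), 1e-8)
})

test_that("windows never span segment boundaries and remainders drop", {
  set.seed(12)
  fs <- 100
  # 5 s and 9 s segments at 4 s windows -> 1 + 2 windows
  segs <- list(rnorm(5 * fs), rnorm(9 * fs))
  ps <- power_spectrum(segs, fs)
  expect_equal(attr(ps, "n_windows"), 3L)
  # equivalent to the per-window manual computation (remainder ignored)
  manual <- (brute_dft_power(segs[[1]][1:400] - mean(segs[[1]][1:400])) +
               brute_dft_power(segs[[2]][1:400] - mean(segs[[2]][1:400])) +
               brute_dft_power(segs[[2]][401:800] -
                                 mean(segs[[2]][401:800]))) / 3
  expect_equal(ps$power, manual, tolerance = 1e-9)
  expect_error(power_spectrum(rnorm(100), fs), "complete")
})

test_that("normalization sums to 100 and is scale invariant", {
  set.seed(13)
  ps <- power_spectrum(rnorm(8000), fs = 500)
  n1 <- normalize_spectrum(ps)
  expect_lt(abs(sum(n1$power[n1$freq <= 35]) - 100), 1e-9 * 100)
  ps7 <- ps
  ps7$power <- ps$power * 7
  expect_equal(normalize_spectrum(ps7)$power, n1$power, tolerance = 1e-12)
  expect_true(all(n1$power >= 0))
})

test_that("band integration follows the half-open shared-edge rule", {
  # spectrum concentrated at 12 Hz
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  n1 <- normalize_spectrum(power_spectrum(sin(2 * pi * 12 * t), fs))
  expect_equal(band_power(n1, 10, 15), 100, tolerance = 1e-9)
  expect_equal(band_power(n1, 0.5, 1.5), 0)
  expect_equal(band_power(n1, 1.5, 4), 0)
  # 1 Hz sine end-to-end: everything in the SO band
  n2 <- normalize_spectrum(power_spectrum(sin(2 * pi * 1 * t), fs))
  expect_gt(band_power(n2, 0.5, 1.5), 99.9)
  expect_lt(band_power(n2, 10, 15), 0.01)
  # uniform density: SO band close to the analytic 100 * 1/35
  nu <- n1
  nu$power <- rep(100 / sum(nu$freq <= 35), nrow(nu))
  expect_equal(band_power(nu, 0.5, 1.5), 4 * 100 / 141, tolerance = 1e-12)
  expect_lt(abs(band_power(nu, 0.5, 1.5) - 100 / 35), 0.1)
  # shared 1.5 Hz edge belongs to SO, not delta: bands partition the axis
  expect_equal(band_power(nu, 0.5, 1.5) + band_power(nu, 1.5, 4),
               band_power(nu, 0.5, 4), tolerance = 1e-12)
  expect_error(band_power(n1, 15, 10), "lo < hi")
})

test_that("band powers of any normalized spectrum sum below 100", {
  set.seed(14)
  for (i in 1:5) {
    ps <- normalize_spectrum(power_spectrum(rnorm(6000), fs = 500))
    bp <- band_powers(ps)
    expect_lte(sum(bp$power), 100 + 1e-9)
  }
})

test_that("total window power obeys the Parseval relation", {
  set.seed(15)
  fs <- 200
  x <- rnorm(4 * fs)
  ps <- power_spectrum(x, fs)
  n <- 4 * fs
  xm <- x - mean(x)
  # one-sided |X_k|^2 with DC and Nyquist counted once
  total <- 2 * sum(ps$power) - ps$power[1] - ps$power[length(ps$power)]
  expect_equal(total / n, sum(xm^2), tolerance = 1e-9)
})

test_that("spectrum averaging is invariant to segment order", {
  set.seed(16)
  segs <- list(rnorm(1600), rnorm(2400), rnorm(800))
  a <- power_spectrum(segs, fs = 200)
  b <- power_spectrum(rev(segs), fs = 200)
  expect_equal(a$power, b$power, tolerance = 1e-12)
})

test_that("delta time course bins epochs evenly and normalizes to baseline", {
  # constant input: every bin 1
  tc <- delta_timecourse(rep(5, 48), rep(5, 144))
  expect_true(all(abs(tc$value - 1) < 1e-12))
  expect_equal(sum(tc$segment == "baseline"), 12)
  expect_equal(sum(tc$segment == "post"), 36)
  # baseline 1, post 2: post bins exactly 2
  tc2 <- delta_timecourse(rep(1, 48), rep(2, 144))
  expect_true(all(tc2$value[tc2$segment == "post"] == 2))
  expect_equal(mean(tc2$value[tc2$segment == "baseline"][1:2]), 1)
  # linear ramp vs brute-force partition oracle
  base <- seq(0.5, 2, length.out = 48)
  post <- seq(2, 0.2, length.out = 144)
  tc3 <- delta_timecourse(base, post)
  oracle <- c(vapply(split(base, rep(1:12, each = 4)), mean, numeric(1)),
              vapply(split(post, rep(1:36, each = 4)), mean, numeric(1)))
  oracle <- oracle / mean(oracle[1:2])
  expect_equal(tc3$value, unname(oracle), tolerance = 1e-12)
  # remainder epochs go to the earliest bins
  tc4 <- delta_timecourse(seq_len(14), seq_len(36), n_baseline_bins = 12)
  expect_equal(tc4$n_epochs[tc4$segment == "baseline"],
               c(2L, 2L, rep(1L, 10)))
  expect_error(delta_timecourse(rep(1, 5), rep(1, 36)), "fewer")
})

test_that("per-epoch delta power tracks an injected delta-band tone", {
  fs <- 250
  hyp <- hypnogram(rep(c("WAKE", "NREMS"), c(2, 8)))
  t <- (0:(40 * fs - 1)) / fs
  x <- 50 * sin(2 * pi * 2.5 * t)
  rec <- recording(matrix(x, nrow = 1), fs = fs)
  pe <- per_epoch_band_power(rec, hyp, band = c(1.5, 4), min_bout_s = 20)
  expect_equal(nrow(pe), 8)
  # all epochs carry the same tone, so powers are equal and nonzero
  expect_gt(min(pe$power), 0)
  expect_lt(diff(range(pe$power)) / mean(pe$power), 1e-6)
  # out-of-band tone leaves nothing
  rec0 <- recording(matrix(50 * sin(2 * pi * 8 * t), nrow = 1), fs = fs)
  pe0 <- per_epoch_band_power(rec0, hyp, band = c(1.5, 4),
                              min_bout_s = 20)
  expect_lt(max(pe0$power) / max(pe$power), 1e-9)
})
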