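# Sigma envelope, threshold formula, event detection rules (cycles,
# extension, fusion, edge discard) and per-event characterization.

test_that("sigma envelope follows the filter-square-smooth contract", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  # in-band tone: squared-and-smoothed plateau near A^2/2 (10 Hz puts an
  # integer number of squared-carrier periods in the smoothing window, so
  # the residual ripple is small)
  se <- sigma_envelope(80 * sin(2 * pi * 10 * t), fs)
  mid <- se$envelope[(3 * fs):(7 * fs)]
  expect_lt(max(abs(mid - 80^2 / 2)) / (80^2 / 2), 0.05)
  # stop-band tone: essentially nothing
  se4 <- sigma_envelope(80 * sin(2 * pi * 4 * t), fs)
  expect_lt(max(se4$envelope[(3 * fs):(7 * fs)]) / (80^2 / 2), 1e-4)
  expect_error(sigma_envelope(rnorm(100), fs = 30), "too low")
})

test_that("sigma envelope equals a step-by-step oracle", {
  set.seed(21)
  fs <- 200
  x <- rnorm(6 * fs)
  x[400:500] <- x[400:500] + 40 * sin(2 * pi * 12 * (0:100) / fs)
  se <- sigma_envelope(x, fs)
  b <- design_fir(fs, 9, 16, transition = 2)
  f_or <- brute_filtfilt(x, b)
  env_or <- brute_moving_average(f_or^2, round(0.1 * fs))
  expect_lt(max(abs(se$filtered - f_or)), 1e-10)
  expect_lt(max(abs(se$envelope - env_or)), 1e-10)
})

test_that("threshold is mean + 1.5 population SD of the NREMS envelope", {
  expect_equal(compute_threshold(rep(4.2, 100)), 4.2)
  expect_equal(compute_threshold(rep(c(0, 2), 50)), 2.5)
  set.seed(22)
  v <- rexp(1000)
  m <- mean(v)
  expect_equal(compute_threshold(v),
               m + 1.5 * sqrt(sum((v - m)^2) / length(v)),
               tolerance = 1e-14)
  expect_error(compute_threshold(numeric(0)), "no NREMS")
})

test_that("detector applies cycle, fusion and edge rules", {
  fs <- 1000
  bouts <- tibble::tibble(bout_id = 1L, state = "NREMS", start_s = 0,
                          end_s = 10, duration_s = 10)
  plateau <- 50^2 / 2
  run_detect <- function(bursts, ...) {
    x <- make_burst_trace(fs, 10, bursts)
    se <- sigma_envelope(x, fs)
    detect_events(se$filtered, se$envelope, fs, threshold = 0.6 * plateau,
                  bouts = bouts, ...)
  }
  # zero signal: nothing
  se0 <- sigma_envelope(numeric(10 * fs), fs)
  expect_equal(nrow(detect_events(se0$filtered, se0$envelope, fs,
                                  1, bouts)), 0)
  # single clean burst: one event
  ev1 <- run_detect(list(c(4, 0.5)))
  expect_equal(nrow(ev1), 1)
  expect_lt(abs(ev1$onset_s - 4), 0.1)
  # 5 ms gap: smoothing bridges the dip -> one fused event
  ev_5 <- run_detect(list(c(4, 0.45), c(4.455, 0.45)))
  expect_equal(nrow(ev_5), 1)
  # 50 ms gap: envelope dips below threshold -> two events
  ev_50 <- run_detect(list(c(4, 0.45), c(4.5, 0.45)))
  expect_equal(nrow(ev_50), 2)
  # two-cycle burst above threshold: rejected by the 3-cycle rule
  ev_2c <- run_detect(list(c(4, 2 / 12)))
  expect_equal(nrow(ev_2c), 0)
  # post-fusion invariant: no two events closer than 10 ms
  if (nrow(ev_50) == 2) {
    expect_gte(ev_50$onset_s[2] - ev_50$offset_s[1], 0.010)
  }
  # an event whose extended interval reaches the bout edges is discarded:
  # supra-threshold everywhere with no zero crossing before the run start
  filt <- sin(2 * pi * 12 * (0:(10 * fs - 1)) / fs) + 0.5
  filt <- filt - mean(filt) + 2    # strictly positive: no crossings at all
  ev_edge <- detect_events(filt, rep(10, 10 * fs), fs, threshold = 5,
                           bouts = bouts, min_cycles = 0)
  expect_equal(nrow(ev_edge), 0)
})

test_that("events are confined to their bouts and never span bouts", {
  fs <- 500
  # two bouts separated by wake; burst in each
  x <- make_burst_trace(fs, 60, list(c(10, 0.5), c(40, 0.5)))
  se <- sigma_envelope(x, fs)
  bouts <- tibble::tibble(bout_id = 1:2, state = "NREMS",
                          start_s = c(0, 30), end_s = c(24, 60),
                          duration_s = c(24, 30))
  ev <- detect_events(se$filtered, se$envelope, fs, 0.6 * 50^2 / 2, bouts)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$bout_id, c(1L, 2L))
  for (i in 1:2) {
    expect_gte(ev$onset_s[i], bouts$start_s[ev$bout_id[i]])
    expect_lte(ev$offset_s[i], bouts$end_s[ev$bout_id[i]])
  }
})

test_that("detection is amplitude-scale covariant", {
  g <- nrems_scene(minutes = 3, seed = 31)
  rec <- g$recording
  sp1 <- detect_spindles(rec, g$hypnogram)
  rec2 <- rec
  rec2$samples <- rec$samples * 3
  sp2 <- detect_spindles(rec2, g$hypnogram)
  expect_equal(attr(sp2, "threshold"), 9 * attr(sp1, "threshold"),
               tolerance = 1e-9)
  expect_equal(nrow(sp2), nrow(sp1))
  expect_equal(sp2$onset_s, sp1$onset_s, tolerance = 1e-9)
  expect_equal(sp2$offset_s, sp1$offset_s, tolerance = 1e-9)
  expect_equal(sp2$amplitude_uv2, 9 * sp1$amplitude_uv2, tolerance = 1e-9)
})

test_that("spindle amplitude is the mean sigma power over the event", {
  env <- rep(7, 1000)
  expect_equal(spindle_amplitude(0.2, 0.6, env, 1000), 7)
  set.seed(23)
  env2 <- rexp(1000)
  a <- spindle_amplitude(0.1, 0.35, env2, 1000)
  expect_equal(a, mean(env2[101:350]), tolerance = 1e-12)
})

test_that("intra-spindle frequency finds real peaks and rejects flat spectra", {
  fs <- 1000
  w12 <- make_spindle_waveform(0.5, 12, 80, fs)
  expect_lt(abs(intra_spindle_frequency(w12, fs) - 12), 0.25 + 1e-9)
  w145 <- make_spindle_waveform(0.5, 14.5, 80, fs)
  expect_lt(abs(intra_spindle_frequency(w145, fs) - 14.5), 0.25 + 1e-9)
  # flat in-band magnitude: equal-amplitude tones at every in-band bin
  # frequency of a full-resolution segment -> no distinguishable peak
  t <- (0:(4 * fs - 1)) / fs
  set.seed(24)
  flat <- rowSums(vapply(seq(9, 16, by = 0.25), function(f) {
    sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }, numeric(length(t))))
  expect_true(is.na(intra_spindle_frequency(flat, fs)))
})

test_that("detector recovers injected spindles in a short scene", {
  g <- nrems_scene(minutes = 5, seed = 32)
  sp <- detect_spindles(g$recording, g$hypnogram)
  gt <- g$ground_truth$spindles
  m <- match_intervals(sp$onset_s, sp$offset_s, gt$onset_s, gt$offset_s)
  expect_gte(m$recall, 0.85)
  expect_gte(m$precision, 0.85)
  # detected intra-frequencies sit near the injected carriers
  expect_lt(abs(mean(sp$intra_freq_hz, na.rm = TRUE) - 11), 0.75)
  # every event lasts at least 3 cycles of the slowest in-band frequency
  expect_true(all(sp$duration_s >= 3 / 16))
})
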