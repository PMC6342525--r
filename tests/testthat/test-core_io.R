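# Recording/hypnogram containers, file round trips, bout extraction and
# state-restricted slicing.

test_that("recording construction and tsv/binary round trips preserve data", {
  set.seed(1)
  rec <- recording(matrix(rnorm(2 * 500), nrow = 2), fs = 250,
                   channel_labels = c("S1", "PFC"))
  expect_equal(recording_duration(rec), 2)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, tmp, format = "tsv")
  back <- read_recording(tmp, format = "tsv")
  expect_equal(back$fs, 250)
  expect_equal(back$channel_labels, c("S1", "PFC"))
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)

  bin <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, bin, format = "binary_matrix")
  back2 <- read_recording(bin, format = "binary_matrix")
  expect_identical(back2$samples, rec$samples)

  # sidecar-less tsv must error, not silently default the sampling rate
  orphan <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(S1 = rnorm(10)), orphan)
  expect_error(read_recording(orphan, format = "tsv"), "sidecar")
})

test_that("EDF round trip echoes header and recovers the signal", {
  set.seed(2)
  x <- 100 * sin(2 * pi * 3 * (0:1023) / 256) + rnorm(1024, sd = 5)
  rec <- recording(matrix(x, nrow = 1), fs = 256, channel_labels = "EEG")
  tmp <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, tmp, format = "edf")
  back <- read_recording(tmp, format = "edf")
  expect_equal(back$fs, 256)
  expect_equal(back$channel_labels, "EEG")
  # 16-bit quantization: worst-case error is one digital step
  step <- 2 * max(abs(x), 1) / 65535
  expect_lt(max(abs(back$samples[1, ] - x)), 2 * step)
})

test_that("hypnogram reader enforces contiguity and maps unknown states", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(epoch_index = 0:9,
                                  state = rep("NREMS", 10)), tmp)
  hyp <- read_hypnogram(tmp)
  expect_s3_class(hyp, "hypnogram")
  expect_equal(nrow(hyp), 10)
  expect_equal(epoch_length(hyp) * nrow(hyp), 40)

  readr::write_tsv(tibble::tibble(epoch_index = 0:2,
                                  state = c("NREMS", "N2", "WAKE")), tmp)
  expect_warning(hyp2 <- read_hypnogram(tmp), "ARTIFACT")
  expect_equal(hyp2$state[2], "ARTIFACT")

  readr::write_tsv(tibble::tibble(epoch_index = c(0L, 2L),
                                  state = c("WAKE", "WAKE")), tmp)
  expect_error(read_hypnogram(tmp), "contiguous")
  readr::write_tsv(tibble::tibble(epoch_index = c(0L, 0L, 1L),
                                  state = rep("WAKE", 3)), tmp)
  expect_error(read_hypnogram(tmp), "duplicated")
})

test_that("bout extraction is strict about the consolidation threshold", {
  # five NREMS epochs = 20 s: excluded under the strict > 20 s rule
  h5 <- hypnogram(c("WAKE", rep("NREMS", 5), "WAKE"))
  expect_equal(nrow(extract_bouts(h5, "NREMS", 20)), 0)
  # six epochs = 24 s: included
  h6 <- hypnogram(c("WAKE", rep("NREMS", 6), "WAKE"))
  b <- extract_bouts(h6, "NREMS", 20)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 24)
  expect_equal(b$end_s - b$start_s, b$duration_s)
  # all-wake hypnogram has no NREMS bouts
  expect_equal(nrow(extract_bouts(hypnogram(rep("WAKE", 20)), "NREMS", 20)),
               0)
  # artifact epochs break runs: two 5-epoch runs separated by one artifact
  ha <- hypnogram(c(rep("NREMS", 6), "ARTIFACT", rep("NREMS", 6)))
  ba <- extract_bouts(ha, "NREMS", 20)
  expect_equal(nrow(ba), 2)
  expect_true(all(ba$duration_s == 24))
})

test_that("bout extraction returns maximal non-adjacent runs", {
  set.seed(3)
  for (i in 1:20) {
    st <- sample(c("WAKE", "NREMS", "REMS"), 100, replace = TRUE)
    b <- extract_bouts(hypnogram(st), "NREMS", 0)
    if (nrow(b) > 1) {
      # maximality: consecutive same-state bouts never touch
      expect_true(all(b$start_s[-1] > b$end_s[-nrow(b)]))
    }
    # every bout is wall-to-wall NREMS and flanked by non-NREMS
    for (k in seq_len(nrow(b))) {
      ep <- (b$start_s[k] / 4 + 1):(b$end_s[k] / 4)
      expect_true(all(st[ep] == "NREMS"))
      if (b$start_s[k] > 0) expect_false(st[ep[1] - 1] == "NREMS")
      if (b$end_s[k] < 400) expect_false(st[ep[length(ep)] + 1] == "NREMS")
    }
  }
})

test_that("segment slicing conserves samples and rejects out-of-range bouts", {
  rec <- recording(matrix(seq_len(24000), nrow = 1), fs = 1000)
  hyp <- hypnogram(c(rep("NREMS", 6)))
  b <- extract_bouts(hyp, "NREMS", 20)
  segs <- concatenate_state_segments(rec, b)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_samples, 24000)

  hyp2 <- hypnogram(c(rep("NREMS", 6), "WAKE", rep("NREMS", 7)))
  rec2 <- recording(matrix(rnorm(56 * 100), nrow = 1), fs = 100)
  b2 <- extract_bouts(hyp2, "NREMS", 20)
  segs2 <- concatenate_state_segments(rec2, b2)
  expect_equal(nrow(segs2), 2)
  expect_equal(sum(segs2$n_samples), sum(b2$duration_s) * 100)

  bad <- tibble::tibble(bout_id = 1L, state = "NREMS", start_s = 50,
                        end_s = 60, duration_s = 10)
  expect_error(concatenate_state_segments(rec2, bad), "outside")
})

test_that("event tables round-trip losslessly, including empty tables", {
  ev <- tibble::tibble(
    channel = "S1", bout_id = c(1L, 1L, 2L),
    onset_s = c(1.23456, 10.5, 30.000123),
    offset_s = c(1.93456, 11.1, 30.700123),
    duration_s = c(0.7, 0.6, 0.7),
    amplitude_uv2 = c(800.1, 950.2, 700.3),
    intra_freq_hz = c(11.25, NA, 12.5))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, tmp)
  back <- read_events(tmp)
  expect_equal(nrow(back), 3)
  expect_equal(back$onset_s, ev$onset_s, tolerance = 1e-9)
  expect_equal(back$intra_freq_hz, ev$intra_freq_hz)

  write_events(ev[0, ], tmp)
  back0 <- read_events(tmp)
  expect_equal(nrow(back0), 0)
  expect_equal(names(back0), names(ev))
})
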