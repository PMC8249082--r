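test_that("text recordings round-trip bit-exactly with sidecar metadata", {
  set.seed(1)
  m <- matrix(rnorm(60), ncol = 6,
              dimnames = list(NULL, names(organ_map6())))
  rec <- multichannel_recording(m, fs = 500, organ_map = organ_map6())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(rec_matrix(back), rec_matrix(rec))
  expect_identical(back$organ_map, rec$organ_map)
  expect_equal(back$fs, rep(500, 6))
})

test_that("single-channel text file reads back with expected shape", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ECG", rep("0", 10)), path)
  rec <- read_recording(path, organ_map = c(ECG = "HEART"), fs = 2000)
  expect_equal(dim(rec_matrix(rec)), c(10L, 1L))
  expect_equal(unname(rec$organ_map), "HEART")
})

test_that("validation rejects non-finite samples naming channel and index", {
  m <- matrix(0, 10, 2, dimnames = list(NULL, c("EEG1", "ECG")))
  m[6, 2] <- NaN   # 0-based sample index 5
  expect_error(
    multichannel_recording(m, fs = 500,
                           organ_map = c(EEG1 = "BRAIN", ECG = "HEART")),
    "ECG.*index 5")
  expect_error(
    multichannel_recording(m[, 1, drop = FALSE], fs = 500,
                           organ_map = c(EEG1 = "BRAIN", ECG = "HEART")),
    "absent")
})

test_that("EDF files from an independent writer read back correctly", {
  fs <- c(rep(500, 4), 2000, 500)
  labs <- names(organ_map6())
  set.seed(7)
  t5 <- seq(0, 5 - 1 / 500, by = 1 / 500)
  signals <- c(lapply(1:4, function(k) 100 * sin(2 * pi * k * t5)),
               list(300 * sin(2 * pi * 8 * seq(0, 5 - 1 / 2000,
                                               by = 1 / 2000))),
               list(50 * cos(2 * pi * 3 * t5)))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(path, signals, fs, labs)
  rec <- read_recording(path, organ_map = organ_map6())
  expect_equal(rec$channel_labels, labs)
  expect_equal(rec$fs, fs)
  expect_equal(as.vector(table(rec$organ_map)[c("BRAIN", "HEART", "LUNGS")]),
               c(4L, 1L, 1L))
  # 16-bit quantization of a +/-1000 physical range
  for (k in seq_along(signals))
    expect_lt(max(abs(rec$signals[[k]] - signals[[k]])), 0.05)
})

test_that("causal Butterworth low-pass matches its analytic digital gain", {
  fs <- 2000; f <- 300; cutoff <- 200; ord <- 4
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * f * t)
  rec <- multichannel_recording(list(ECG = x), fs = fs,
                                channel_labels = "ECG",
                                organ_map = c(ECG = "HEART"))
  out <- lowpass_downsample(rec, cutoff, ord, target_fs = 500)
  expect_equal(out$fs, 500)
  expect_equal(length(out$signals[[1]]), length(x) / 4)
  # steady-state amplitude on the tail by sinusoid regression
  y <- out$signals[[1]]
  tt <- seq_along(y) / 500
  keep <- tt > 2
  fitm <- lm(y[keep] ~ sin(2 * pi * f * tt[keep]) +
               cos(2 * pi * f * tt[keep]))
  amp <- sqrt(sum(coef(fitm)[2:3]^2))
  # bilinear-transform Butterworth magnitude (exact for this design)
  gain <- 1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * ord))
  expect_equal(amp, gain, tolerance = 0.02)
})

test_that("decimation passes DC exactly and leaves at-rate channels alone", {
  n <- 4000
  rec <- multichannel_recording(
    list(ECG = rep(3.25, 2 * n), EEG1 = rnorm(n)),
    fs = c(2000, 500), channel_labels = c("ECG", "EEG1"),
    organ_map = c(ECG = "HEART", EEG1 = "BRAIN"))
  out <- lowpass_downsample(rec)
  # constant channel: unit DC gain, mean preserved (transient excluded)
  expect_lt(abs(mean(tail(out$signals[["ECG"]], 500)) - 3.25), 1e-9)
  expect_identical(out$signals[["EEG1"]], rec$signals[["EEG1"]])
  # non-integer ratio is refused
  bad <- multichannel_recording(list(ECG = rnorm(1200)), fs = 1200,
                                channel_labels = "ECG",
                                organ_map = c(ECG = "HEART"))
  expect_error(lowpass_downsample(bad), "integer divisor")
  expect_error(lowpass_downsample(rec, cutoff_hz = 260), "Nyquist")
})

test_that("windowing is gapless, exact-length, and drops the partial tail", {
  rec <- white_noise_recording(D = 2, duration_s = 25, seed = 3)
  expect_message(wins <- segment_windows(rec, window_spec(10, 0)),
                 "dropping trailing partial")
  expect_length(wins, 2L)
  expect_equal(vapply(wins, function(w) nrow(w$data), integer(1)),
               c(5000L, 5000L))
  expect_equal(vapply(wins, `[[`, numeric(1), "start_s"), c(0, 10))
  expect_equal(vapply(wins, `[[`, integer(1), "window_index"), 0:1)
  # gapless prefix: concatenated windows reproduce the first 20 s
  m <- rec_matrix(rec)
  expect_identical(rbind(wins[[1]]$data, wins[[2]]$data), m[1:10000, ])
  # a 10-s 6-channel window at 500 Hz carries 30,000 values
  rec6 <- white_noise_recording(D = 6, duration_s = 10, seed = 4)
  w6 <- segment_windows(rec6, window_spec(10, 0))
  expect_length(w6, 1L)
  expect_equal(length(w6[[1]]$data), 30000L)
  expect_error(segment_windows(rec6, window_spec(11, 0)), "shorter")
})
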