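toy_series <- function(values, dt = 10) {
  out <- data.frame(time_s = (seq_along(values) - 1) * dt, value = values)
  attr(out, "band") <- c(80, 90)
  attr(out, "pair") <- c(from = "HEART", to = "BRAIN")
  attr(out, "events") <- NULL
  attr(out, "smoothing_k") <- NA_integer_
  class(out) <- c("connectivity_ts", "data.frame")
  out
}

test_that("band time series average significant in-band values per window", {
  v1 <- array(0, c(2, 2, 3)); m1 <- array(FALSE, c(2, 2, 3))
  v1[2, 1, 1:2] <- c(0.2, 0.4); m1[2, 1, 1:2] <- TRUE
  v2 <- array(0.9, c(2, 2, 3)); m2 <- array(FALSE, c(2, 2, 3))
  windows <- list(
    list(window_index = 0L, start_s = 0, fit_ok = TRUE, values = v1,
         p_values = 1 - m1 * 0.99, mask = m1, spectral_radius = .5,
         sigma2 = c(1, 1)),
    list(window_index = 1L, start_s = 10, fit_ok = TRUE, values = v2,
         p_values = 1 - m2 * 0.99, mask = m2, spectral_radius = .5,
         sigma2 = c(1, 1)))
  cs <- structure(list(windows = windows,
                       grid = structure(list(freqs = c(5, 8, 15), fs = 500,
                                             f_max = 20),
                                        class = "frequency_grid"),
                       fs = 500, channel_labels = c("EEG1", "ECG"),
                       organ_map = c(EEG1 = "BRAIN", ECG = "HEART"),
                       alpha = 0.05, method = "SURROGATE",
                       n_surrogates = 99, order = 7,
                       window_spec = window_spec(), n_excluded = 0L),
                  class = "connectivity_set")
  ts <- extract_band_timeseries(cs, "BRAIN", "HEART", c(0, 10))
  expect_equal(ts$value, c(0.3, 0))        # mean of {0.2, 0.4}; empty -> 0
  expect_equal(ts$time_s, c(0, 10))
  gap <- extract_band_timeseries(cs, "BRAIN", "HEART", c(0, 10),
                                 zero_empty = FALSE)
  expect_true(is.na(gap$value[2]))
  # event annotations are metadata only
  ev <- data.frame(time_s = 5, label = "seizure")
  tse <- extract_band_timeseries(cs, "BRAIN", "HEART", c(0, 10),
                                 events = ev)
  expect_equal(tse$value, ts$value)
  expect_equal(attr(tse, "events"), ev)
})

test_that("centered smoothing honours the 9-point window and edge shrink", {
  x <- c(0, 0, 0, 0, 9, 0, 0, 0, 0)
  sm <- smooth_series(toy_series(x), k = 4)
  expect_equal(sm$value[5], 1)             # 9/9 at the full-width center
  expect_equal(sm$value[1], 0)             # edge window shrinks to 1 point
  expect_equal(sm$raw, x)
  # constant series is preserved exactly at every position
  const <- smooth_series(toy_series(rep(0.37, 25)), k = 4)
  expect_equal(const$value, rep(0.37, 25))
  expect_equal(mean(const$value), 0.37)
  # k = 0 is the identity
  set.seed(3)
  y <- runif(12)
  expect_equal(smooth_series(toy_series(y), k = 0)$value, y)
  # a 9-point smooth of 10-s windows spans 90 s of raw data
  k <- 4
  expect_equal((2 * k + 1) * 10, 90)
})

test_that("reference bands summarize group pools and skip empty groups", {
  rb <- reference_bands(list(WT = c(0.2, 0.4), KO = c(0.2, 0.4)),
                        band = c(80, 90))
  expect_equal(rb$mean, c(0.3, 0.3))
  expect_equal(rb$sem, rep(stats::sd(c(0.2, 0.4)) / sqrt(2), 2))
  expect_equal(rb$sem[1], 0.1, tolerance = 1e-9)
  expect_equal(rb$low, c(80, 80))
  expect_warning(
    rb2 <- reference_bands(list(WT = c(0.2, 0.4), KO = numeric(0))),
    "empty pool")
  expect_equal(rb2$group, "WT")
  expect_error(suppressWarnings(reference_bands(list(A = numeric(0)))),
               "no non-empty")
})

test_that("seizure-epoch elevation shows up in the smoothed series", {
  tb <- make_testbed("KO_SEIZING", duration_s = 1200, seed = 20)
  expect_equal(tb$events$label,
               rep(c("seizure_cluster_onset", "seizure_cluster_offset"), 2))
  cs <- window_connectivity(tb$recording, n_surrogates = 39, seed = 21)
  ts <- smooth_series(
    extract_band_timeseries(cs, "BRAIN", "LUNGS", c(0, 10)), k = 4)
  seizing <- (ts$time_s >= 300 & ts$time_s < 600) |
             (ts$time_s >= 900 & ts$time_s < 1200)
  expect_gt(mean(ts$value[seizing]), mean(ts$value[!seizing]))
})
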