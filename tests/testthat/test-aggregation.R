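# hand-built connectivity_set: 2 channels (BRAIN, HEART), 3 frequencies
toy_cs <- function(windows, freqs = c(5, 15, 25), alpha = 0.05) {
  structure(list(
    windows = windows,
    grid = structure(list(freqs = freqs, fs = 500, f_max = max(freqs)),
                     class = "frequency_grid"),
    fs = 500, channel_labels = c("EEG1", "ECG"),
    organ_map = c(EEG1 = "BRAIN", ECG = "HEART"),
    alpha = alpha, method = "SURROGATE", n_surrogates = 99,
    order = 7, window_spec = window_spec(), n_excluded = 0L),
    class = "connectivity_set")
}
toy_window <- function(idx, vals, mask) {
  list(window_index = idx, start_s = idx * 10, fit_ok = TRUE,
       values = vals, p_values = 1 - mask * 0.99, mask = mask,
       spectral_radius = 0.5, sigma2 = c(1, 1))
}

test_that("band grids partition the spectrum and exclude mains harmonics", {
  b <- define_bands(10, 200, 60)
  expect_equal(nrow(b), 20L)
  expect_equal(b$low, seq(0, 190, 10))
  expect_equal(b$high, seq(10, 200, 10))
  excl <- b[b$excluded, c("low", "high")]
  expect_equal(excl$low, c(50, 110, 170))
  expect_equal(sum(!b$excluded), 17L)
  expect_false(any(define_bands(10, 200, 0)$excluded))
  expect_error(define_bands(7, 200), "divide")
})

test_that("organ-pair pooling collects exactly the significant multiset", {
  v1 <- array(0, c(2, 2, 3)); v2 <- v1
  m1 <- array(FALSE, c(2, 2, 3)); m2 <- m1
  # BRAIN -> HEART means from EEG1 (col 1) to ECG (row 2)
  v1[2, 1, ] <- c(0.1, 0.2, 0.3); m1[2, 1, ] <- TRUE
  v2[2, 1, ] <- c(0.4, 0.5, 0.6); m2[2, 1, ] <- TRUE
  cs <- toy_cs(list(toy_window(0L, v1, m1), toy_window(1L, v2, m2)))
  pooled <- pool_organ_pair(cs, "BRAIN", "HEART", band = c(0, 30))
  expect_equal(sort(as.numeric(pooled)), seq(0.1, 0.6, by = 0.1))
  expect_equal(length(pooled), 6L)
  expect_equal(mean(pooled), 0.35)
  expect_equal(attr(pooled, "n_total"), 6L)
  # reverse direction has an all-false mask: empty pool
  expect_length(as.numeric(pool_organ_pair(cs, "HEART", "BRAIN")), 0L)
  expect_error(pool_organ_pair(cs, "BRAIN", "SPLEEN"), "unknown organ")
  expect_error(pool_organ_pair(cs, "BRAIN", "BRAIN"), "different organs")
})

test_that("band profiles apply the zero rule and the SEM conventions", {
  v <- array(0, c(2, 2, 3)); m <- array(FALSE, c(2, 2, 3))
  v[2, 1, 1] <- 0.2; v[2, 1, 2] <- 0.4; m[2, 1, 1:2] <- TRUE
  cs <- toy_cs(list(toy_window(0L, v, m)), freqs = c(5, 8, 15))
  bands <- define_bands(10, 20, 0)
  prof <- band_profile(cs, "BRAIN", "HEART", bands)
  # band (0,10] holds 0.2 and 0.4 -> mean 0.3, sem = sd/sqrt(2)
  expect_equal(prof$mean[1], 0.3)
  expect_equal(prof$sem[1], stats::sd(c(0.2, 0.4)) / sqrt(2))
  expect_equal(prof$sem[1], 0.1, tolerance = 1e-9)
  expect_false(prof$zero_assigned[1])
  # band (10,20] has no significant values -> zero-assigned
  expect_equal(prof$mean[2], 0)
  expect_equal(prof$sem[2], 0)
  expect_true(prof$zero_assigned[2])
  # single value: sem reported as 0 with n = 1
  v2 <- v; m2 <- m; m2[2, 1, 2] <- FALSE
  cs2 <- toy_cs(list(toy_window(0L, v2, m2)), freqs = c(5, 8, 15))
  p2 <- band_profile(cs2, "BRAIN", "HEART", bands)
  expect_equal(p2$n[1], 1L)
  expect_equal(p2$sem[1], 0)
})

test_that("pooled counts are conserved across the band partition", {
  set.seed(41)
  tb <- make_testbed("WT_LIKE", duration_s = 40, seed = 6)
  cs <- window_connectivity(tb$recording, n_surrogates = 39, seed = 3)
  bands <- define_bands(10, 200, 60)
  for (pr in list(c("BRAIN", "HEART"), c("HEART", "BRAIN"))) {
    per_band <- sum(vapply(seq_len(nrow(bands)), function(b)
      length(pool_organ_pair(cs, pr[1], pr[2],
                             band = c(bands$low[b], bands$high[b]))),
      numeric(1)))
    total <- length(pool_organ_pair(cs, pr[1], pr[2]))
    expect_equal(per_band, total)
  }
})

test_that("full-spectrum averages equal a single-band pool over retained bands", {
  tb <- make_testbed("KO_LIKE", duration_s = 30, seed = 9)
  cs <- window_connectivity(tb$recording, n_surrogates = 39, seed = 4)
  bands <- define_bands(10, 200, 60)
  fb <- fullband_average(cs, "BRAIN", "LUNGS", bands)
  manual <- unlist(lapply(which(!bands$excluded), function(b)
    as.numeric(pool_organ_pair(cs, "BRAIN", "LUNGS",
                               band = c(bands$low[b], bands$high[b])))))
  expect_equal(fb$n, length(manual))
  expect_equal(fb$mean, mean(manual))
  # profiles are window-order invariant (multiset pooling)
  cs_rev <- cs; cs_rev$windows <- rev(cs$windows)
  fb2 <- fullband_average(cs_rev, "BRAIN", "LUNGS", bands)
  expect_equal(fb2$mean, fb$mean)
  expect_equal(sort(fb2$values), sort(fb$values))
})

test_that("significance fractions count mask rates per pair and band", {
  v <- array(0.5, c(2, 2, 3))
  m_all <- array(TRUE, c(2, 2, 3)); m_none <- array(FALSE, c(2, 2, 3))
  cs_all <- toy_cs(list(toy_window(0L, v, m_all)), freqs = c(5, 8, 15))
  cs_none <- toy_cs(list(toy_window(0L, v, m_none)), freqs = c(5, 8, 15))
  bands <- define_bands(10, 20, 0)
  sf_all <- significance_fraction(cs_all, bands)
  sf_none <- significance_fraction(cs_none, bands)
  bh <- sf_all$from == "BRAIN" & sf_all$to == "HEART"
  expect_true(all(sf_all$fraction[bh] == 1))
  expect_true(all(sf_none$fraction == 0, na.rm = TRUE))
  expect_true(all(sf_none$pct_not_significant == 100, na.rm = TRUE))
  # 1 of 2 in-band values significant -> 0.5
  m_half <- m_none; m_half[2, 1, 1] <- TRUE
  cs_half <- toy_cs(list(toy_window(0L, v, m_half)), freqs = c(5, 8, 15))
  sf_half <- significance_fraction(cs_half, bands)
  row1 <- sf_half$from == "BRAIN" & sf_half$to == "HEART" & sf_half$low == 0
  expect_equal(sf_half$fraction[row1], 0.5)
})
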