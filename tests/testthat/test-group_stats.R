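test_that("rank-sum test matches hand cases and the star conventions", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  # stars follow the strict caption thresholds
  expect_equal(gpdcnet:::star_label(0.0009), "**")
  expect_equal(gpdcnet:::star_label(0.049), "*")
  expect_equal(gpdcnet:::star_label(0.05), "")
  expect_equal(gpdcnet:::star_label(0.001), "*")
  # empty samples are flagged not-testable, not errors
  nt <- mann_whitney(numeric(0), c(1, 2))
  expect_false(nt$testable)
  expect_true(is.na(nt$p_value))
})

test_that("exact p-values match full enumeration for small samples", {
  set.seed(7)
  for (rep in 1:20) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    x <- sample(100, na + nb)   # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(mann_whitney(a, b)$p_value, oracle_mw_enum(a, b),
                 tolerance = 1e-12,
                 label = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("the test is invariant under common monotone transforms", {
  set.seed(8)
  a <- rnorm(30); b <- rnorm(25, mean = 0.8)
  p0 <- mann_whitney(a, b)$p_value
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) atan(x) * 5)) {
    expect_equal(mann_whitney(f(a), f(b))$p_value, p0, tolerance = 1e-12)
  }
})

test_that("per-band comparisons localize an injected band difference", {
  # two toy groups identical except in one band of one interaction
  mk <- function(shift) {
    windows <- lapply(0:9, function(k) {
      v <- array(0, c(2, 2, 4)); m <- array(FALSE, c(2, 2, 4))
      set.seed(100 + k)
      v[2, 1, ] <- runif(4, 0.2, 0.4); m[2, 1, ] <- TRUE
      v[2, 1, 4] <- v[2, 1, 4] + shift   # 4th frequency = (30,40] band
      list(window_index = k, start_s = k * 10, fit_ok = TRUE, values = v,
           p_values = 1 - m * 0.99, mask = m, spectral_radius = 0.5,
           sigma2 = c(1, 1))
    })
    structure(list(windows = windows,
                   grid = structure(list(freqs = c(5, 15, 25, 35),
                                         fs = 500, f_max = 40),
                                    class = "frequency_grid"),
                   fs = 500, channel_labels = c("EEG1", "ECG"),
                   organ_map = c(EEG1 = "BRAIN", ECG = "HEART"),
                   alpha = 0.05, method = "SURROGATE", n_surrogates = 99,
                   order = 7, window_spec = window_spec(),
                   n_excluded = 0L),
              class = "connectivity_set")
  }
  bands <- define_bands(10, 40, 0)
  cmp <- compare_groups_per_band(mk(0), mk(0.5), "BRAIN", "HEART", bands,
                                 "A", "B")
  expect_equal(nrow(cmp), 4L)
  sel <- select_discriminative_band(cmp)
  expect_equal(c(sel$low, sel$high), c(30, 40))
  expect_lt(sel$p_value, 0.001)
  # identical groups: no band significant
  cmp0 <- compare_groups_per_band(mk(0), mk(0), "BRAIN", "HEART", bands)
  expect_true(all(cmp0$p_value > 0.99))
})

test_that("discriminative-band selection breaks ties toward low frequency", {
  df <- data.frame(low = c(0, 10, 20), high = c(10, 20, 30),
                   p_value = c(0.2, 0.01, 0.01), testable = TRUE)
  sel <- select_discriminative_band(df)
  expect_equal(sel$low, 10)
  df$testable <- FALSE
  expect_error(select_discriminative_band(df), "no testable band")
})

test_that("within-group interaction comparison covers all 15 pairs", {
  tb <- make_testbed("WT_LIKE", duration_s = 30, seed = 10)
  cs <- window_connectivity(tb$recording, n_surrogates = 39, seed = 5)
  m <- compare_interaction_pairs(cs)
  expect_equal(dim(m), c(6L, 6L))
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))
  expect_equal(sum(!is.na(m[upper.tri(m)])),
               sum(!is.na(m)) / 2)
})
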