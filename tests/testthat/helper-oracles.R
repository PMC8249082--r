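# Independent oracles and fixture builders.  Everything here is
# deliberately written without reference to the package's own compiled
# fitting/GPDC path so the two routes can disagree.

# VAR OLS by explicitly formed normal equations (plain R)
oracle_fit_var <- function(X, p, demean = TRUE) {
  n <- nrow(X); D <- ncol(X)
  if (demean) X <- sweep(X, 2, colMeans(X))
  Y <- X[(p + 1):n, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(r)
    X[(p + 1 - r):(n - r), , drop = FALSE]))
  B <- solve(crossprod(Z), crossprod(Z, Y))
  E <- Y - Z %*% B
  A <- array(0, c(D, D, p))
  for (r in seq_len(p)) A[, , r] <- t(B[((r - 1) * D + 1):(r * D), ,
                                        drop = FALSE])
  list(A = A, Sigma = crossprod(E) / (n - p - p * D), resid = E, Z = Z)
}

# squared GPDC straight from the definition (plain R, loops)
oracle_gpdc <- function(A, sigma2, freqs, fs) {
  D <- dim(A)[1]; p <- dim(A)[3]
  out <- array(NA_real_, c(D, D, length(freqs)))
  for (fi in seq_along(freqs)) {
    Abar <- diag(D) + 0i
    for (r in seq_len(p))
      Abar <- Abar - A[, , r] * exp(-2i * pi * freqs[fi] * r / fs)
    for (j in seq_len(D)) {
      den <- sum(Mod(Abar[, j])^2 / sigma2)
      for (i in seq_len(D))
        out[i, j, fi] <- (Mod(Abar[i, j])^2 / sigma2[i]) / den
    }
  }
  out
}

# exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(na+nb, na) rank assignments (no-ties case)
oracle_mw_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  allr <- seq_len(na + nb)
  us <- apply(combos, 2, function(idx) sum(allr[idx]) - na * (na + 1) / 2)
  # two-sided: double the smaller tail of the exact distribution
  mu <- na * nb / 2
  p <- if (u_obs <= mu) mean(us <= u_obs) else mean(us >= u_obs)
  min(1, 2 * p)
}

# random stable MVAR model (rejection-sampled coefficient scaling)
random_stable_model <- function(D, p, fs = 500) {
  repeat {
    A <- array(stats::rnorm(D * D * p, sd = 0.3 / p), c(D, D, p))
    st <- check_stability(A)
    if (st$stable) break
  }
  sigma2 <- stats::runif(D, 0.2, 5)
  structure(list(coeffs = A, noise_cov = diag(sigma2, nrow = D),
                 sigma2 = sigma2, order = p, dim = D, fs = fs,
                 window_index = NA_integer_, n_samples = NA_integer_),
            class = "mvar_model")
}

white_noise_recording <- function(D = 6, duration_s = 60, fs = 500,
                                  seed = 1) {
  nd <- data.frame(f0_hz = rep(0, D), radius = rep(0, D))
  labs <- if (D == 6) c("EEG1", "EEG2", "EEG3", "EEG4", "ECG", "PLETH")
          else paste0("CH", seq_len(D))
  om <- if (D == 6) stats::setNames(c(rep("BRAIN", 4), "HEART", "LUNGS"), labs)
        else stats::setNames(rep("BRAIN", D), labs)
  sp <- coupling_spec(nd, fs = fs, channel_labels = labs, organ_map = om,
                      duration_s = duration_s, seed = seed)
  simulate_recording(sp)
}

# independent minimal EDF writer (16-bit), one data record per second
write_edf_fixture <- function(path, signals, fs, labels,
                              phys_min = -1000, phys_max = 1000) {
  ns <- length(signals)
  fs <- rep_len(fs, ns)
  record_dur <- 1
  n_records <- min(floor(sapply(signals, length) / fs))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = w, flag = "-")
    substr(s, 1, w)
  }
  dig_min <- -32768; dig_max <- 32767
  hdr <- paste0(pad("0", 8), pad("test patient", 80), pad("test rec", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 + ns * 256, 8), pad("", 44), pad(n_records, 8),
                pad(record_dur, 8), pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(labels, pad, "", w = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(rep(phys_min, ns), pad, "", w = 8), collapse = ""),
    paste(vapply(rep(phys_max, ns), pad, "", w = 8), collapse = ""),
    paste(vapply(rep(dig_min, ns), pad, "", w = 8), collapse = ""),
    paste(vapply(rep(dig_max, ns), pad, "", w = 8), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(vapply(fs * record_dur, pad, "", w = 8), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, sig_hdr)), con)
  to_dig <- function(x, s) {
    d <- round((x - phys_min) / (phys_max - phys_min) *
               (dig_max - dig_min) + dig_min)
    as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  for (rec in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      idx <- ((rec - 1) * fs[s] + 1):(rec * fs[s])
      writeBin(to_dig(signals[[s]][idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

organ_map6 <- function()
  stats::setNames(c(rep("BRAIN", 4), "HEART", "LUNGS"),
                  c("EEG1", "EEG2", "EEG3", "EEG4", "ECG", "PLETH"))
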