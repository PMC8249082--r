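#' Fit a multivariate autoregressive (MVAR) model to one window
#'
#' Estimates the order-`p` MVAR model
#' \deqn{x(t) = \sum_{r=1}^{p} A_r x(t-r) + e(t)}
#' by multivariate least squares on the lagged design matrix.  Entry
#' `(i, j)` of `A_r` is the influence of channel `j` at lag `r` on
#' channel `i` (project-wide convention: flow FROM column TO row).  The
#' residual covariance uses the small-sample denominator
#' `n_eff - p * D`.  The fit is deterministic for a fixed input.
#'
#' With the standard settings (D = 6 channels, p = 7, 10-s windows at
#' 500 Hz) each window supplies 30,000 data points for the 252
#' coefficients, i.e. more than a 100-fold data-to-parameter ratio; a
#' warning is raised when a window falls below that ratio.
#'
#' @param block Samples x channels numeric matrix (one analysis window).
#' @param order Model order `p` (number of lags), default 7.
#' @param demean Remove each channel's mean before fitting (default
#'   `TRUE`).
#' @param fs Sampling rate in Hz carried into the model metadata.
#' @param window_index Optional window index carried into metadata.
#' @return An object of class `mvar_model`: `coeffs` (D x D x p array),
#'   `noise_cov` (D x D), `sigma2` (its diagonal), `order`, `dim`, `fs`,
#'   `window_index`, `n_samples`, `gram` (lagged-regressor Gram matrix
#'   Z'Z/n_eff, used by the asymptotic significance backend) and
#'   `resid` (residual matrix).
#'   On a singular design (e.g. a constant channel) an object of class
#'   `mvar_fit_failure` is returned instead.
#' @export
fit_mvar <- function(block, order = 7, demean = TRUE, fs = NA_real_,
                     window_index = NA_integer_) {
  block <- as.matrix(block)
  storage.mode(block) <- "double"
  p <- as.integer(order)
  if (p < 1L) stop("order must be >= 1")
  n <- nrow(block); D <- ncol(block)
  if (n * D < 100 * (p * D * D))
    warning(sprintf(
      "only %d data points for %d parameters (< 100x ratio); estimates may be unstable",
      n * D, p * D * D))
  fit <- cpp_fit_mvar(block, p, demean)
  if (!isTRUE(fit$ok))
    return(structure(list(window_index = window_index,
                          reason = "singular regressor Gram matrix"),
                     class = "mvar_fit_failure"))
  structure(list(coeffs = fit$coeffs, noise_cov = fit$noise_cov,
                 sigma2 = diag(fit$noise_cov), order = p, dim = D,
                 fs = fs, window_index = window_index, n_samples = n,
                 gram = fit$gram, resid = fit$resid),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  st <- check_stability(x)
  cat(sprintf("<mvar_model> D = %d, p = %d (%d coefficients), n = %d\n",
              x$dim, x$order, length(x$coeffs), x$n_samples))
  cat(sprintf("  spectral radius %.4f (%s)\n", st$spectral_radius,
              if (st$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Companion-matrix stability check
#'
#' Builds the `pD x pD` companion matrix of the model and returns its
#' spectral radius; the model is stable iff all eigenvalues have modulus
#' strictly below 1.
#'
#' @param model An `mvar_model`, or a D x D x p coefficient array.
#' @return `list(stable = logical, spectral_radius = numeric)`.
#' @export
check_stability <- function(model) {
  A <- if (inherits(model, "mvar_model")) model$coeffs else model
  D <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, p * D, p * D)
  for (r in seq_len(p)) comp[1:D, ((r - 1) * D + 1):(r * D)] <- A[, , r]
  if (p > 1) {
    idx <- seq_len((p - 1) * D)
    comp[cbind(D + idx, idx)] <- 1
  }
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  list(stable = rho < 1, spectral_radius = rho)
}

#' Sensitivity of band profiles to the MVAR model order
#'
#' Reruns the full window-level connectivity analysis (fit + GPDC +
#' significance) at each candidate order and rebuilds the organ-pair
#' band profiles, then reports the largest absolute change in band mean
#' between consecutive orders.  Used as a convergence diagnostic: band
#' profiles should stabilize once the order exceeds the system's
#' effective memory.
#'
#' @param rec A harmonized `multichannel_recording`.
#' @param orders Integer vector of candidate model orders.
#' @param pairs Organ pairs to profile; default all six ordered pairs.
#' @param bands A [define_bands()] grid.
#' @param ... Passed to [window_connectivity()] (window spec, grid,
#'   significance method, seed, ...).
#' @return `list(profiles = per-order list of per-pair profiles,
#'   max_abs_diff = named numeric, one entry per consecutive order pair,
#'   failures = per-order fit-failure counts)`.
#' @export
order_sensitivity <- function(rec, orders, pairs = organ_pairs(),
                              bands = define_bands(), ...) {
  orders <- sort(unique(as.integer(orders)))
  profiles <- vector("list", length(orders))
  names(profiles) <- paste0("p", orders)
  failures <- integer(length(orders))
  for (k in seq_along(orders)) {
    cs <- window_connectivity(rec, order = orders[k], ...)
    failures[k] <- sum(!vapply(cs$windows, `[[`, TRUE, "fit_ok"))
    if (failures[k] == length(cs$windows)) {
      profiles[[k]] <- NULL
      next
    }
    profiles[[k]] <- lapply(seq_len(nrow(pairs)), function(q)
      band_profile(cs, pairs[q, "from"], pairs[q, "to"], bands))
    names(profiles[[k]]) <- rownames(pairs)
  }
  diffs <- numeric(0)
  if (length(orders) > 1) {
    for (k in seq_len(length(orders) - 1L)) {
      a <- profiles[[k]]; b <- profiles[[k + 1L]]
      if (is.null(a) || is.null(b)) { d <- NA_real_ }
      else {
        d <- max(vapply(seq_along(a), function(q) {
          ma <- a[[q]]$mean[!a[[q]]$excluded]
          mb <- b[[q]]$mean[!b[[q]]$excluded]
          max(abs(ma - mb))
        }, numeric(1)))
      }
      diffs[sprintf("p%d_vs_p%d", orders[k], orders[k + 1L])] <- d
    }
  }
  names(failures) <- names(profiles)
  list(profiles = profiles, max_abs_diff = diffs, failures = failures)
}

#' Information-criterion diagnostics for MVAR order choice
#'
#' AIC/BIC per candidate order on one window, reported as a diagnostic
#' only (the pipeline default order is fixed, not auto-selected).
#'
#' @param block Samples x channels matrix.
#' @param orders Integer vector of candidate orders.
#' @param demean Passed to [fit_mvar()].
#' @return Data frame with `order`, `aic`, `bic`.
#' @export
order_criteria <- function(block, orders, demean = TRUE) {
  n <- nrow(block); D <- ncol(block)
  res <- lapply(orders, function(p) {
    fit <- suppressWarnings(fit_mvar(block, p, demean = demean))
    if (inherits(fit, "mvar_fit_failure"))
      return(data.frame(order = p, aic = NA_real_, bic = NA_real_))
    neff <- n - p
    ldet <- determinant(fit$noise_cov, logarithm = TRUE)$modulus
    k <- p * D * D
    data.frame(order = p,
               aic = as.numeric(neff * ldet + 2 * k),
               bic = as.numeric(neff * ldet + log(neff) * k))
  })
  do.call(rbind, res)
}
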