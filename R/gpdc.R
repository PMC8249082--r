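#' Frequency grid for spectral connectivity
#'
#' @param f_min,f_max Grid limits in Hz; defaults 1 and 200.
#' @param spacing Grid spacing in Hz; default 1 Hz (200 points over
#'   1-200 Hz).
#' @param fs Sampling rate in Hz; `f_max` must not exceed `fs/2`.
#' @return Object of class `frequency_grid` with fields `freqs`, `fs`,
#'   `f_max`.
#' @export
frequency_grid <- function(f_min = 1, f_max = 200, spacing = 1, fs = 500) {
  freqs <- seq(f_min, f_max, by = spacing)
  if (!(f_min > 0)) stop("f_min must be positive")
  if (f_max > fs / 2) stop("f_max exceeds the Nyquist rate fs/2")
  structure(list(freqs = freqs, fs = fs, f_max = f_max),
            class = "frequency_grid")
}

#' Spectral transfer structure of an MVAR model
#'
#' Evaluates
#' \deqn{\bar{A}(f) = I - \sum_{r=1}^{p} A_r e^{-i 2 \pi f r / f_s}}
#' on the frequency grid.  The entries of this complex array drive the
#' GPDC normalization.
#'
#' @param model An `mvar_model`.
#' @param grid A [frequency_grid()]; its `fs` must match the model's
#'   when the model records one.
#' @return Complex D x D x F array.
#' @export
spectral_transfer <- function(model, grid) {
  stopifnot(inherits(model, "mvar_model"), inherits(grid, "frequency_grid"))
  if (!is.na(model$fs) && model$fs != grid$fs)
    stop("grid fs does not match the model's sampling rate")
  A <- model$coeffs
  D <- model$dim; p <- model$order
  Fn <- length(grid$freqs)
  out <- array(0i, dim = c(D, D, Fn))
  I <- diag(D)
  for (fi in seq_len(Fn)) {
    w <- 2 * pi * grid$freqs[fi] / grid$fs
    Abar <- I + 0i
    for (r in seq_len(p)) Abar <- Abar - A[, , r] * exp(-1i * w * r)
    out[, , fi] <- Abar
  }
  out
}

#' Squared generalized partial directed coherence
#'
#' From a fitted MVAR model computes, for every ordered channel pair and
#' grid frequency,
#' \deqn{|\bar{\pi}_{ij}(f)|^2 =
#'   \frac{|\bar{A}_{ij}(f)|^2 / \sigma_i^2}
#'        {\sum_{k=1}^{D} |\bar{A}_{kj}(f)|^2 / \sigma_k^2}}
#' where \eqn{\sigma_k^2} are the residual noise variances.  Entry
#' `(i, j, f)` is the effective direct inflow from channel `j` to
#' channel `i` at frequency `f`.  The residual-variance weighting makes
#' the measure invariant to per-channel rescaling, so signals of vastly
#' different amplitudes (EEG vs ECG vs Pleth) are comparable.  Every
#' column sums to 1 over the receiving index, and values lie in [0, 1].
#' Diagonal (self) entries are computed but are never interpreted as
#' inter-organ flow downstream.
#'
#' @param model An `mvar_model`.
#' @param grid A [frequency_grid()].
#' @return Object of class `gpdc_spectrum`: `values` (D x D x F array of
#'   squared GPDC), `grid`, `window_index`.
#' @export
compute_gpdc <- function(model, grid) {
  stopifnot(inherits(model, "mvar_model"), inherits(grid, "frequency_grid"))
  if (!is.na(model$fs) && model$fs != grid$fs)
    stop("grid fs does not match the model's sampling rate")
  if (any(model$sigma2 <= 0)) stop("noise variances must be positive")
  vals <- cpp_gpdc(model$coeffs, model$sigma2, grid$freqs, grid$fs)
  if (anyNA(vals))
    warning("numerically zero transfer column at some frequency; NaN emitted")
  dimnames(vals) <- NULL
  structure(list(values = vals, grid = grid,
                 window_index = model$window_index),
            class = "gpdc_spectrum")
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gpdc_spectrum> %d x %d channels x %d frequencies (%g-%g Hz)\n",
              d[1], d[2], d[3], min(x$grid$freqs), max(x$grid$freqs)))
  invisible(x)
}
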