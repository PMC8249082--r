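#' Per-value significance of squared GPDC for one window
#'
#' Attaches a p-value to every GPDC value and masks at the strict
#' `p < alpha` rule; only masked ("statistically significant") values --
#' ssGPDC -- are pooled by the aggregation stage.
#'
#' Two backends:
#' \describe{
#' \item{`"surrogate"` (default)}{Circular-shift surrogates.  Each of
#'   `n_surrogates` surrogates independently rotates every channel by a
#'   random offset of at least `p` samples, which destroys cross-channel
#'   lag coupling while preserving each channel's autospectrum; the MVAR
#'   fit and GPDC are recomputed per surrogate and the p-value is the
#'   rank-based \eqn{(1 + \#\{null \ge obs\}) / (1 + S)}.  Distribution
#'   free; p-values are discrete multiples of \eqn{1/(S+1)}.}
#' \item{`"asymptotic"`}{Large-sample Gaussian null for
#'   \eqn{\bar A_{ij}(f) = 0} built from the lagged-regressor Gram
#'   matrix, with a two-moment (Satterthwaite) chi-square approximation
#'   to the quadratic-form null of \eqn{|\hat{\bar A}_{ij}(f)|^2}.
#'   Requires a stable model.  Diagonal entries have no zero-coupling
#'   null and get `NA` p-values (never masked).}
#' }
#'
#' No multiple-testing correction is applied across frequencies or
#' pairs: the mask is a raw per-value `p < alpha` rule, which is the
#' standard convention for ssGPDC profiles; see the package vignette for
#' the implications.
#'
#' @param block Samples x channels matrix (the window the model was fit
#'   on; required by the surrogate backend).
#' @param model The `mvar_model` fitted to `block` (asymptotic backend;
#'   recomputed internally for the surrogate backend).
#' @param grid A [frequency_grid()].
#' @param method `"surrogate"` or `"asymptotic"`.
#' @param alpha Significance level (default 0.05); masking uses strict
#'   `p < alpha`.
#' @param n_surrogates Number of surrogates (default 99; minimum 19).
#' @param demean Per-channel mean removal before fitting.
#' @param order Model order for the surrogate refits (default: taken
#'   from `model`, else 7).
#' @return Object of class `gpdc_significance`: `gpdc` (observed squared
#'   GPDC, D x D x F), `p_values`, `mask` (`p < alpha`, `NA` p never
#'   masked), `alpha`, `method`, `n_surrogates`, `n_failed`.
#' @export
gpdc_significance <- function(block = NULL, model = NULL, grid,
                              method = c("surrogate", "asymptotic"),
                              alpha = 0.05, n_surrogates = 99,
                              demean = TRUE, order = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "frequency_grid"))
  if (method == "surrogate") {
    if (is.null(block)) stop("surrogate method needs the window data block")
    if (n_surrogates < 19) stop("n_surrogates must be >= 19")
    p <- if (!is.null(order)) as.integer(order)
         else if (!is.null(model)) model$order else 7L
    block <- as.matrix(block); storage.mode(block) <- "double"
    n <- nrow(block); D <- ncol(block)
    if (n <= 2 * p) stop("window too short for circular-shift surrogates")
    # offsets >= p so lagged alignment is destroyed; drawn from R's RNG
    shifts <- matrix(sample.int(n - 2L * p + 1L, n_surrogates * D,
                                replace = TRUE) + p - 1L,
                     nrow = n_surrogates, ncol = D)
    res <- cpp_surrogate_gpdc(block, p, grid$freqs, grid$fs, shifts, demean)
    if (!isTRUE(res$ok))
      stop("MVAR fit failed on the observed window (singular design)")
    if (res$n_failed > 0.2 * n_surrogates)
      stop(sprintf("window aborted: %d of %d surrogate fits failed",
                   res$n_failed, n_surrogates))
    pv <- (1 + res$count) / (1 + res$n_used)
    out <- list(gpdc = res$gpdc, p_values = pv,
                mask = !is.na(pv) & pv < alpha, alpha = alpha,
                method = "SURROGATE", n_surrogates = n_surrogates,
                n_failed = res$n_failed)
  } else {
    if (is.null(model)) {
      if (is.null(block)) stop("asymptotic method needs a model or a block")
      model <- fit_mvar(block, order = if (is.null(order)) 7L else order,
                        demean = demean, fs = grid$fs)
    }
    if (inherits(model, "mvar_fit_failure"))
      stop("MVAR fit failed on the observed window (singular design)")
    st <- check_stability(model)
    if (!st$stable)
      stop(sprintf(
        "asymptotic null needs a stable model (spectral radius %.3f); use method = 'surrogate'",
        st$spectral_radius))
    pv <- asymptotic_pvalues(model, grid)
    spec <- compute_gpdc(model, grid)
    out <- list(gpdc = spec$values, p_values = pv,
                mask = !is.na(pv) & pv < alpha, alpha = alpha,
                method = "ASYMPTOTIC", n_surrogates = NA_integer_,
                n_failed = 0L)
  }
  structure(out, class = "gpdc_significance")
}

# Asymptotic p-values for H0: Abar_ij(f) = 0 (zero direct coupling j -> i).
# Under H0 the OLS coefficient subvector b_.j (lags r = 1..p of source j in
# equation i) is asymptotically N(0, sigma_i^2 W_j / n_eff) with
# W_j = [Gram^{-1}] restricted to source-j columns.  |Abar_ij(f)|^2 =
# (c'b)^2 + (s'b)^2 with c_r = cos(wr), s_r = sin(wr) is then a
# two-component chi-square quadratic form whose exact weights are the
# eigenvalues of the 2x2 covariance of (c'b, s'b); a Satterthwaite
# two-moment chi-square matches those weights.
asymptotic_pvalues <- function(model, grid) {
  D <- model$dim; p <- model$order
  neff <- model$n_samples - p
  Ginv <- solve(model$gram)
  Abar <- spectral_transfer(model, grid)
  freqs <- grid$freqs
  pv <- array(NA_real_, dim = c(D, D, length(freqs)))
  for (fi in seq_along(freqs)) {
    w <- 2 * pi * freqs[fi] / grid$fs
    cvec <- cos(w * seq_len(p)); svec <- sin(w * seq_len(p))
    obs <- Mod(Abar[, , fi])^2
    for (j in seq_len(D)) {
      idx <- j + D * (seq_len(p) - 1L)
      W <- Ginv[idx, idx, drop = FALSE]
      qcc <- drop(crossprod(cvec, W %*% cvec))
      qss <- drop(crossprod(svec, W %*% svec))
      qcs <- drop(crossprod(cvec, W %*% svec))
      # eigenvalues of [[qcc, -qcs], [-qcs, qss]], scaled per target i
      tr <- (qcc + qss) / 2
      dd <- sqrt(((qcc - qss) / 2)^2 + qcs^2)
      lam <- c(tr + dd, max(tr - dd, 0))
      for (i in seq_len(D)) {
        if (i == j) next
        li <- lam * model$sigma2[i] / neff
        sl <- sum(li); sl2 <- sum(li^2)
        if (sl2 <= 0) { pv[i, j, fi] <- 1; next }
        g <- sl2 / sl; nu <- sl^2 / sl2
        pv[i, j, fi] <- stats::pchisq(obs[i, j] / g, df = nu,
                                      lower.tail = FALSE)
      }
    }
  }
  pv
}

#' Windowed connectivity analysis of a recording
#'
#' The central driver: segments the harmonized recording, fits the MVAR
#' model to every window, computes the squared GPDC spectrum and the
#' per-value significance mask, and returns the per-window results in a
#' container the aggregation, group-comparison and dynamics stages
#' consume.  Windows whose fit (or more than 20% of whose surrogate
#' fits) fails are flagged and excluded downstream, with a log entry.
#'
#' @param rec A rate-harmonized `multichannel_recording`.
#' @param spec A [window_spec()] (default 10-s non-overlapping windows).
#' @param order MVAR model order (default 7).
#' @param grid A [frequency_grid()]; defaults to 1-200 Hz at 1 Hz
#'   spacing at the recording's rate.
#' @param method,alpha,n_surrogates Passed to [gpdc_significance()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   once so all surrogate offsets (the only randomness) are
#'   reproducible bit-for-bit.
#' @param demean Per-window per-channel mean removal (default `TRUE`).
#' @param progress Print a dot every 50 windows.
#' @return Object of class `connectivity_set`: `windows` (list of
#'   `list(window_index, start_s, fit_ok, values, p_values, mask,
#'   spectral_radius, sigma2)`), plus `grid`, `fs`, `channel_labels`,
#'   `organ_map`, `alpha`, `method`, `n_surrogates`, `order`,
#'   `window_spec`, `n_excluded`.
#' @export
window_connectivity <- function(rec, spec = window_spec(), order = 7,
                                grid = NULL,
                                method = c("surrogate", "asymptotic"),
                                alpha = 0.05, n_surrogates = 99,
                                seed = NULL, demean = TRUE,
                                progress = FALSE) {
  method <- match.arg(method)
  if (is.null(grid)) grid <- frequency_grid(fs = rec$fs[1])
  if (!is.null(seed)) set.seed(seed)
  wins <- segment_windows(rec, spec)
  out <- vector("list", length(wins))
  n_excluded <- 0L
  for (k in seq_along(wins)) {
    w <- wins[[k]]
    fit <- suppressWarnings(fit_mvar(w$data, order = order, demean = demean,
                                     fs = grid$fs,
                                     window_index = w$window_index))
    if (inherits(fit, "mvar_fit_failure")) {
      message(sprintf("window %d excluded: %s", w$window_index, fit$reason))
      n_excluded <- n_excluded + 1L
      out[[k]] <- list(window_index = w$window_index, start_s = w$start_s,
                       fit_ok = FALSE)
      next
    }
    sig <- tryCatch(
      gpdc_significance(block = w$data, model = fit, grid = grid,
                        method = method, alpha = alpha,
                        n_surrogates = n_surrogates, demean = demean,
                        order = order),
      error = function(e) e)
    if (inherits(sig, "error")) {
      message(sprintf("window %d excluded: %s", w$window_index,
                      conditionMessage(sig)))
      n_excluded <- n_excluded + 1L
      out[[k]] <- list(window_index = w$window_index, start_s = w$start_s,
                       fit_ok = FALSE)
      next
    }
    st <- check_stability(fit)
    if (!st$stable)
      message(sprintf(
        "window %d: unstable fit (spectral radius %.3f); kept and flagged",
        w$window_index, st$spectral_radius))
    out[[k]] <- list(window_index = w$window_index, start_s = w$start_s,
                     fit_ok = TRUE, values = sig$gpdc,
                     p_values = sig$p_values, mask = sig$mask,
                     spectral_radius = st$spectral_radius,
                     sigma2 = fit$sigma2)
    if (progress && k %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(windows = out, grid = grid, fs = rec$fs[1],
                 channel_labels = rec$channel_labels,
                 organ_map = rec$organ_map, alpha = alpha,
                 method = toupper(method), n_surrogates = n_surrogates,
                 order = order, window_spec = spec,
                 n_excluded = n_excluded),
            class = "connectivity_set")
}

#' @export
print.connectivity_set <- function(x, ...) {
  ok <- sum(vapply(x$windows, `[[`, TRUE, "fit_ok"))
  cat(sprintf(
    "<connectivity_set> %d window(s) (%d excluded), D = %d, p = %d, %s alpha = %g\n",
    length(x$windows), x$n_excluded, length(x$channel_labels), x$order,
    x$method, x$alpha))
  invisible(x)
}

#' Long-format export of per-window GPDC values
#'
#' @param cs A `connectivity_set`.
#' @param path Optional file; when given, written as a tab-separated
#'   table.
#' @return Data frame with columns `window_index`, `from_channel`,
#'   `to_channel`, `freq_hz`, `gpdc_sq`, `p_value`, `significant`.
#' @export
export_gpdc_table <- function(cs, path = NULL) {
  stopifnot(inherits(cs, "connectivity_set"))
  labs <- cs$channel_labels
  D <- length(labs); freqs <- cs$grid$freqs
  rows <- lapply(cs$windows, function(w) {
    if (!isTRUE(w$fit_ok)) return(NULL)
    data.frame(window_index = w$window_index,
               from_channel = rep(rep(labs, each = D), length(freqs)),
               to_channel = rep(labs, D * length(freqs)),
               freq_hz = rep(freqs, each = D * D),
               gpdc_sq = as.vector(w$values),
               p_value = as.vector(w$p_values),
               significant = as.vector(w$mask))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
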