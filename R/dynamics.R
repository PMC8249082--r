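#' In-band connectivity time series for one organ pair
#'
#' One value per analysed window: the mean of the statistically
#' significant in-band squared GPDC values across the pair's channel
#' combinations, or 0 when the window has none (consistent with the
#' profile zero rule).  With `zero_empty = FALSE` empty windows are
#' `NA` (gap) instead, for sensitivity analysis.  Windows excluded by
#' fit failure are always `NA`.
#'
#' @param cs A `connectivity_set`.
#' @param from_organ,to_organ Ordered organ pair.
#' @param band Numeric `c(low, high)` in Hz (half-open `(low, high]`).
#' @param zero_empty Treat windows without significant values as 0
#'   (default) or as missing.
#' @param events Optional data frame of annotations with columns
#'   `time_s`, `label` (e.g. seizure onsets); pure metadata, never
#'   alters values.
#' @return Object of class `connectivity_ts`: a data frame with
#'   `time_s`, `value`, plus attributes `band`, `pair`, `events`,
#'   `smoothing_k` (`NA` until smoothed).
#' @export
extract_band_timeseries <- function(cs, from_organ, to_organ, band,
                                    zero_empty = TRUE, events = NULL) {
  stopifnot(inherits(cs, "connectivity_set"))
  combos <- pair_channels(cs, from_organ, to_organ)
  fsel <- which(cs$grid$freqs > band[1] & cs$grid$freqs <= band[2])
  if (length(fsel) == 0) stop("band contains no grid frequencies")
  ii <- combos$i; jj <- combos$j
  idx <- cbind(rep(ii, length(fsel)), rep(jj, length(fsel)),
               rep(fsel, each = length(ii)))
  times <- vapply(cs$windows, `[[`, numeric(1), "start_s")
  vals <- vapply(cs$windows, function(w) {
    if (!isTRUE(w$fit_ok)) return(NA_real_)
    v <- w$values[idx][w$mask[idx]]
    if (length(v) == 0) { if (zero_empty) 0 else NA_real_ } else mean(v)
  }, numeric(1))
  out <- data.frame(time_s = times, value = vals)
  attr(out, "band") <- band
  attr(out, "pair") <- c(from = toupper(from_organ), to = toupper(to_organ))
  attr(out, "events") <- events
  attr(out, "smoothing_k") <- NA_integer_
  class(out) <- c("connectivity_ts", "data.frame")
  out
}

#' Centered moving-average smoothing of a connectivity series
#'
#' Smooths with a centered window of half-width `k` (default 4, i.e. 9
#' points: previous 4, current, next 4 -- each smoothed value then
#' reflects 90 s of raw data for 10-s windows).  At the edges the window
#' shrinks symmetrically to the available points, so a constant series
#' is preserved exactly and `k = 0` is the identity.  Timestamps and
#' event annotations are unchanged.  `NA` values (excluded windows /
#' gaps) are dropped from each local average.
#'
#' @param series A `connectivity_ts`.
#' @param k Half-width in windows (window length is `2k + 1`).
#' @return A `connectivity_ts` with the smoothed values; the raw values
#'   are kept in column `raw`.
#' @export
smooth_series <- function(series, k = 4) {
  stopifnot(inherits(series, "connectivity_ts"), k >= 0)
  x <- series$value
  n <- length(x)
  sm <- numeric(n)
  for (i in seq_len(n)) {
    ke <- min(k, i - 1L, n - i)
    win <- x[(i - ke):(i + ke)]
    sm[i] <- mean(win, na.rm = TRUE)
  }
  sm[is.nan(sm)] <- NA_real_
  out <- data.frame(time_s = series$time_s, value = sm, raw = x)
  for (a in c("band", "pair", "events")) attr(out, a) <- attr(series, a)
  attr(out, "smoothing_k") <- as.integer(k)
  class(out) <- c("connectivity_ts", "data.frame")
  out
}

#' Group reference bands (mean +/- SEM envelopes) at a selected band
#'
#' For overlaying time-resolved series on the background of each
#' group's pooled in-band ssGPDC level: one (mean, SEM) pair per group,
#' e.g. the WT envelope and the seizure-free KO envelope behind a
#' seizing animal's trace.
#'
#' @param pools Named list of numeric vectors: one pooled ssGPDC sample
#'   per group (e.g. from [pool_organ_pair()] at the selected band).
#' @param band Numeric `c(low, high)` carried into the result.
#' @return Data frame with `group`, `n`, `mean`, `sem`, `low`, `high`;
#'   groups with empty pools are omitted with a warning.
#' @export
reference_bands <- function(pools, band = c(NA_real_, NA_real_)) {
  stopifnot(is.list(pools), !is.null(names(pools)))
  rows <- list()
  for (g in names(pools)) {
    v <- as.numeric(pools[[g]])
    if (length(v) == 0) {
      warning("group ", g, " has an empty pool; reference band omitted")
      next
    }
    rows[[g]] <- data.frame(group = g, n = length(v), mean = mean(v),
                            sem = sem0(v), low = band[1], high = band[2])
  }
  if (length(rows) == 0) stop("no non-empty group pools")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a connectivity time series as a tidy table
#'
#' @param series A (smoothed or raw) `connectivity_ts`.
#' @param path Optional file; written tab-separated when given.
#' @return Data frame with `time_s`, `raw_value`, `smoothed_value`,
#'   `from`, `to`, `band_low`, `band_high`.
#' @export
export_series_table <- function(series, path = NULL) {
  pair <- attr(series, "pair"); band <- attr(series, "band")
  raw <- if ("raw" %in% names(series)) series$raw else series$value
  smo <- if ("raw" %in% names(series)) series$value else NA_real_
  df <- data.frame(time_s = series$time_s, raw_value = raw,
                   smoothed_value = smo,
                   from = pair[["from"]], to = pair[["to"]],
                   band_low = band[1], band_high = band[2])
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
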