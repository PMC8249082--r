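#' Frequency-band grid with line-noise harmonic exclusion
#'
#' Partitions `(0, f_max]` into consecutive half-open bands
#' `(low, high]` of width `width_hz` and flags as excluded every band
#' whose interval contains a multiple of the mains frequency
#' `line_hz`.  With the defaults (10 Hz bands to 200 Hz, 60 Hz mains)
#' the bands `(50,60]`, `(110,120]` and `(170,180]` are excluded,
#' leaving 17 of 20 bands.  Set `line_hz = 0` to disable exclusion.
#'
#' @param width_hz Band width in Hz; must divide `f_max`.
#' @param f_max Upper edge of the last band in Hz.
#' @param line_hz Mains frequency in Hz (0 disables harmonic exclusion).
#' @return Object of class `band_grid`: a data frame with columns `low`,
#'   `high`, `excluded`.
#' @export
define_bands <- function(width_hz = 10, f_max = 200, line_hz = 60) {
  if (abs(f_max / width_hz - round(f_max / width_hz)) > 1e-9)
    stop("width_hz must divide f_max")
  nb <- as.integer(round(f_max / width_hz))
  low <- (seq_len(nb) - 1L) * width_hz
  high <- seq_len(nb) * width_hz
  excluded <- rep(FALSE, nb)
  if (line_hz > 0) {
    harmonics <- seq(line_hz, f_max, by = line_hz)
    for (h in harmonics) excluded <- excluded | (low < h & h <= high)
  }
  structure(data.frame(low = low, high = high, excluded = excluded),
            class = c("band_grid", "data.frame"))
}

# channel index combinations for an ordered organ pair
pair_channels <- function(cs, from_organ, to_organ) {
  from_organ <- toupper(from_organ); to_organ <- toupper(to_organ)
  bad <- setdiff(c(from_organ, to_organ), ORGANS)
  if (length(bad) > 0) stop("unknown organ(s): ", paste(bad, collapse = ", "))
  if (from_organ == to_organ)
    stop("organ pair must connect two different organs")
  src <- which(cs$organ_map == from_organ)
  dst <- which(cs$organ_map == to_organ)
  if (length(src) == 0 || length(dst) == 0)
    stop("no channel for organ ", if (length(src) == 0) from_organ else to_organ)
  expand.grid(i = dst, j = src)  # value index (to-row i, from-col j)
}

#' Pool significant GPDC values for one organ pair and frequency band
#'
#' Collects the multiset of all statistically significant squared GPDC
#' (ssGPDC) values over all channel pairs in the ordered organ pair, all
#' grid frequencies inside the half-open band `(low, high]`, and all
#' analysed windows.  Non-significant values are dropped (not zeroed) at
#' the value level; the zero rule applies only to empty band means in
#' [band_profile()].
#'
#' @param cs A `connectivity_set`.
#' @param from_organ,to_organ Ordered pair of organs (`"BRAIN"`,
#'   `"HEART"`, `"LUNGS"`); flow is from `from_organ` to `to_organ`.
#' @param band Numeric `c(low, high)` in Hz; default the full grid.
#' @return Numeric vector of pooled ssGPDC values, with attributes
#'   `n_total` (count of values tested, significant or not) and
#'   `n_windows` (analysed windows).  May be empty.
#' @export
pool_organ_pair <- function(cs, from_organ, to_organ,
                            band = c(0, max(cs$grid$freqs))) {
  stopifnot(inherits(cs, "connectivity_set"))
  combos <- pair_channels(cs, from_organ, to_organ)
  fsel <- which(cs$grid$freqs > band[1] & cs$grid$freqs <= band[2])
  vals <- numeric(0)
  n_total <- 0L; n_windows <- 0L
  if (length(fsel) > 0) {
    ii <- combos$i; jj <- combos$j
    for (w in cs$windows) {
      if (!isTRUE(w$fit_ok)) next
      n_windows <- n_windows + 1L
      v <- w$values[cbind(rep(ii, length(fsel)), rep(jj, length(fsel)),
                          rep(fsel, each = length(ii)))]
      m <- w$mask[cbind(rep(ii, length(fsel)), rep(jj, length(fsel)),
                        rep(fsel, each = length(ii)))]
      n_total <- n_total + length(v)
      vals <- c(vals, v[m])
    }
  }
  attr(vals, "n_total") <- n_total
  attr(vals, "n_windows") <- n_windows
  vals
}

sem0 <- function(x) {
  n <- length(x)
  if (n <= 1) return(0)
  stats::sd(x) / sqrt(n)
}

#' Organ-pair interaction profile across frequency bands
#'
#' Mean and SEM of pooled ssGPDC values per retained band.  Bands with no
#' significant values get mean 0 and SEM 0 with `zero_assigned = TRUE`
#' (the profile zero rule); excluded (line-noise harmonic) bands carry no
#' profile values (`NA` with `excluded = TRUE`).  Single-value bands
#' report SEM 0 and are flagged via `n = 1`.
#'
#' @param cs A `connectivity_set`.
#' @param from_organ,to_organ Ordered organ pair.
#' @param bands A [define_bands()] grid.
#' @return Object of class `interaction_profile`: a data frame with
#'   columns `from`, `to`, `low`, `high`, `n`, `mean`, `sem`,
#'   `zero_assigned`, `excluded`, plus attribute `pools` (the per-band
#'   value multisets, retained bands only).
#' @export
band_profile <- function(cs, from_organ, to_organ, bands = define_bands()) {
  stopifnot(inherits(bands, "band_grid"))
  nb <- nrow(bands)
  out <- data.frame(from = toupper(from_organ), to = toupper(to_organ),
                    low = bands$low, high = bands$high,
                    n = NA_integer_, mean = NA_real_, sem = NA_real_,
                    zero_assigned = FALSE, excluded = bands$excluded)
  pools <- vector("list", nb)
  for (b in seq_len(nb)) {
    if (bands$excluded[b]) next
    v <- pool_organ_pair(cs, from_organ, to_organ,
                         band = c(bands$low[b], bands$high[b]))
    pools[[b]] <- as.numeric(v)
    out$n[b] <- length(v)
    if (length(v) == 0) {
      out$mean[b] <- 0; out$sem[b] <- 0; out$zero_assigned[b] <- TRUE
    } else {
      out$mean[b] <- mean(v); out$sem[b] <- sem0(v)
    }
  }
  attr(out, "pools") <- pools
  class(out) <- c("interaction_profile", "data.frame")
  out
}

#' Full-spectrum pooled average for one organ pair
#'
#' Pools ssGPDC values over the whole grid, omitting frequencies that
#' fall in excluded (line-noise harmonic) bands, and returns the pooled
#' mean and SEM.  Equivalent to a [band_profile()] with a single band
#' spanning the full range.
#'
#' @inheritParams band_profile
#' @return `list(from, to, n, mean, sem, zero_assigned, values)`.
#' @export
fullband_average <- function(cs, from_organ, to_organ,
                             bands = define_bands()) {
  vals <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    if (bands$excluded[b]) next
    vals <- c(vals, as.numeric(
      pool_organ_pair(cs, from_organ, to_organ,
                      band = c(bands$low[b], bands$high[b]))))
  }
  if (length(vals) == 0)
    list(from = toupper(from_organ), to = toupper(to_organ), n = 0L,
         mean = 0, sem = 0, zero_assigned = TRUE, values = vals)
  else
    list(from = toupper(from_organ), to = toupper(to_organ),
         n = length(vals), mean = mean(vals), sem = sem0(vals),
         zero_assigned = FALSE, values = vals)
}

#' Fraction of GPDC values reaching significance, per pair and band
#'
#' For every ordered organ pair and retained band, the fraction of all
#' tested GPDC values (channel pairs x in-band frequencies x windows)
#' whose p-value passed `p < alpha`.  The complementary non-significant
#' percentage is included for export.
#'
#' @param cs A `connectivity_set`.
#' @param bands A [define_bands()] grid.
#' @return Data frame with `from`, `to`, `low`, `high`, `n_total`,
#'   `n_significant`, `fraction`, `pct_not_significant`.
#' @export
significance_fraction <- function(cs, bands = define_bands()) {
  prs <- organ_pairs()
  present <- unique(cs$organ_map)
  prs <- prs[prs[, "from"] %in% present & prs[, "to"] %in% present, ,
             drop = FALSE]
  rows <- list()
  for (q in seq_len(nrow(prs))) {
    for (b in seq_len(nrow(bands))) {
      if (bands$excluded[b]) next
      v <- pool_organ_pair(cs, prs[q, "from"], prs[q, "to"],
                           band = c(bands$low[b], bands$high[b]))
      nt <- attr(v, "n_total")
      frac <- if (nt > 0) length(v) / nt else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(from = prs[q, "from"], to = prs[q, "to"],
                   low = bands$low[b], high = bands$high[b],
                   n_total = nt, n_significant = length(v),
                   fraction = frac,
                   pct_not_significant = 100 * (1 - frac))
    }
  }
  do.call(rbind, rows)
}
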