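#' Multichannel physiological recording
#'
#' Container for concurrent multichannel signals (e.g. 4 EEG + 1 ECG +
#' 1 Pleth).  Channels may have different sampling rates before
#' harmonization (as when ECG is acquired at 2 kHz and EEG/Pleth at
#' 500 Hz), so signals are stored as a list of numeric vectors; once all
#' channels share one rate, [rec_matrix()] yields the samples x channels
#' matrix the modelling stages consume.
#'
#' @param signals A numeric matrix (samples x channels) or a list of
#'   numeric vectors, one per channel.
#' @param fs Sampling rate(s) in Hz; a single value or one per channel.
#' @param channel_labels Character vector of channel names; defaults to
#'   matrix column names.
#' @param organ_map Named character vector mapping every channel label to
#'   an organ: `"BRAIN"`, `"HEART"` or `"LUNGS"`.
#' @param start_time Offset of the first sample, in seconds.
#' @return An object of class `multichannel_recording` with fields
#'   `signals`, `fs`, `channel_labels`, `organ_map`, `start_time`.
#' @export
multichannel_recording <- function(signals, fs, channel_labels = NULL,
                                   organ_map, start_time = 0) {
  if (is.matrix(signals)) {
    if (is.null(channel_labels)) channel_labels <- colnames(signals)
    signals <- lapply(seq_len(ncol(signals)), function(j) signals[, j])
  }
  if (!is.list(signals) || length(signals) < 1L)
    stop("'signals' must be a non-empty matrix or list of numeric vectors")
  D <- length(signals)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(D))
  if (length(channel_labels) != D)
    stop("need one channel label per channel")
  names(signals) <- channel_labels
  fs <- rep_len(as.numeric(fs), D)
  if (any(!is.finite(fs)) || any(fs <= 0)) stop("sampling rates must be positive")
  organ_map <- validate_organ_map(organ_map, channel_labels)
  for (lab in channel_labels) {
    x <- signals[[lab]]
    if (length(x) < 1L) stop("channel ", lab, " has no samples")
    bad <- which(!is.finite(x))
    if (length(bad) > 0L)
      stop(sprintf("non-finite value in channel %s at sample index %d",
                   lab, bad[1L] - 1L))
  }
  structure(list(signals = signals, fs = fs,
                 channel_labels = channel_labels,
                 organ_map = organ_map,
                 start_time = as.numeric(start_time)),
            class = "multichannel_recording")
}

validate_organ_map <- function(organ_map, channel_labels) {
  if (is.null(organ_map)) stop("an organ_map is required")
  organ_map <- unlist(organ_map)
  if (is.null(names(organ_map)) || any(names(organ_map) == ""))
    stop("organ_map must be a named channel -> organ mapping")
  missing <- setdiff(names(organ_map), channel_labels)
  if (length(missing) > 0L)
    stop("organ_map names channel(s) absent from the data: ",
         paste(missing, collapse = ", "))
  unmapped <- setdiff(channel_labels, names(organ_map))
  if (length(unmapped) > 0L)
    stop("channel(s) without organ assignment: ",
         paste(unmapped, collapse = ", "))
  organ_map <- toupper(organ_map[channel_labels])
  bad <- setdiff(unique(organ_map), ORGANS)
  if (length(bad) > 0L)
    stop("unknown organ(s): ", paste(bad, collapse = ", "),
         " (expected BRAIN, HEART or LUNGS)")
  organ_map
}

#' @export
print.multichannel_recording <- function(x, ...) {
  ns <- vapply(x$signals, length, integer(1))
  cat(sprintf("<multichannel_recording> %d channel(s)\n", length(x$signals)))
  for (i in seq_along(x$signals))
    cat(sprintf("  %-8s %-6s %8d samples @ %g Hz (%.1f s)\n",
                x$channel_labels[i], x$organ_map[i], ns[i], x$fs[i],
                ns[i] / x$fs[i]))
  invisible(x)
}

#' Samples-by-channels matrix of a rate-harmonized recording
#'
#' @param rec A `multichannel_recording` whose channels all share one
#'   sampling rate and length.
#' @return Numeric matrix, samples x channels, with channel labels as
#'   column names.
#' @export
rec_matrix <- function(rec) {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (length(unique(rec$fs)) != 1L)
    stop("channels have mixed sampling rates; run lowpass_downsample() first")
  ns <- vapply(rec$signals, length, integer(1))
  if (length(unique(ns)) != 1L)
    stop("channels have unequal lengths; harmonize first")
  m <- do.call(cbind, rec$signals)
  colnames(m) <- rec$channel_labels
  m
}

#' Read a multichannel recording from EDF or delimited text
#'
#' Delimited text: one header row of channel labels, one row per sample,
#' tab- or comma-separated; the sampling rate comes from a YAML sidecar
#' `<path>.meta.yaml` written by [write_recording()], or from `fs`.
#' EDF (European Data Format, 16-bit): labels, per-signal rates and
#' physical calibration are taken from the header; channels may have
#' different rates.
#'
#' @param path Path to an `.edf` file or a delimited-text matrix.
#' @param organ_map Named channel -> organ mapping; if `NULL`, taken from
#'   the text sidecar when present.
#' @param fs Sampling rate in Hz for text input without a sidecar.
#' @return A validated [multichannel_recording()], channels in file order.
#' @export
read_recording <- function(path, organ_map = NULL, fs = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is_edf(path)) {
    edf <- read_edf(path)
    return(multichannel_recording(edf$signals, fs = edf$fs,
                                  channel_labels = edf$labels,
                                  organ_map = organ_map))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (nrow(dat) < 1L || ncol(dat) < 1L) stop("empty recording: ", path)
  meta_path <- paste0(path, ".meta.yaml")
  start_time <- 0
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (is.null(fs)) fs <- meta$fs
    if (is.null(organ_map)) organ_map <- unlist(meta$organ_map)
    if (!is.null(meta$start_time)) start_time <- meta$start_time
  }
  if (is.null(fs))
    stop("no sampling rate: pass fs= or provide ", meta_path)
  multichannel_recording(as.matrix(dat), fs = fs,
                         channel_labels = colnames(dat),
                         organ_map = organ_map, start_time = start_time)
}

#' Write a recording as delimited text plus a YAML sidecar
#'
#' Inverse of [read_recording()] for the text dialect; the sidecar
#' `<path>.meta.yaml` stores sampling rate, organ map and start time.
#' Values are written with full precision so text round-trips are
#' bit-exact.
#'
#' @param rec A rate-harmonized `multichannel_recording`.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  m <- rec_matrix(rec)
  df <- as.data.frame(m)
  # format() with digits=17 keeps doubles exact under read.table round-trip
  for (j in seq_along(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(fs = rec$fs[1], organ_map = as.list(rec$organ_map),
                        start_time = rec$start_time),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

is_edf <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  identical(rawToChar(magic), "0       ")
}

# Minimal EDF/EDF+C reader (16-bit samples).  Header layout per the EDF
# standard: 256-byte fixed header, then 256 bytes per signal of field
# blocks, then data records of int16 little-endian, channel-sequential.
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr_chr <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  version <- hdr_chr(8L)
  if (!identical(version, "0")) stop("not an EDF file (version field): ", path)
  hdr_chr(80L); hdr_chr(80L)           # patient / recording id
  hdr_chr(8L); hdr_chr(8L)             # start date / time
  header_bytes <- as.integer(hdr_chr(8L))
  reserved <- hdr_chr(44L)
  n_records <- as.integer(hdr_chr(8L))
  record_dur <- as.numeric(hdr_chr(8L))
  ns <- as.integer(hdr_chr(4L))
  if (is.na(ns) || ns < 1L) stop("EDF header: bad signal count")
  field <- function(nbytes) vapply(seq_len(ns), function(i) hdr_chr(nbytes), "")
  labels <- field(16L)
  field(80L)                           # transducer
  field(8L)                            # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                           # prefiltering
  spr <- as.integer(field(8L))         # samples per record
  field(32L)                           # reserved
  if (startsWith(reserved, "EDF+D"))
    stop("discontinuous EDF+ files are not supported")
  seek(con, header_bytes)
  total <- sum(spr) * n_records
  raw_smp <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                     endian = "little")
  if (length(raw_smp) < total) stop("EDF data truncated: ", path)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- vector("list", ns)
  offs <- cumsum(c(0L, spr))
  rec_len <- sum(spr)
  for (s in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[s]) + offs[s],
                           (seq_len(n_records) - 1L) * rec_len, `+`))
    dig <- raw_smp[idx]
    signals[[s]] <- phys_min[s] + (dig - dig_min[s]) * gain[s]
  }
  list(signals = signals, labels = labels, fs = spr / record_dur)
}

#' Window specification
#'
#' @param length_s Window length in seconds (default 10, the standard
#'   short-time epoch for MVAR connectivity analysis).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (default 0: consecutive, non-overlapping windows).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 10, overlap_s = 0) {
  if (!(length_s > 0)) stop("length_s must be positive")
  if (overlap_s < 0 || overlap_s >= length_s)
    stop("overlap_s must satisfy 0 <= overlap_s < length_s")
  structure(list(length_s = length_s, overlap_s = overlap_s),
            class = "window_spec")
}

#' Segment a recording into analysis windows
#'
#' Cuts the harmonized recording into windows of exactly
#' `length_s * fs` samples.  With zero overlap the windows are
#' consecutive and cover a gapless prefix of the recording; a trailing
#' partial window is dropped (with a message).  Window indices are
#' 0-based and start times are the half-open interval starts
#' `[start, start + length_s)`.
#'
#' @param rec A rate-harmonized `multichannel_recording`.
#' @param spec A [window_spec()].
#' @return List of windows, each `list(window_index, start_s, data)` with
#'   `data` a samples x channels matrix.
#' @export
segment_windows <- function(rec, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  m <- rec_matrix(rec)
  fs <- rec$fs[1]
  wlen <- round(spec$length_s * fs)
  step <- round((spec$length_s - spec$overlap_s) * fs)
  n <- nrow(m)
  if (n < wlen)
    stop(sprintf("recording (%d samples) shorter than one %g-s window",
                 n, spec$length_s))
  starts <- seq(1L, n - wlen + 1L, by = step)
  dropped <- n - (starts[length(starts)] + wlen - 1L)
  if (dropped > 0L)
    message(sprintf("dropping trailing partial window: %d samples (%.2f s)",
                    dropped, dropped / fs))
  lapply(seq_along(starts), function(k) {
    s <- starts[k]
    list(window_index = k - 1L,
         start_s = rec$start_time + (s - 1L) / fs,
         data = m[s:(s + wlen - 1L), , drop = FALSE])
  })
}
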