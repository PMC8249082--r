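#' Low-pass filter and decimate channels to a common sampling rate
#'
#' Channels above `target_fs` are low-pass filtered with a Butterworth
#' digital filter (order `order`, cutoff `cutoff_hz`) applied causally
#' (forward only), then decimated by the integer ratio
#' `fs / target_fs`.  Channels already at `target_fs` pass through
#' unfiltered by default, mirroring an acquisition chain in which only
#' the high-rate channel (e.g. 2 kHz ECG) needs anti-alias filtering
#' before matching the 500 Hz EEG/Pleth rate.
#'
#' @param rec A `multichannel_recording`.
#' @param cutoff_hz Filter cutoff in Hz; must be below `target_fs / 2`.
#' @param order Butterworth filter order (default 4).
#' @param target_fs Common output rate in Hz; must divide each channel's
#'   rate that requires decimation.
#' @param zero_phase If `TRUE`, apply the filter forward and backward
#'   (`signal::filtfilt`) for zero phase lag; default `FALSE` (causal).
#' @param filter_passthrough If `TRUE`, also filter channels already at
#'   `target_fs`.
#' @return A harmonized `multichannel_recording` with all channels at
#'   `target_fs`.
#' @export
lowpass_downsample <- function(rec, cutoff_hz = 200, order = 4,
                               target_fs = 500, zero_phase = FALSE,
                               filter_passthrough = FALSE) {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (!(cutoff_hz < target_fs / 2))
    stop("cutoff_hz must be below the target Nyquist rate target_fs/2")
  out <- rec$signals
  for (i in seq_along(out)) {
    fs_i <- rec$fs[i]
    needs_decim <- fs_i != target_fs
    if (needs_decim) {
      if (fs_i < target_fs)
        stop(sprintf("channel %s at %g Hz is below target_fs = %g Hz",
                     rec$channel_labels[i], fs_i, target_fs))
      ratio <- fs_i / target_fs
      if (abs(ratio - round(ratio)) > 1e-9)
        stop(sprintf(
          "target_fs = %g Hz is not an integer divisor of channel %s's %g Hz",
          target_fs, rec$channel_labels[i], fs_i))
      ratio <- as.integer(round(ratio))
    }
    if (needs_decim || filter_passthrough) {
      bf <- signal::butter(order, cutoff_hz / (fs_i / 2), type = "low")
      x <- out[[i]]
      out[[i]] <- if (zero_phase) signal::filtfilt(bf, x)
                  else as.numeric(signal::filter(bf, x))
    }
    if (needs_decim)
      out[[i]] <- out[[i]][seq(1L, length(out[[i]]), by = ratio)]
  }
  multichannel_recording(out, fs = target_fs,
                         channel_labels = rec$channel_labels,
                         organ_map = rec$organ_map,
                         start_time = rec$start_time)
}
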