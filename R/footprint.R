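#' Electrical footprint of a single unit
#'
#' The spike-triggered average extracellular waveform of one neuron across
#' all electrodes that sense it (channels x samples, uV), together with the
#' channel coordinates and sampling rate. The peak channel is the electrode
#' attaining the largest absolute trough amplitude.
#'
#' @param unit_id integer unit label.
#' @param waveform channels x samples numeric matrix (uV).
#' @param channels data.frame with `electrode_id`, `x`, `y` (um), one row per
#'   waveform row.
#' @param fs sampling rate (Hz).
#' @param n_spikes_averaged number of spikes averaged (NA if synthetic).
#' @param t0_ms time of the first sample relative to the trigger trough (ms,
#'   negative = before).
#' @return list of class `electrical_footprint`; `$peak_channel` is the
#'   0-based row index (into `channels`) of the peak channel.
#' @export
electrical_footprint <- function(unit_id, waveform, channels, fs,
                                 n_spikes_averaged = NA_integer_,
                                 t0_ms = NA_real_) {
  if (!is.matrix(waveform)) stop("`waveform` must be a channels x samples matrix")
  if (nrow(waveform) != nrow(channels))
    stop("`channels` must have one row per waveform channel")
  assert_scalar_num(fs, "fs", positive = TRUE)
  depth <- trough_depth(waveform)
  structure(list(
    unit_id = as.integer(unit_id),
    waveform = waveform,
    channels = channels,
    fs = fs,
    peak_channel = which.max(depth) - 1L,
    n_spikes_averaged = n_spikes_averaged,
    t0_ms = t0_ms
  ), class = "electrical_footprint")
}

#' @export
print.electrical_footprint <- function(x, ...) {
  cat(sprintf(
    "<electrical_footprint> unit %d: %d channels x %d samples @ %g Hz, peak channel %d\n",
    x$unit_id, nrow(x$waveform), ncol(x$waveform), x$fs, x$peak_channel))
  invisible(x)
}

# Peak-channel waveform (numeric vector) and its trough depth (uV).
peak_waveform <- function(ef) ef$waveform[ef$peak_channel + 1L, ]
peak_amplitude <- function(ef) -min(peak_waveform(ef))
peak_position <- function(ef) {
  unlist(ef$channels[ef$peak_channel + 1L, c("x", "y")])
}

#' Spike-triggered electrical footprint
#'
#' Averages trace windows aligned on the spikes of one unit — the standard
#' way an electrical footprint is obtained from a multi-channel recording.
#' Only spikes whose full window lies inside the trace are used; units with
#' fewer than `min_spikes` usable spikes are skipped (returns NULL with a
#' warning) since their averages are too noisy to interpret.
#'
#' @param traces channels x samples numeric matrix (uV).
#' @param spike_times spike times of one unit (s).
#' @param fs sampling rate of `traces` (Hz).
#' @param channels data.frame (`electrode_id`, `x`, `y`) describing trace rows.
#' @param pre_ms,post_ms window before/after each spike time (ms).
#' @param min_spikes minimum usable spikes (default 30).
#' @param unit_id unit label stored in the result.
#' @return an [electrical_footprint()] or NULL.
#' @export
spike_triggered_ef <- function(traces, spike_times, fs, channels,
                               pre_ms = 2, post_ms = 3, min_spikes = 30,
                               unit_id = 1L) {
  pre_n <- round(pre_ms / 1000 * fs)
  post_n <- round(post_ms / 1000 * fs)
  centers <- round(spike_times * fs) + 1L
  ok <- centers - pre_n >= 1L & centers + post_n <= ncol(traces)
  centers <- centers[ok]
  if (length(centers) < min_spikes) {
    warning(sprintf("unit %s: only %d usable spikes (< %d), skipped",
                    unit_id, length(centers), min_spikes))
    return(NULL)
  }
  n_samp <- pre_n + post_n + 1L
  acc <- matrix(0, nrow = nrow(traces), ncol = n_samp)
  for (c0 in centers)
    acc <- acc + traces[, (c0 - pre_n):(c0 + post_n), drop = FALSE]
  electrical_footprint(unit_id, acc / length(centers), channels, fs,
                       n_spikes_averaged = length(centers), t0_ms = -pre_ms)
}
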