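#' Spike table
#'
#' The substrate for all spike-train operations: one row per spike with a
#' dense integer unit label and a spike time in seconds. Rows are kept sorted
#' by unit and, within unit, by time.
#'
#' @param unit_id integer unit labels (one per spike).
#' @param t spike times in seconds; must be non-negative.
#' @param amplitude optional per-spike amplitude in microvolts.
#' @return data.frame of class `spike_table` with columns `unit_id`, `t`
#'   (and `amplitude` if supplied).
#' @export
spike_table <- function(unit_id = integer(), t = numeric(), amplitude = NULL) {
  if (length(unit_id) != length(t))
    stop("`unit_id` and `t` must have the same length")
  if (length(t) && any(!is.finite(t))) stop("spike times must be finite")
  if (length(t) && any(t < 0)) stop("spike times must be non-negative")
  df <- data.frame(unit_id = as.integer(unit_id), t = as.numeric(t))
  if (!is.null(amplitude)) {
    if (length(amplitude) != length(t))
      stop("`amplitude` must match the number of spikes")
    df$amplitude <- as.numeric(amplitude)
  }
  o <- order(df$unit_id, df$t)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_table", "data.frame")
  df
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("<spike_table> %d spikes, %d units\n",
              nrow(x), length(unique(x$unit_id))))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Spike times of one unit
#' @param spikes a [spike_table()].
#' @param unit unit id.
#' @return numeric vector of spike times (s), sorted.
#' @export
unit_spikes <- function(spikes, unit) {
  sort(spikes$t[spikes$unit_id == unit])
}

#' Per-unit firing rates
#'
#' @param spikes a [spike_table()].
#' @param duration recording duration in seconds.
#' @param units optional vector of unit ids to report (defaults to the units
#'   present); units with no spikes get rate 0.
#' @return data.frame with `unit_id`, `n_spikes`, `rate_hz`.
#' @export
firing_rates <- function(spikes, duration, units = NULL) {
  assert_scalar_num(duration, "duration", positive = TRUE)
  units <- units %||% sort(unique(spikes$unit_id))
  n <- vapply(units, function(u) sum(spikes$unit_id == u), integer(1))
  data.frame(unit_id = as.integer(units), n_spikes = n, rate_hz = n / duration)
}
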