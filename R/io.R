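# Unit conventions used by every on-disk artifact: times in seconds
# (float64), coordinates in micrometers, amplitudes in microvolts, 0-based
# electrode/channel indexing, end-exclusive intervals.

#' Read a spike table from CSV
#'
#' Expects a header `unit_id,t_s` (optionally `amplitude_uv`). Malformed
#' rows are reported with their line numbers; negative times are rejected.
#' The returned table is sorted by unit and time.
#'
#' @param path CSV file path.
#' @return a [spike_table()].
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "t_s") %in% names(df)))
    stop("spike table must have header columns `unit_id,t_s`: ", path)
  uid <- suppressWarnings(as.numeric(df$unit_id))
  tt <- suppressWarnings(as.numeric(df$t_s))
  bad <- which(!is.finite(uid) | !is.finite(tt) | uid != round(uid))
  if (length(bad))
    stop("malformed spike table rows (file lines ",
         paste(bad + 1L, collapse = ", "), ") in ", path)
  neg <- which(tt < 0)
  if (length(neg))
    stop("negative spike times (file lines ",
         paste(neg + 1L, collapse = ", "), ") in ", path)
  amp <- if ("amplitude_uv" %in% names(df)) as.numeric(df$amplitude_uv)
  spike_table(as.integer(uid), tt, amplitude = amp)
}

#' Write a spike table to CSV
#' @param spikes a [spike_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  df <- data.frame(unit_id = spikes$unit_id,
                   t_s = format(spikes$t, digits = 17, scientific = FALSE,
                                trim = TRUE))
  if (!is.null(spikes$amplitude))
    df$amplitude_uv <- format(spikes$amplitude, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an electrode map from CSV
#'
#' Expects a header `electrode_id,x_um,y_um`.
#'
#' @param path CSV file path.
#' @return data.frame of class `electrode_array` (pitch attribute inferred
#'   as the minimal inter-electrode distance).
#' @export
read_electrode_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("electrode_id", "x_um", "y_um") %in% names(df)))
    stop("electrode map must have header `electrode_id,x_um,y_um`: ", path)
  if (anyDuplicated(df[, c("x_um", "y_um")]))
    stop("electrode positions must be unique: ", path)
  arr <- data.frame(electrode_id = as.integer(df$electrode_id),
                    x = as.numeric(df$x_um), y = as.numeric(df$y_um))
  pitch <- if (nrow(arr) > 1)
    min(stats::dist(arr[, c("x", "y")])) else NA_real_
  attr(arr, "pitch") <- pitch
  class(arr) <- c("electrode_array", "data.frame")
  arr
}

#' Write an electrode map to CSV
#' @param array an [electrode_array()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_electrode_map <- function(array, path) {
  utils::write.csv(data.frame(electrode_id = array$electrode_id,
                              x_um = array$x, y_um = array$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of electrical footprints to a plain-text store
#'
#' The store is a directory holding, per unit, a full-precision waveform CSV
#' (`ef_<unit>_waveform.csv`, channels x samples) and a channel-coordinate
#' CSV (`ef_<unit>_channels.csv`), plus a `meta.json` with the sampling rate
#' and unit index. Values round-trip exactly (17 significant digits).
#'
#' @param efs list of [electrical_footprint()]s.
#' @param path store directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_ef_store <- function(efs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(efs, function(e) e$unit_id, integer(1))
  fs <- vapply(efs, function(e) e$fs, numeric(1))
  meta <- list(format = "orgephys-ef-store-v1", fs_hz = fs[1],
               unit_ids = sort(ids))
  if (length(unique(fs)) > 1) stop("all footprints must share one fs")
  for (e in efs) {
    wf <- format(e$waveform, digits = 17, trim = TRUE)
    utils::write.table(wf, file.path(path,
                                     sprintf("ef_%d_waveform.csv", e$unit_id)),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.csv(data.frame(electrode_id = e$channels$electrode_id,
                                x_um = e$channels$x, y_um = e$channels$y),
                     file.path(path, sprintf("ef_%d_channels.csv", e$unit_id)),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an electrical-footprint store
#'
#' @param path store directory written by [write_ef_store()].
#' @return list of [electrical_footprint()]s in ascending `unit_id` order.
#' @export
read_ef_store <- function(path) {
  mfile <- file.path(path, "meta.json")
  if (!file.exists(mfile)) stop("not an EF store (missing meta.json): ", path)
  meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("EF store missing `fs_hz` attribute: ", path)
  ids <- sort(as.integer(meta$unit_ids))
  lapply(ids, function(u) {
    wf <- as.matrix(utils::read.csv(
      file.path(path, sprintf("ef_%d_waveform.csv", u)), header = FALSE))
    dimnames(wf) <- NULL
    ch <- utils::read.csv(file.path(path, sprintf("ef_%d_channels.csv", u)))
    electrical_footprint(u, wf,
                         data.frame(electrode_id = as.integer(ch$electrode_id),
                                    x = ch$x_um, y = ch$y_um),
                         fs = meta$fs_hz)
  })
}

#' Write burst events to CSV
#' @param bursts a `burst_events` data.frame from [detect_bursts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_burst_table <- function(bursts, path) {
  utils::write.csv(data.frame(onset_s = bursts$onset,
                              offset_s = bursts$offset,
                              peak_s = bursts$peak_time,
                              duration_s = bursts$duration),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write velocity estimates to CSV
#' @param estimates list of `velocity_estimate`s from [fit_velocity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity_table <- function(estimates, path) {
  estimates <- Filter(Negate(is.null), estimates)
  df <- do.call(rbind, lapply(estimates, function(v)
    data.frame(unit_id = v$unit_id, velocity_mps = v$velocity_mps,
               r2 = v$r2, n_segments = v$n_segments,
               traced_um = v$traced_um, included = v$included)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
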