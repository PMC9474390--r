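#' Default pipeline configuration
#'
#' All numeric analysis parameters with their standard values, grouped by
#' stage. [read_config()] validates user files against this structure and
#' rejects unknown keys.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    qc = list(
      max_violation_fraction = 0.05,
      refractory_ms = 1,
      duplicate_window_ms = 0.5,
      duplicate_radius_um = 100,
      min_spikes_per_unit = 50,
      sta_min_spikes = 30,
      ef_pre_ms = 2,
      ef_post_ms = 3
    ),
    bursts = list(
      bin_s = 0.1,
      smooth_sd_s = 0.1,
      threshold_sd = 2,
      min_duration_s = 0.5
    ),
    lfp = list(
      fs_target_hz = 1000,
      welch_segment_s = 1,
      welch_overlap = 0.5,
      fit_range_hz = c(2, 100),
      min_peak_power = 0.3,
      max_n_peaks = 6,
      peak_width_limits_hz = c(1, 12)
    ),
    clustering = list(
      resolution = 1.5,
      n_neighbors = 15,
      sweep_iterations = 20,
      hp_hz = 150
    ),
    velocity = list(
      max_edge_um = 60,
      r2_min = 0.8,
      interp = "parabolic"
    ),
    connectivity = list(
      ccg_bin_ms = 1,
      ccg_lag_ms = 50,
      ccg_conv_sd_ms = 10,
      ccg_window_ms = 5,
      alpha = 0.001,
      te_k_target = 1,
      te_l_source = 4,
      te_delay_bins = 1,
      te_n_surrogates = 50,
      te_jitter_bins = 7,
      te_scales_ms = c(1, 1.6, 3.5, 7.4, 16, 35, 74, 160)
    ),
    tracking = list(
      sim_threshold = 0.85
    )
  )
}

# Recursively merge user values into defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key `", full, "` must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Values omitted from the file keep their defaults; unknown keys are an
#' error, catching typos before a run.
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(default_config())
  merge_config(default_config(), user)
}

#' Write a pipeline configuration to YAML
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
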