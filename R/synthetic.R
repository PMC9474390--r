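#' Ground-truth parameter set for synthetic HD-MEA data
#'
#' Collects the generative parameters of the synthetic recording: sparse
#' background firing, rare long population bursts carrying an oscillatory
#' rate modulation, axonal conduction velocity, and a sparse directed
#' synaptic graph with millisecond transmission delays. Defaults are the
#' emergent statistics of developing organoid slice cultures on HD-MEAs:
#' 0.38 Hz background unit rate, 0.01 Hz burst rate, 4.05 s burst duration,
#' 14.33 Hz intra-burst oscillation, 0.41 m/s conduction velocity.
#'
#' @param unit_rate background firing rate per unit (Hz).
#' @param burst_rate Poisson rate of network-burst initiation (Hz).
#' @param burst_duration burst length (s).
#' @param burst_osc_freq oscillatory modulation frequency inside bursts (Hz).
#' @param burst_gain peak rate multiplier inside a burst (unitless).
#' @param burst_ramp raised-cosine onset/offset ramp length (s).
#' @param osc_depth relative depth of the sinusoidal rate modulation in
#'   bursts (0..1).
#' @param true_velocity axonal conduction velocity (m/s).
#' @param syn_graph directed synaptic edge list: data.frame with columns
#'   `src`, `tgt` (unit ids), `delay_ms` (>= 1 ms) and `prob` (transmission
#'   probability in 0..1), or NULL for no connections.
#' @param seed root seed; every random draw flows from it via named
#'   substreams (per-unit, per-edge), so adding units does not perturb
#'   existing ones.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(unit_rate = 0.38, burst_rate = 0.01,
                         burst_duration = 4.05, burst_osc_freq = 14.33,
                         burst_gain = 20, burst_ramp = 0.5, osc_depth = 0.5,
                         true_velocity = 0.41, syn_graph = NULL, seed = 1L) {
  for (nm in c("burst_duration", "burst_osc_freq", "burst_gain"))
    assert_scalar_num(get(nm), nm, positive = TRUE)
  if (unit_rate < 0 || burst_rate < 0) stop("rates must be non-negative")
  if (osc_depth < 0 || osc_depth > 1) stop("`osc_depth` must be in [0, 1]")
  if (!is.null(syn_graph)) {
    need <- c("src", "tgt", "delay_ms", "prob")
    if (!all(need %in% names(syn_graph)))
      stop("`syn_graph` needs columns src, tgt, delay_ms, prob")
    if (any(syn_graph$delay_ms < 1))
      stop("synaptic delays must be >= 1 ms")
    if (any(syn_graph$prob < 0 | syn_graph$prob > 1))
      stop("transmission probabilities must be in [0, 1]")
  }
  structure(list(
    unit_rate = unit_rate, burst_rate = burst_rate,
    burst_duration = burst_duration, burst_osc_freq = burst_osc_freq,
    burst_gain = burst_gain, burst_ramp = burst_ramp, osc_depth = osc_depth,
    true_velocity = true_velocity, syn_graph = syn_graph,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

# Raised-cosine burst envelope on [0, duration]: 0 -> 1 over `ramp` seconds,
# plateau, 1 -> 0 over the final `ramp` seconds. Vectorized over tau.
burst_envelope <- function(tau, duration, ramp) {
  env <- numeric(length(tau))
  inside <- tau >= 0 & tau <= duration
  env[inside] <- 1
  r <- inside & tau < ramp
  env[r] <- 0.5 * (1 - cos(pi * tau[r] / ramp))
  r <- inside & tau > duration - ramp
  env[r] <- 0.5 * (1 - cos(pi * (duration - tau[r]) / ramp))
  env
}

# Instantaneous rate multiplier at time t for bursts with given onsets.
burst_multiplier <- function(t, onsets, gt) {
  m <- rep(1, length(t))
  for (on in onsets) {
    tau <- t - on
    env <- burst_envelope(tau, gt$burst_duration, gt$burst_ramp)
    osc <- 1 + gt$osc_depth * sin(2 * pi * gt$burst_osc_freq * tau)
    m <- m + (gt$burst_gain - 1) * env * osc
  }
  m
}

#' Simulate a network of spiking units with population bursts
#'
#' Background activity is homogeneous Poisson per unit at `gt$unit_rate`.
#' Network bursts arrive as a Poisson process at `gt$burst_rate`; within a
#' burst each unit's rate is multiplied by `gt$burst_gain` under a
#' raised-cosine envelope, sinusoidally modulated at `gt$burst_osc_freq`.
#' Each ground-truth synaptic edge (i -> j, delay d, probability p)
#' independently copies each source spike to the target at `t + d` with
#' probability p. Fully reproducible given `gt$seed`; per-unit and per-edge
#' draws use independent substreams.
#'
#' @param gt a [ground_truth()] object.
#' @param n_units number of units.
#' @param duration recording length in seconds.
#' @return list of class `spike_sim` with elements `spikes` (a
#'   [spike_table()]; unit ids 1..n_units), `bursts` (data.frame of true
#'   burst `onset`/`offset` in s), `gt`, `n_units`, `duration`.
#' @export
simulate_spike_network <- function(gt, n_units, duration) {
  stopifnot(inherits(gt, "ground_truth"))
  assert_scalar_num(duration, "duration", positive = TRUE)
  n_units <- as.integer(n_units)

  # substream 0: burst initiation times
  set.seed(substream_seed(gt$seed, 0L))
  n_bursts <- stats::rpois(1, gt$burst_rate * duration)
  onsets <- sort(stats::runif(n_bursts, 0, max(duration - gt$burst_duration, 0)))
  bursts <- data.frame(onset = onsets, offset = onsets + gt$burst_duration)

  # per-unit substreams 1..n_units: background + burst excess via thinning
  extra_max <- gt$unit_rate * (gt$burst_gain - 1) * (1 + gt$osc_depth)
  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    set.seed(substream_seed(gt$seed, u))
    n_bg <- stats::rpois(1, gt$unit_rate * duration)
    t_bg <- stats::runif(n_bg, 0, duration)
    t_burst <- numeric(0)
    if (n_bursts > 0 && extra_max > 0) {
      for (on in onsets) {
        n_cand <- stats::rpois(1, extra_max * gt$burst_duration)
        tc <- stats::runif(n_cand, on, on + gt$burst_duration)
        tau <- tc - on
        env <- burst_envelope(tau, gt$burst_duration, gt$burst_ramp)
        osc <- 1 + gt$osc_depth * sin(2 * pi * gt$burst_osc_freq * tau)
        rate <- gt$unit_rate * (gt$burst_gain - 1) * env * osc
        keep <- stats::runif(n_cand) < rate / (extra_max * gt$unit_rate) *
          gt$unit_rate
        t_burst <- c(t_burst, tc[keep])
      }
    }
    spikes[[u]] <- sort(c(t_bg, t_burst))
  }

  # per-edge substreams: synaptic transmission
  if (!is.null(gt$syn_graph) && nrow(gt$syn_graph)) {
    added <- vector("list", nrow(gt$syn_graph))
    for (e in seq_len(nrow(gt$syn_graph))) {
      ed <- gt$syn_graph[e, ]
      set.seed(substream_seed(gt$seed, n_units + e))
      src_t <- spikes[[ed$src]]
      fire <- stats::runif(length(src_t)) < ed$prob
      tt <- src_t[fire] + ed$delay_ms / 1000
      added[[e]] <- list(tgt = ed$tgt, t = tt[tt <= duration])
    }
    for (a in added)
      spikes[[a$tgt]] <- sort(c(spikes[[a$tgt]], a$t))
  }

  n_per <- lengths(spikes)
  tab <- spike_table(rep.int(seq_len(n_units), n_per), unlist(spikes))
  structure(list(spikes = tab, bursts = bursts, gt = gt,
                 n_units = n_units, duration = duration),
            class = "spike_sim")
}

#' @export
print.spike_sim <- function(x, ...) {
  cat(sprintf("<spike_sim> %d units, %.6g s, %d spikes, %d bursts\n",
              x$n_units, x$duration, nrow(x$spikes), nrow(x$bursts)))
  invisible(x)
}

# Biphasic extracellular spike template (negative trough then positive
# rebound, ~1.5 ms total), unit trough depth. `tau` in seconds rel. trough.
spike_template <- function(tau) {
  -exp(-0.5 * (tau / 1.0e-4)^2) + 0.4 * exp(-0.5 * ((tau - 4e-4) / 1.8e-4)^2)
}

# Triphasic axonal variant: small positive pre-peak before the trough.
spike_template_triphasic <- function(tau) {
  0.3 * exp(-0.5 * ((tau + 3e-4) / 1.5e-4)^2) + spike_template(tau)
}

#' Simulate a propagating electrical footprint
#'
#' Places a spike-like waveform on each electrode of an axonal path. The
#' trough on path electrode k lags the path origin by `cumdist(k)/velocity`
#' (plus optional Gaussian latency jitter), and its amplitude decays
#' exponentially with cumulative distance. Off-path electrodes carry noise
#' only. The path origin is the peak channel by construction.
#'
#' @param array an [electrode_array()].
#' @param axon_path ordered electrode ids of the axonal path; consecutive
#'   electrodes should be <= 60 um apart for downstream flow-graph tracing.
#' @param velocity conduction velocity in m/s (> 0).
#' @param peak_amp trough amplitude at the path origin (uV).
#' @param decay_const exponential amplitude decay constant (um).
#' @param noise_sd additive white noise SD (uV).
#' @param fs sampling rate (Hz).
#' @param latency_jitter_sd Gaussian jitter SD added to each electrode's true
#'   latency (s); 0 for noise-free latencies.
#' @param extra_channels electrode ids carrying noise only.
#' @param pre_ms,post_ms waveform window before/after the origin trough (ms).
#' @param seed optional seed for noise and jitter.
#' @return an `electrical_footprint` (see [spike_triggered_ef()]) with the
#'   true per-electrode latencies attached as attribute `true_latency_s`.
#' @export
simulate_ef <- function(array, axon_path, velocity, peak_amp = 100,
                        decay_const = 100, noise_sd = 1, fs = 20000,
                        latency_jitter_sd = 0, extra_channels = integer(0),
                        pre_ms = 2, post_ms = 3, seed = NULL) {
  assert_scalar_num(velocity, "velocity", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  xy <- array_coords(array, axon_path)
  step <- sqrt(diff(xy[, "x"])^2 + diff(xy[, "y"])^2)
  cumdist <- c(0, cumsum(step))                       # um
  lat <- cumdist / (velocity * 1e6)                   # s
  if (latency_jitter_sd > 0)
    lat <- lat + stats::rnorm(length(lat), 0, latency_jitter_sd)
  amp <- peak_amp * exp(-cumdist / decay_const)

  channels <- c(axon_path, extra_channels)
  coords <- array_coords(array, channels)
  n_samp <- round((pre_ms + post_ms) / 1000 * fs) + 1L
  tgrid <- (seq_len(n_samp) - 1) / fs - pre_ms / 1000 # s rel. origin trough
  wf <- matrix(0, nrow = length(channels), ncol = n_samp)
  for (k in seq_along(axon_path))
    wf[k, ] <- amp[k] * spike_template(tgrid - lat[k])
  if (noise_sd > 0)
    wf <- wf + matrix(stats::rnorm(length(wf), 0, noise_sd), nrow = nrow(wf))

  ef <- electrical_footprint(
    unit_id = 1L, waveform = wf,
    channels = data.frame(electrode_id = channels,
                          x = coords[, "x"], y = coords[, "y"]),
    fs = fs, n_spikes_averaged = NA_integer_, t0_ms = -pre_ms
  )
  attr(ef, "true_latency_s") <- lat
  attr(ef, "true_path") <- axon_path
  ef
}

#' Random axonal path on the electrode grid
#'
#' Draws a straight path of `n` electrodes starting at a random grid position
#' in one of eight lattice directions (step <= one diagonal, i.e. <= 25 um at
#' 17.5 um pitch), for use with [simulate_ef()].
#'
#' @param array an [electrode_array()].
#' @param n path length in electrodes.
#' @return integer vector of electrode ids.
#' @export
random_axon_path <- function(array, n = 12) {
  d <- attr(array, "dims")
  dirs <- cbind(dr = c(0, 0, 1, -1, 1, 1, -1, -1),
                dc = c(1, -1, 0, 0, 1, -1, 1, -1))
  repeat {
    dir <- dirs[sample.int(8, 1), ]
    r0 <- sample.int(d[["rows"]], 1) - 1L
    c0 <- sample.int(d[["cols"]], 1) - 1L
    r <- r0 + dir[["dr"]] * (seq_len(n) - 1L)
    c <- c0 + dir[["dc"]] * (seq_len(n) - 1L)
    if (all(r >= 0 & r < d[["rows"]] & c >= 0 & c < d[["cols"]]))
      return(as.integer(r * d[["cols"]] + c))
  }
}

#' Simulate burst-gated local field potentials
#'
#' Generates, for each burst window and channel group, a 1/f^exponent
#' aperiodic background plus (optionally) a sinusoid at `osc_freq` — the
#' oscillatory component network bursts carry. Signals are generated only
#' inside burst windows, which is all the burst-period spectral analysis
#' consumes.
#'
#' @param osc_freq oscillation frequency (Hz); requires `fs >= 2 * osc_freq`.
#' @param burst_windows data.frame with `onset`, `offset` (s).
#' @param fs sampling rate (Hz); the LFP convention is 1 kHz.
#' @param aperiodic_exponent exponent of the 1/f^x background power spectrum.
#' @param osc_amp sinusoid amplitude relative to the background SD (0
#'   disables the oscillation).
#' @param n_groups number of electrode channel groups.
#' @param seed optional seed.
#' @return list of class `burst_lfp`: `fs`, `windows`, `n_groups`, and
#'   `segments` (one groups x samples matrix per window).
#' @export
simulate_burst_lfp <- function(osc_freq, burst_windows, fs = 1000,
                               aperiodic_exponent = 2, osc_amp = 1.5,
                               n_groups = 4, seed = NULL) {
  assert_scalar_num(osc_freq, "osc_freq", positive = TRUE)
  if (fs < 2 * osc_freq) stop("`fs` must be at least 2 * osc_freq")
  if (!is.null(seed)) set.seed(seed)
  segs <- vector("list", nrow(burst_windows))
  for (w in seq_len(nrow(burst_windows))) {
    n <- round((burst_windows$offset[w] - burst_windows$onset[w]) * fs)
    m <- matrix(0, nrow = n_groups, ncol = n)
    for (g in seq_len(n_groups)) {
      bg <- one_over_f_noise(n, fs, aperiodic_exponent)
      x <- bg / stats::sd(bg)
      if (osc_amp > 0) {
        ph <- stats::runif(1, 0, 2 * pi)
        x <- x + osc_amp * sin(2 * pi * osc_freq * (seq_len(n) - 1) / fs + ph)
      }
      m[g, ] <- x
    }
    segs[[w]] <- m
  }
  structure(list(fs = fs, windows = burst_windows, n_groups = n_groups,
                 segments = segs),
            class = "burst_lfp")
}

# Gaussian noise spectrally shaped to power ~ 1/f^exponent (FFT method).
one_over_f_noise <- function(n, fs, exponent) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]                 # two-sided frequencies
  scale <- c(0, f[-1]^(-exponent / 2))                # kill DC
  Re(stats::fft(sp * scale, inverse = TRUE)) / n
}
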