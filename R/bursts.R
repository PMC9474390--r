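#' Detect network bursts on multi-unit activity
#'
#' Pools all spikes into a binned (default 0.1 s) multi-unit activity (MUA)
#' vector, smooths it with a Gaussian kernel, normalizes it to its maximum,
#' and flags bursts as peaks exceeding `mean + 2 SD` of the normalized
#' vector. Each peak is extended to the nearest crossings of the lower
#' threshold (the mean of the normalized vector), which define burst onset
#' and offset; crossing times are linearly interpolated between bin centers.
#' Bursts separated by less than one bin are merged. Candidate events whose
#' MUA stays above the detection threshold for less than `min_duration` are
#' discarded: genuine network bursts exceed the high threshold for seconds,
#' while chance excursions of stationary activity (about 2% of bins under
#' the 2 SD rule) fall back within a bin or two. The mean+2SD rule
#' is applied to the normalized vector, so detection is invariant to uniform
#' rescaling of the MUA.
#'
#' @param spikes a [spike_table()] (all units pooled).
#' @param duration recording duration (s); defaults to the last spike time.
#' @param bin MUA bin width (s), default 0.1.
#' @param smooth_sd Gaussian smoothing SD (s), default 0.1 (one bin): enough to
#'   suppress bin noise while keeping onset/offset crossings sharp; wider
#'   kernels systematically inflate measured durations because a smoothed
#'   edge crosses the low mean-level threshold well outside the true edge.
#' @param min_duration minimum time above the detection threshold (s),
#'   default 0.5.
#' @param n_sd threshold height above the mean, in SDs (default 2).
#' @return data.frame of class `burst_events` with columns `onset`, `offset`,
#'   `peak_time`, `duration` (s), and attributes `rate_hz` (bursts/s) and
#'   `duration_s` (recording length).
#' @export
detect_bursts <- function(spikes, duration = NULL, bin = 0.1,
                          smooth_sd = 0.1, min_duration = 0.5, n_sd = 2) {
  duration <- duration %||% (if (nrow(spikes)) max(spikes$t) else 0)
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      peak_time = numeric(), duration = numeric())
  n_bins <- floor(duration / bin)
  if (n_bins <= 10L || !nrow(spikes)) {
    if (n_bins <= 10L && duration > 0)
      warning("recording shorter than 10 MUA bins; no burst detection")
    return(structure(empty, class = c("burst_events", "data.frame"),
                     rate_hz = 0, duration_s = duration))
  }
  edges <- seq(0, n_bins * bin, by = bin)
  counts <- graphics::hist(spikes$t[spikes$t < n_bins * bin], breaks = edges,
                           plot = FALSE)$counts
  sm <- smooth_convolve(counts, gaussian_kernel(smooth_sd / bin))
  if (max(sm) <= 0)
    return(structure(empty, class = c("burst_events", "data.frame"),
                     rate_hz = 0, duration_s = duration))
  mua <- sm / max(sm)
  mu <- mean(mua)
  thr <- mu + n_sd * stats::sd(mua)
  centers <- edges[-length(edges)] + bin / 2

  above <- mua > thr
  if (!any(above))
    return(structure(empty, class = c("burst_events", "data.frame"),
                     rate_hz = 0, duration_s = duration))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hi <- which(runs$values)

  cross_left <- function(i) {           # walk left to the mean crossing
    while (i > 1 && mua[i - 1] > mu) i <- i - 1
    if (i == 1) return(centers[1])
    # interpolate between bins i-1 (below) and i (above)
    centers[i - 1] + bin * (mu - mua[i - 1]) / (mua[i] - mua[i - 1])
  }
  cross_right <- function(i) {
    n <- length(mua)
    while (i < n && mua[i + 1] > mu) i <- i + 1
    if (i == n) return(centers[n])
    centers[i] + bin * (mua[i] - mu) / (mua[i] - mua[i + 1])
  }

  ev <- data.frame(onset = numeric(), offset = numeric(),
                   peak_time = numeric())
  for (r in hi) {
    s <- starts[r]; e <- ends[r]
    if ((e - s + 1L) * bin < min_duration) next      # chance excursion
    on <- cross_left(s); off <- cross_right(e)
    pk <- centers[s - 1L + which.max(mua[s:e])]
    ev <- rbind(ev, data.frame(onset = on, offset = off, peak_time = pk))
  }
  if (!nrow(ev))
    return(structure(empty, class = c("burst_events", "data.frame"),
                     rate_hz = 0, duration_s = duration))
  # merge events whose gap is below one bin (also handles shared extensions)
  ev <- ev[order(ev$onset), , drop = FALSE]
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (k in 2:nrow(ev)) {
      last <- nrow(merged)
      if (ev$onset[k] - merged$offset[last] < bin) {
        merged$offset[last] <- max(merged$offset[last], ev$offset[k])
        if (mua[which.min(abs(centers - ev$peak_time[k]))] >
            mua[which.min(abs(centers - merged$peak_time[last]))])
          merged$peak_time[last] <- ev$peak_time[k]
      } else {
        merged <- rbind(merged, ev[k, ])
      }
    }
  }
  merged$duration <- merged$offset - merged$onset
  rownames(merged) <- NULL
  structure(merged[, c("onset", "offset", "peak_time", "duration")],
            class = c("burst_events", "data.frame"),
            rate_hz = nrow(merged) / duration, duration_s = duration)
}

#' @export
print.burst_events <- function(x, ...) {
  cat(sprintf("<burst_events> %d bursts in %.6g s (rate %.4g Hz)\n",
              nrow(x), attr(x, "duration_s"), attr(x, "rate_hz")))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Burst rate in Hz
#' @param bursts a `burst_events` object from [detect_bursts()].
#' @return bursts per second.
#' @export
burst_rate <- function(bursts) attr(bursts, "rate_hz")
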