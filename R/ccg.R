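#' Spike-train cross-correlogram
#'
#' Counts target spikes at each lag relative to each source spike, in 1 ms
#' bins over a +/- 50 ms window by default. Bins are indexed by their left
#' edge: bin `b` collects lags in `[b, b + bin_ms)` ms, so the two center
#' bins (left edges -1 and 0) hold the sub-millisecond lags.
#'
#' @param source,target spike time vectors (s), sorted.
#' @param bin_ms bin width (ms), default 1.
#' @param lag_ms half-window (ms), default 50.
#' @return numeric vector of counts with names giving bin left edges (ms).
#' @export
ccg <- function(source, target, bin_ms = 1, lag_ms = 50) {
  if (!length(source) || !length(target))
    stop("both spike trains must be non-empty")
  source <- sort(source); target <- sort(target)
  w <- lag_ms / 1000
  lo <- findInterval(source - w, target)
  hi <- findInterval(source + w - 1e-12, target)
  nper <- hi - lo
  n_bins <- as.integer(2 * lag_ms / bin_ms)
  counts <- numeric(n_bins)
  if (sum(nper) > 0) {
    idx <- sequence(nper) + rep.int(lo, nper)
    dt <- target[idx] - rep.int(source, nper)
    b <- floor(dt * 1000 / bin_ms) + n_bins %/% 2 + 1L
    ok <- b >= 1L & b <= n_bins
    counts <- tabulate(b[ok], n_bins)
  }
  names(counts) <- seq(-lag_ms, lag_ms - bin_ms, by = bin_ms)
  counts
}

#' Significance of a cross-correlogram peak
#'
#' Compares the tallest CCG bin inside the monosynaptic window (default
#' +/- 5 ms) to a slow baseline obtained by convolving the full CCG with a
#' Gaussian kernel (default SD 10 ms, truncated at 3 SD). The probability of
#' the observed peak count given the baseline rate at the peak bin is the
#' upper tail of a Poisson distribution, `P(X >= peak | lambda)`, compared
#' to `alpha`. CCGs whose in-window maximum falls in a sub-millisecond bin
#' (|lag| < 1 ms) are excluded outright: such latencies are shorter than
#' synaptic transmission and typically reflect duplicate or split units.
#'
#' @param counts CCG counts from [ccg()] (named by bin left edge, ms).
#' @param bin_ms CCG bin width (ms).
#' @param conv_sd_ms Gaussian baseline kernel SD (ms), default 10.
#' @param window_ms monosynaptic search half-window (ms), default 5.
#' @param alpha significance level, default 0.001.
#' @return list of class `ccg_result`: `peak_count`, `peak_lag_ms` (bin
#'   center), `baseline` (lambda at the peak bin), `p`, `significant`,
#'   `excluded` (sub-millisecond peak), `degenerate` (zero-baseline flag).
#' @export
ccg_significance <- function(counts, bin_ms = 1, conv_sd_ms = 10,
                             window_ms = 5, alpha = 0.001) {
  edges <- as.numeric(names(counts))
  if (is.null(edges) || anyNA(edges))
    stop("`counts` must be named by bin left edges (use ccg())")
  baseline <- smooth_convolve(counts, gaussian_kernel(conv_sd_ms / bin_ms,
                                                      trunc_sd = 3))
  inwin <- which(edges >= -window_ms & edges < window_ms)
  i_max <- inwin[which.max(counts[inwin])]
  center <- abs(edges[i_max] + bin_ms / 2) < 1      # |lag| < 1 ms bins
  if (center) {
    return(structure(list(peak_count = counts[[i_max]],
                          peak_lag_ms = edges[i_max] + bin_ms / 2,
                          baseline = baseline[i_max], p = NA_real_,
                          significant = FALSE, excluded = TRUE,
                          degenerate = FALSE),
                     class = "ccg_result"))
  }
  valid <- inwin[abs(edges[inwin] + bin_ms / 2) >= 1]
  i_pk <- valid[which.max(counts[valid])]
  lam <- baseline[i_pk]
  degenerate <- FALSE
  if (lam <= 0) {
    if (counts[[i_pk]] > 0) { lam <- 1e-6; degenerate <- TRUE }
    else lam <- 1e-6
  }
  p <- stats::ppois(counts[[i_pk]] - 1, lambda = lam, lower.tail = FALSE)
  structure(list(peak_count = counts[[i_pk]],
                 peak_lag_ms = edges[i_pk] + bin_ms / 2,
                 baseline = lam, p = p,
                 significant = p < alpha, excluded = FALSE,
                 degenerate = degenerate),
            class = "ccg_result")
}

#' CCG functional connectivity over all unit pairs
#'
#' Computes a cross-correlogram for every unit pair and keeps significant
#' peaks; the direction of each detected connection follows the sign of the
#' peak lag (a peak at positive lag means the first unit leads).
#'
#' @param spikes a [spike_table()].
#' @param bin_ms,lag_ms,conv_sd_ms,window_ms,alpha see [ccg()] and
#'   [ccg_significance()].
#' @param min_spikes pairs where either unit has fewer spikes are skipped.
#' @return a `connectivity_graph` (see [connectivity_graph()]) with one row
#'   per significant directed connection (`stat` = peak count, `p`).
#' @export
connectivity_ccg <- function(spikes, bin_ms = 1, lag_ms = 50,
                             conv_sd_ms = 10, window_ms = 5, alpha = 0.001,
                             min_spikes = 2) {
  units <- sort(unique(spikes$unit_id))
  trains <- lapply(units, function(u) unit_spikes(spikes, u))
  edges <- data.frame(source = integer(), target = integer(),
                      stat = numeric(), p = numeric(), lag_ms = numeric())
  n <- length(units)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (length(trains[[i]]) < min_spikes ||
            length(trains[[j]]) < min_spikes) next
        cc <- ccg(trains[[i]], trains[[j]], bin_ms, lag_ms)
        res <- ccg_significance(cc, bin_ms, conv_sd_ms, window_ms, alpha)
        if (isTRUE(res$significant)) {
          if (res$peak_lag_ms > 0)
            edges <- rbind(edges, data.frame(
              source = units[i], target = units[j], stat = res$peak_count,
              p = res$p, lag_ms = res$peak_lag_ms))
          else
            edges <- rbind(edges, data.frame(
              source = units[j], target = units[i], stat = res$peak_count,
              p = res$p, lag_ms = -res$peak_lag_ms))
        }
      }
    }
  }
  connectivity_graph(edges, units, method = "ccg",
                     params = list(bin_ms = bin_ms, alpha = alpha))
}
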