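#' Binarize a spike train onto a bin grid
#'
#' @param t spike times (s).
#' @param bin_ms bin width (ms).
#' @param duration recording length (s).
#' @return integer 0/1 vector of length `floor(duration / bin)`; multiple
#'   spikes in a bin collapse to 1.
#' @export
binarize_train <- function(t, bin_ms, duration) {
  n <- floor(duration * 1000 / bin_ms)
  v <- integer(n)
  idx <- floor(t * 1000 / bin_ms) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  v[idx] <- 1L
  v
}

#' Bivariate transfer entropy between binarized spike trains
#'
#' Plug-in estimate of the directed information transfer from a source to a
#' target binary sequence:
#' `TE = sum p(j_t, j_hist, i_hist) * log2[ p(j_t | j_hist, i_hist) /
#' p(j_t | j_hist) ]`,
#' with the target history of `k_target` bins immediately before `t` and the
#' source history of `l_source` bins ending `delay` bins before `t`.
#' Probabilities are joint pattern frequencies. Always >= 0 for the plug-in
#' estimator.
#'
#' @param source,target equal-length integer 0/1 vectors.
#' @param k_target target history length in bins (default 1).
#' @param l_source source history length in bins (default 4).
#' @param delay source delay in bins (default 1); the source window then
#'   spans lags `delay` to `delay + l_source - 1`.
#' @return transfer entropy in bits.
#' @export
transfer_entropy <- function(source, target, k_target = 1, l_source = 4,
                             delay = 1) {
  n <- length(target)
  if (length(source) != n) stop("source and target must have equal length")
  first <- max(k_target, delay + l_source - 1) + 1L
  if (first > n) stop("sequences shorter than the configured histories")
  ts <- first:n
  jh <- integer(length(ts))
  for (m in seq_len(k_target)) jh <- jh + target[ts - m] * 2L^(m - 1L)
  ih <- integer(length(ts))
  for (m in seq_len(l_source))
    ih <- ih + source[ts - delay - (m - 1L)] * 2L^(m - 1L)
  j <- target[ts]
  nj <- 2L^k_target; ni <- 2L^l_source
  state <- j + 2L * jh + 2L * nj * ih
  cnt <- tabulate(state + 1L, nbins = 2L * nj * ni)
  N <- length(ts)
  te_from_counts(cnt, nj, ni, N)
}

# Target-side context reused across the surrogates of one pair: the code
# j + 2*jh per evaluated bin, its marginal counts, and index bookkeeping.
te_target_context <- function(target, k_target, l_source, delay) {
  n <- length(target)
  first <- max(k_target, delay + l_source - 1) + 1L
  if (first > n) stop("sequences shorter than the configured histories")
  ts <- first:n
  jh <- integer(length(ts))
  for (m in seq_len(k_target)) jh <- jh + target[ts - m] * 2L^(m - 1L)
  jcode <- target[ts] + 2L * jh
  nj <- 2L^k_target
  list(n = n, first = first, N = length(ts), nj = nj,
       ni = 2L^l_source, jcode = jcode,
       cnt0 = tabulate(jcode + 1L, nbins = 2L * nj))
}

# TE of one source spike-bin set against a precomputed target context,
# exploiting source sparsity: only bins within the source window of a spike
# can have a nonzero source-history pattern; all remaining bins contribute
# through the target-side marginal counts. Exactly equals
# transfer_entropy() on the corresponding dense vectors.
te_sparse <- function(spike_bins, ctx, l_source, delay) {
  src <- integer(ctx$n)
  src[spike_bins] <- 1L
  P <- unique(rep(spike_bins, each = l_source) + delay + 0:(l_source - 1L))
  P <- P[P >= ctx$first & P <= ctx$n]
  cnt <- integer(2L * ctx$nj * ctx$ni)
  cnt[seq_len(2L * ctx$nj)] <- ctx$cnt0
  if (length(P)) {
    ih <- integer(length(P))
    for (m in seq_len(l_source)) ih <- ih + src[P - delay - (m - 1L)] * 2L^(m - 1L)
    jc <- ctx$jcode[P - ctx$first + 1L]
    move <- ih > 0L
    if (any(move)) {
      sub <- tabulate(jc[move] + 1L, nbins = 2L * ctx$nj)
      cnt[seq_len(2L * ctx$nj)] <- cnt[seq_len(2L * ctx$nj)] - sub
      add <- tabulate(jc[move] + 2L * ctx$nj * ih[move] + 1L,
                      nbins = 2L * ctx$nj * ctx$ni)
      cnt <- cnt + add
    }
  }
  te_from_counts(cnt, ctx$nj, ctx$ni, ctx$N)
}

# TE in bits from joint (j, jh, ih) pattern counts laid out as
# index = j + 2*jh + 2*nj*ih (0-based).
te_from_counts <- function(cnt, nj, ni, N) {
  arr <- array(cnt, dim = c(2L, nj, ni))          # [j, jh, ih]
  c_hi <- apply(arr, c(2, 3), sum)                # (jh, ih)
  c_jh <- apply(arr, c(1, 2), sum)                # (j, jh)
  c_h <- apply(arr, 2, sum)                       # (jh)
  te <- 0
  for (ii in seq_len(ni)) for (hh in seq_len(nj)) for (jj in 1:2) {
    c3 <- arr[jj, hh, ii]
    if (c3 == 0) next
    p3 <- c3 / N
    p_cond_full <- c3 / c_hi[hh, ii]
    p_cond_hist <- c_jh[jj, hh] / c_h[hh]
    te <- te + p3 * log2(p_cond_full / p_cond_hist)
  }
  max(te, 0)
}

#' Transfer-entropy significance via jittered surrogates
#'
#' Destroys fine source-target timing while preserving the source rate by
#' jittering each source spike bin with an integer offset drawn uniformly
#' from a window of `jitter_bins` bins (width 7 means offsets -3..3); the
#' target is left unchanged. Offsets that would collide in one bin or fall
#' outside the recording are redrawn, so surrogates keep the empirical
#' train's bin occupancy rather than running at a slight occupancy deficit
#' that would bias every surrogate TE low. The empirical TE is z-scored against the mean
#' and SD of `n_surrogates` surrogate TE values and deemed significant when
#' z exceeds the Gaussian quantile at `alpha`.
#'
#' @param source,target integer 0/1 vectors (see [binarize_train()]).
#' @param k_target,l_source,delay history parameters, see
#'   [transfer_entropy()].
#' @param n_surrogates number of surrogate trains (default 50).
#' @param jitter_bins uniform jitter window width in bins (default 7).
#' @param alpha significance level (default 0.001).
#' @param seed optional seed for the surrogate draws.
#' @return list of class `te_result`: `te` (bits), `z`, `significant`,
#'   `surrogate_mean`, `surrogate_sd`, `degenerate` (zero surrogate SD).
#' @export
te_significance <- function(source, target, k_target = 1, l_source = 4,
                            delay = 1, n_surrogates = 50, jitter_bins = 7,
                            alpha = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(source) != length(target))
    stop("source and target must have equal length")
  ctx <- te_target_context(target, k_target, l_source, delay)
  spike_bins <- which(source == 1L)
  te_emp <- te_sparse(spike_bins, ctx, l_source, delay)
  half <- (jitter_bins - 1) %/% 2
  n <- length(source)
  te_surr <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    jb <- spike_bins + sample.int(2L * half + 1L, length(spike_bins),
                                  replace = TRUE) - (half + 1L)
    # redraw offsets that would collide or fall off the edge, so surrogate
    # trains keep the empirical train's bin occupancy (a collision-induced
    # occupancy deficit would bias every surrogate TE slightly low)
    for (tries in 1:8) {
      bad <- which(duplicated(jb) | jb < 1L | jb > n)
      if (!length(bad)) break
      jb[bad] <- spike_bins[bad] +
        sample.int(2L * half + 1L, length(bad), replace = TRUE) - (half + 1L)
    }
    jb <- unique(jb[jb >= 1L & jb <= n])
    te_surr[s] <- te_sparse(jb, ctx, l_source, delay)
  }
  m <- mean(te_surr); sdev <- stats::sd(te_surr)
  if (sdev == 0) {
    return(structure(list(te = te_emp, z = NA_real_, significant = FALSE,
                          surrogate_mean = m, surrogate_sd = 0,
                          degenerate = TRUE),
                     class = "te_result"))
  }
  z <- (te_emp - m) / sdev
  structure(list(te = te_emp, z = z,
                 significant = z > stats::qnorm(1 - alpha),
                 surrogate_mean = m, surrogate_sd = sdev,
                 degenerate = FALSE),
            class = "te_result")
}

#' Source-history window of a TE time scale
#'
#' The source history spans lags `delay` to `delay + l_source - 1` bins, so
#' at bin size `bin_ms` it covers `bin_ms * delay` to
#' `bin_ms * (delay + l_source - 1)` milliseconds before the target bin
#' (35-140 ms at a 35 ms bin with the default history of 4 bins).
#'
#' @param bin_ms bin size (ms).
#' @param l_source source history length (bins), default 4.
#' @param delay source delay (bins), default 1.
#' @return numeric c(lower, upper) window edges in ms.
#' @export
te_source_window <- function(bin_ms, l_source = 4, delay = 1) {
  c(lower_ms = bin_ms * delay, upper_ms = bin_ms * (delay + l_source - 1))
}

#' Default TE time-scale ladder
#'
#' Eight log-spaced bin sizes spanning 1-160 ms with scale 2 at 1.6 ms and
#' scale 6 at 35 ms.
#'
#' @return numeric vector of bin sizes (ms).
#' @export
te_scales <- function() c(1, 1.6, 3.5, 7.4, 16, 35, 74, 160)

#' Transfer-entropy connectivity across a ladder of time scales
#'
#' For each bin size, binarizes all spike trains, tests every ordered unit
#' pair with [te_significance()], and summarizes the resulting directed
#' graph by its connection density (significant fraction of ordered pairs)
#' and the modularity Q of a Louvain partition of the significant-edge
#' graph.
#'
#' @param spikes a [spike_table()].
#' @param duration recording duration (s).
#' @param scales_ms bin-size ladder (ms), default [te_scales()].
#' @param k_target,l_source,delay,n_surrogates,jitter_bins,alpha see
#'   [te_significance()].
#' @param seed root seed; pair surrogates use derived substreams.
#' @return list of class `te_sweep`: `summary` (data.frame `scale`,
#'   `bin_ms`, `source_lo_ms`, `source_hi_ms`, `n_significant`, `density`,
#'   `q_modularity`) and `graphs` (one `connectivity_graph` per scale).
#' @export
te_scale_sweep <- function(spikes, duration, scales_ms = te_scales(),
                           k_target = 1, l_source = 4, delay = 1,
                           n_surrogates = 50, jitter_bins = 7,
                           alpha = 0.001, seed = 1L) {
  units <- sort(unique(spikes$unit_id))
  n <- length(units)
  graphs <- vector("list", length(scales_ms))
  summ <- NULL
  for (sc in seq_along(scales_ms)) {
    bin_ms <- scales_ms[sc]
    bins <- lapply(units, function(u)
      binarize_train(unit_spikes(spikes, u), bin_ms, duration))
    edges <- data.frame(source = integer(), target = integer(),
                        stat = numeric(), z = numeric())
    if (n >= 2) {
      pair_idx <- 0L
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        pair_idx <- pair_idx + 1L
        res <- te_significance(
          bins[[i]], bins[[j]], k_target, l_source, delay,
          n_surrogates, jitter_bins, alpha,
          seed = substream_seed(seed, sc * 100000L + pair_idx))
        if (isTRUE(res$significant))
          edges <- rbind(edges, data.frame(source = units[i],
                                           target = units[j],
                                           stat = res$te, z = res$z))
      }
    }
    gobj <- connectivity_graph(edges, units, method = "te",
                               params = list(bin_ms = bin_ms, alpha = alpha,
                                             scale = sc))
    graphs[[sc]] <- gobj
    win <- te_source_window(bin_ms, l_source, delay)
    summ <- rbind(summ, data.frame(
      scale = sc, bin_ms = bin_ms,
      source_lo_ms = win[["lower_ms"]], source_hi_ms = win[["upper_ms"]],
      n_significant = nrow(edges), density = gobj$density,
      q_modularity = modularity_q(gobj)))
  }
  structure(list(summary = summ, graphs = graphs), class = "te_sweep")
}
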