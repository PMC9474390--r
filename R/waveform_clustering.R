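#' Prepare normalized peak-channel waveform snippets
#'
#' For each unit's electrical footprint, takes the peak-channel waveform at
#' 20 kHz (up-sampling if recorded at a lower rate), high-pass filters it
#' (2nd-order Butterworth, default 150 Hz cut-off, zero-phase), aligns on
#' the filtered trough, cuts a 61-point snippet (1 ms before to 2 ms after
#' the trough at 20 kHz) and normalizes it so the trough equals -1. Units
#' with a flat (zero-trough) waveform are excluded with a warning.
#'
#' @param efs list of [electrical_footprint()]s.
#' @param fs_target analysis rate (Hz), default 20000.
#' @param hp_hz high-pass cut-off (Hz), default 150.
#' @param n_before,n_after samples kept before/after the trough (defaults 20
#'   and 40, i.e. 61 points).
#' @return numeric matrix (units x 61) of class `waveform_snippets`, row
#'   names = unit ids; every row has minimum exactly -1.
#' @export
prepare_snippets <- function(efs, fs_target = 20000, hp_hz = 150,
                             n_before = 20, n_after = 40) {
  len <- n_before + n_after + 1L
  out <- NULL; ids <- integer()
  bf <- signal::butter(2, hp_hz / (fs_target / 2), type = "high")
  for (ef in efs) {
    w <- peak_waveform(ef)
    if (ef$fs < fs_target) w <- resample_wave(w, ef$fs, fs_target)
    wf <- signal::filtfilt(bf, w)
    i <- which.min(wf)
    if (wf[i] >= 0) {
      warning(sprintf("unit %d: flat waveform (no trough), excluded",
                      ef$unit_id))
      next
    }
    # pad with edge values if the trough sits close to a window border
    idx <- (i - n_before):(i + n_after)
    idx <- pmin(pmax(idx, 1L), length(wf))
    snip <- wf[idx] / (-wf[i])
    out <- rbind(out, snip)
    ids <- c(ids, ef$unit_id)
  }
  if (is.null(out)) stop("no usable waveforms")
  rownames(out) <- ids
  colnames(out) <- NULL
  stopifnot(ncol(out) == len)
  class(out) <- c("waveform_snippets", class(out))
  out
}

#' Fuzzy k-nearest-neighbour graph over waveform snippets
#'
#' Builds the high-dimensional neighbour graph that the clustering step
#' consumes: for each point, distances to its k nearest neighbours are
#' converted to membership strengths `exp(-(d - rho) / sigma)` with `rho`
#' the distance to the nearest neighbour and `sigma` calibrated per point so
#' the total membership equals `log2(k)`; directed memberships are
#' symmetrized by the fuzzy union `a + b - a b`.
#'
#' @param x numeric matrix (points x features).
#' @param k neighbourhood size, default 15 (capped at n - 1).
#' @return weighted undirected igraph.
#' @export
fuzzy_knn_graph <- function(x, k = 15) {
  n <- nrow(x)
  if (n < 3) stop("need at least 3 points")
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  A <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    ord <- order(di)[seq_len(k)]
    dk <- di[ord]
    rho <- dk[1]
    ex <- pmax(dk - rho, 0)
    if (all(ex == 0)) {
      w <- rep(1, k)
    } else {
      lo <- 1e-6; hi <- max(ex) * 20
      for (it in 1:64) {
        mid <- (lo + hi) / 2
        s <- sum(exp(-ex / mid))
        if (s > target) hi <- mid else lo <- mid
      }
      w <- exp(-ex / mid)
    }
    idx <- seq_len(n)[-i][ord]
    A[i, idx] <- w
  }
  S <- A + t(A) - A * t(A)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Cluster waveform snippets on the neighbour graph
#'
#' Louvain community detection at a given resolution on the fuzzy k-NN
#' graph of the snippets. The modularity Q reported is the standard
#' (resolution-1) modularity of the obtained partition, computed on the
#' same weighted graph that was clustered.
#'
#' @param snippets matrix from [prepare_snippets()] (or any points x
#'   features matrix).
#' @param resolution Louvain resolution parameter, default 1.5.
#' @param k neighbour count for the graph, default 15.
#' @param seed seed for the Louvain pass.
#' @return list of class `cluster_solution`: `labels` (named integer vector,
#'   dense 1..n_clusters), `resolution`, `Q`, `n_clusters`, `graph`.
#' @export
cluster_waveforms <- function(snippets, resolution = 1.5, k = 15,
                              seed = 1L) {
  if (nrow(snippets) < 10) stop("need at least 10 snippets")
  g <- fuzzy_knn_graph(unclass(snippets), k = k)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  labels <- match(labels, sort(unique(labels)))   # dense 1..K
  names(labels) <- rownames(snippets)
  Q <- igraph::modularity(g, labels, weights = igraph::E(g)$weight)
  structure(list(labels = labels, resolution = resolution, Q = Q,
                 n_clusters = length(unique(labels)), graph = g),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d clusters at resolution %.3g (Q = %.3f)\n",
              x$n_clusters, x$resolution, x$Q))
  invisible(x)
}

#' Sweep the Louvain resolution parameter
#'
#' Repeats the clustering `n_iter` times per resolution with distinct seeds
#' (root seed + iteration index) and reports the mean modularity and mean
#' cluster count — the standard diagnostic for choosing a resolution.
#'
#' @param snippets matrix from [prepare_snippets()].
#' @param resolutions vector of resolution parameters.
#' @param n_iter iterations per resolution, default 20.
#' @param k neighbour count, default 15.
#' @param seed root seed.
#' @return data.frame `resolution`, `mean_q`, `mean_n_clusters`.
#' @export
resolution_sweep <- function(snippets, resolutions = seq(0.5, 3, by = 0.5),
                             n_iter = 20, k = 15, seed = 1L) {
  out <- NULL
  for (r in resolutions) {
    qs <- numeric(n_iter); ks <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      sol <- cluster_waveforms(snippets, resolution = r, k = k,
                               seed = seed + it)
      qs[it] <- sol$Q; ks[it] <- sol$n_clusters
    }
    out <- rbind(out, data.frame(resolution = r, mean_q = mean(qs),
                                 mean_n_clusters = mean(ks)))
  }
  out
}
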