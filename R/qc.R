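#' Refractory-period quality filter
#'
#' Removes units whose fraction of inter-spike intervals in the 0-1 ms bin
#' exceeds the violation threshold (default 5% of all spikes) — such
#' contamination indicates that the sorted cluster mixes spikes from more
#' than one neuron. Spike times are never altered, only whole units dropped.
#'
#' @param spikes a [spike_table()].
#' @param max_violation maximum tolerated violation fraction (default 0.05).
#' @param refractory_ms refractory bin upper edge in ms (violations are ISIs
#'   in `[0, refractory_ms)`).
#' @return list with `spikes` (filtered table) and `report` (data.frame
#'   `unit_id`, `n_spikes`, `violation_fraction`, `kept`).
#' @export
refractory_filter <- function(spikes, max_violation = 0.05,
                              refractory_ms = 1) {
  units <- sort(unique(spikes$unit_id))
  rep_df <- data.frame(unit_id = integer(), n_spikes = integer(),
                       violation_fraction = numeric(), kept = logical())
  for (u in units) {
    tt <- unit_spikes(spikes, u)
    n <- length(tt)
    viol <- if (n > 1) sum(diff(tt) < refractory_ms / 1000) else 0L
    frac <- if (n > 0) viol / n else 0
    rep_df <- rbind(rep_df, data.frame(
      unit_id = u, n_spikes = n, violation_fraction = frac,
      kept = frac <= max_violation))
  }
  keep_units <- rep_df$unit_id[rep_df$kept]
  out <- spikes[spikes$unit_id %in% keep_units, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(spikes)
  list(spikes = out, report = rep_df)
}

#' Remove duplicate spikes between co-located units
#'
#' When two units' peak channels lie within `radius_um` of each other, near-
#' coincident spikes are likely the same event picked up twice by the sorter.
#' For each such pair, spikes of the lower-amplitude unit falling within
#' `window_ms` of a spike of the higher-amplitude unit are dropped (ties in
#' amplitude broken in favour of the lower unit id). The kept unit's
#' original spike train defines the coincidences, so the operation is
#' idempotent.
#'
#' @param spikes a [spike_table()].
#' @param efs named list of [electrical_footprint()]s (names = unit ids, or
#'   `$unit_id` fields used) supplying peak-channel positions and amplitudes.
#' @param window_ms coincidence window (default 0.5 ms).
#' @param radius_um peak-channel distance threshold (default 100 um).
#' @return filtered [spike_table()] with attribute `n_removed`.
#' @export
remove_duplicate_spikes <- function(spikes, efs, window_ms = 0.5,
                                    radius_um = 100) {
  units <- sort(unique(spikes$unit_id))
  ef_ids <- vapply(efs, function(e) e$unit_id, integer(1))
  missing <- setdiff(units, ef_ids)
  if (length(missing))
    stop("no electrical footprint for unit(s): ",
         paste(missing, collapse = ", "))
  ef_of <- function(u) efs[[match(u, ef_ids)]]

  orig <- lapply(units, function(u) unit_spikes(spikes, u))
  names(orig) <- as.character(units)
  kept <- orig
  n_removed <- 0L
  if (length(units) > 1) {
    for (i in seq_along(units)[-length(units)]) {
      for (j in (i + 1):length(units)) {
        a <- units[i]; b <- units[j]
        pa <- peak_position(ef_of(a)); pb <- peak_position(ef_of(b))
        if (sqrt(sum((pa - pb)^2)) > radius_um) next
        amp_a <- peak_amplitude(ef_of(a)); amp_b <- peak_amplitude(ef_of(b))
        # winner keeps its spikes; ties broken by lower unit id
        if (amp_a > amp_b || (amp_a == amp_b && a < b)) {
          win <- a; lose <- b
        } else {
          win <- b; lose <- a
        }
        wt <- orig[[as.character(win)]]
        lt <- kept[[as.character(lose)]]
        if (!length(wt) || !length(lt)) next
        # nearest winner spike within window_ms => duplicate
        idx <- findInterval(lt, wt)
        d_lo <- ifelse(idx >= 1, lt - wt[pmax(idx, 1)], Inf)
        d_hi <- ifelse(idx < length(wt), wt[pmin(idx + 1, length(wt))] - lt, Inf)
        dup <- pmin(d_lo, d_hi) <= window_ms / 1000
        n_removed <- n_removed + sum(dup)
        kept[[as.character(lose)]] <- lt[!dup]
      }
    }
  }
  n_per <- lengths(kept)
  out <- spike_table(rep.int(units, n_per), unlist(kept, use.names = FALSE))
  attr(out, "n_removed") <- n_removed
  out
}
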