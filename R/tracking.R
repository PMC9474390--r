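# Hungarian algorithm (O(n^3), potentials + augmenting paths) for the
# rectangular assignment problem, minimizing total cost. No assignment-
# problem solver ships with the installed stack, so this is implemented
# here and checked against an exhaustive-permutation oracle in the tests.
hungarian_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

# Cosine similarity between flattened EF waveforms on shared channels.
ef_cosine <- function(ef_a, ef_b) {
  if (!identical(ef_a$channels$electrode_id, ef_b$channels$electrode_id))
    stop("electrical footprints recorded on different channel sets")
  a <- as.vector(ef_a$waveform); b <- as.vector(ef_b$waveform)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match single units across recording sessions
#'
#' Tracks units over consecutive sessions recorded on a fixed electrode
#' configuration by template matching of their electrical footprints: for
#' each consecutive day pair, the one-to-one assignment maximizing the total
#' cosine similarity between flattened EFs is computed (Hungarian
#' algorithm), and assignments with similarity at least `sim_threshold` are
#' accepted as matches. Chains of consecutive matches define units tracked
#' across spans (day 1 to 2, 1 to 3, ...); the tracked count is therefore
#' non-increasing with span. Cosine similarity is invariant to global gain,
#' so uniform amplitude drift between sessions does not impair matching.
#'
#' @param efs_by_day list (one element per day) of lists of
#'   [electrical_footprint()]s, all on the same channel set.
#' @param sim_threshold minimum cosine similarity to accept a match
#'   (default 0.85).
#' @return list of class `tracking_result`: `matches` (data.frame `day_a`,
#'   `day_b`, `unit_a`, `unit_b`, `similarity` for consecutive day pairs),
#'   `tracked_counts` (named vector: units tracked from day 1 through day
#'   k, for k = 2..n_days), `chains` (data.frame of day-1 units and their
#'   correspondents per day, NA once lost).
#' @export
match_sessions <- function(efs_by_day, sim_threshold = 0.85) {
  n_days <- length(efs_by_day)
  if (n_days < 2) stop("need at least two sessions")
  ids <- lapply(efs_by_day, function(day)
    vapply(day, function(e) e$unit_id, integer(1)))
  matches <- data.frame(day_a = integer(), day_b = integer(),
                        unit_a = integer(), unit_b = integer(),
                        similarity = numeric())
  maps <- vector("list", n_days - 1L)   # per pair: named correspondence
  for (d in seq_len(n_days - 1L)) {
    A <- efs_by_day[[d]]; B <- efs_by_day[[d + 1L]]
    sim <- matrix(0, length(A), length(B))
    for (i in seq_along(A)) for (j in seq_along(B))
      sim[i, j] <- ef_cosine(A[[i]], B[[j]])
    flip <- FALSE
    S <- sim
    if (nrow(S) > ncol(S)) { S <- t(S); flip <- TRUE }
    asg <- hungarian_assignment(-S)
    mp <- integer(0)
    for (i in seq_along(asg)) {
      ia <- if (flip) asg[i] else i
      ib <- if (flip) i else asg[i]
      s <- sim[ia, ib]
      if (s >= sim_threshold) {
        matches <- rbind(matches, data.frame(
          day_a = d, day_b = d + 1L,
          unit_a = ids[[d]][ia], unit_b = ids[[d + 1L]][ib],
          similarity = s))
        mp[as.character(ids[[d]][ia])] <- ids[[d + 1L]][ib]
      }
    }
    maps[[d]] <- mp
  }
  # chains from day 1
  day1 <- ids[[1]]
  chains <- matrix(NA_integer_, nrow = length(day1), ncol = n_days)
  chains[, 1] <- day1
  for (d in seq_len(n_days - 1L)) {
    prev <- chains[, d]
    nxt <- rep(NA_integer_, length(prev))
    ok <- !is.na(prev)
    hit <- match(as.character(prev[ok]), names(maps[[d]]))
    nxt[ok][!is.na(hit)] <- unname(maps[[d]][hit[!is.na(hit)]])
    chains[, d + 1L] <- nxt
  }
  tracked <- vapply(2:n_days, function(k) sum(!is.na(chains[, k])),
                    integer(1))
  names(tracked) <- paste0("day1_to_", 2:n_days)
  chains_df <- as.data.frame(chains)
  names(chains_df) <- paste0("day", seq_len(n_days))
  structure(list(matches = matches, tracked_counts = tracked,
                 chains = chains_df),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat("<tracking_result> tracked units:",
      paste(sprintf("%s=%d", names(x$tracked_counts), x$tracked_counts),
            collapse = ", "), "\n")
  invisible(x)
}
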