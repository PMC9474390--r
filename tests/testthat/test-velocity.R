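test_that("noise-free propagation gives exact latencies and velocity", {
  arr <- electrode_array(10, 10)
  ef <- simulate_ef(arr, 0:2, velocity = 0.35, noise_sd = 0, seed = 1)
  lmap <- latency_map(ef, noise_floor = 1)
  expect_equal(lmap$electrodes$latency_ms, c(0, 0.05, 0.10), tolerance = 1e-6)
  v <- fit_velocity(extract_path(build_flow_graph(lmap), 0))
  expect_equal(v$velocity_mps, 0.35, tolerance = 1e-6)
  expect_equal(v$r2, 1, tolerance = 1e-9)
  expect_equal(v$n_segments, 1L)
  expect_equal(v$traced_um, 35)
})

test_that("negative-latency and sub-floor electrodes are masked", {
  arr <- electrode_array(10, 10)
  ef <- simulate_ef(arr, 0:4, velocity = 0.4, noise_sd = 0, seed = 2)
  # make electrode 3 fire before the peak channel and electrode 4 tiny
  wf <- ef$waveform
  wf[4, ] <- wf[1, ]                                   # same time as origin
  wf[4, ] <- c(wf[1, -(1:8)], rep(0, 8))               # 8 samples earlier
  wf[5, ] <- wf[5, ] * 0.001
  ef2 <- electrical_footprint(1L, wf, ef$channels, ef$fs, t0_ms = ef$t0_ms)
  lmap <- latency_map(ef2, noise_floor = 0.5)
  expect_false(lmap$electrodes$included[4])            # negative latency
  expect_false(lmap$electrodes$included[5])            # below floor
  # mask equals a direct amplitude-threshold scan
  depth <- apply(wf, 1, function(w) -min(w))
  expect_equal(lmap$electrodes$included,
               depth > 0.5 & lmap$electrodes$latency_ms >= 0)
})

test_that("flow-graph edges follow the latency-order / 60 um rule exactly", {
  # 3x3 grid with strictly increasing latency left to right
  el <- expand.grid(x = (0:2) * 17.5, y = (0:2) * 17.5)
  lmap <- structure(list(
    electrodes = data.frame(
      electrode_id = 0:8, x = el$x, y = el$y,
      latency_ms = rep(c(0, 0.05, 0.1), times = 3) + (0:8) * 1e-4,
      amplitude = 50, included = TRUE),
    peak_channel = 0L, unit_id = 1L), class = "latency_map")
  g <- build_flow_graph(lmap, max_edge = 60)
  got <- igraph::as_edgelist(g)
  # brute-force enumeration over ordered pairs
  want <- NULL
  for (i in 1:9) for (j in 1:9) {
    d <- sqrt((el$x[i] - el$x[j])^2 + (el$y[i] - el$y[j])^2)
    li <- lmap$electrodes$latency_ms
    if (d <= 60 && li[i] < li[j]) want <- rbind(want, c(i, j))
  }
  expect_equal(got[order(got[, 1], got[, 2]), ],
               want[order(want[, 1], want[, 2]), ])
  # acyclic by construction
  expect_true(igraph::is_dag(g))
  # electrodes 70 um apart get no edge
  lmap2 <- structure(list(
    electrodes = data.frame(electrode_id = 0:1, x = c(0, 70), y = 0,
                            latency_ms = c(0, 0.1), amplitude = 50,
                            included = TRUE),
    peak_channel = 0L, unit_id = 1L), class = "latency_map")
  expect_equal(igraph::ecount(build_flow_graph(lmap2)), 0)
  # single electrode: one node, no edges
  lmap3 <- structure(list(
    electrodes = data.frame(electrode_id = 0L, x = 0, y = 0,
                            latency_ms = 0, amplitude = 50, included = TRUE),
    peak_channel = 0L, unit_id = 1L), class = "latency_map")
  g3 <- build_flow_graph(lmap3)
  expect_equal(igraph::vcount(g3), 1)
  expect_equal(igraph::ecount(g3), 0)
})

test_that("shortest path matches exhaustive enumeration on a small graph", {
  # two routes to the far corner of a 2 x 4 strip with a detour
  set.seed(3)
  xs <- c(0, 17.5, 35, 52.5, 0, 17.5, 35, 52.5)
  ys <- c(0, 0, 0, 0, 17.5, 17.5, 26, 17.5)   # second row bent at node 7
  lat <- c(0, 1, 2, 3, 0.5, 1.5, 2.5, 3.5) / 10
  lmap <- structure(list(
    electrodes = data.frame(electrode_id = 0:7, x = xs, y = ys,
                            latency_ms = lat, amplitude = 50,
                            included = TRUE),
    peak_channel = 0L, unit_id = 1L), class = "latency_map")
  g <- build_flow_graph(lmap, max_edge = 30)
  paths <- extract_path(g, 0)
  expect_equal(length(paths), 1L)
  # exhaustive DFS enumeration of all simple paths from origin to target
  el <- igraph::as_edgelist(g)
  target_id <- paths[[1]]$electrode_id[length(paths[[1]]$electrode_id)]
  target <- target_id + 1
  adj <- lapply(1:8, function(v) el[el[, 1] == v, 2])
  best <- Inf
  dfs <- function(v, len, seen) {
    if (v == target) { best <<- min(best, len); return() }
    for (w in adj[[v]]) if (!w %in% seen) {
      d <- sqrt((xs[v] - xs[w])^2 + (ys[v] - ys[w])^2)
      dfs(w, len + d, c(seen, w))
    }
  }
  dfs(1, 0, 1)
  expect_equal(max(paths[[1]]$cumdist_um), best, tolerance = 1e-9)
})

test_that("disconnected flow-graph clusters yield one path per segment", {
  xs <- c(0, 17.5, 35, 200, 217.5, 235)
  lmap <- structure(list(
    electrodes = data.frame(electrode_id = 0:5, x = xs, y = 0,
                            latency_ms = c(0, .04, .08, .2, .24, .28),
                            amplitude = 50, included = TRUE),
    peak_channel = 0L, unit_id = 1L), class = "latency_map")
  g <- build_flow_graph(lmap)
  paths <- extract_path(g, 0)
  expect_equal(length(paths), 2L)
  v <- fit_velocity(paths)
  expect_equal(v$n_segments, 2L)
  expect_gt(v$r2, 0.99)
})

test_that("velocity estimates are invariant to rotation and translation", {
  arr <- electrode_array(40, 40)
  p <- 0:9
  ef <- simulate_ef(arr, p, velocity = 0.41, noise_sd = 0.5,
                    latency_jitter_sd = 1e-5, seed = 17)
  v1 <- estimate_velocity(ef)
  # rotate coordinates by 37 degrees and translate
  th <- 37 * pi / 180
  ch <- ef$channels
  ch2 <- data.frame(
    electrode_id = ch$electrode_id,
    x = cos(th) * ch$x - sin(th) * ch$y + 123,
    y = sin(th) * ch$x + cos(th) * ch$y - 45)
  ef2 <- electrical_footprint(ef$unit_id, ef$waveform, ch2, ef$fs,
                              t0_ms = ef$t0_ms)
  v2 <- estimate_velocity(ef2)
  expect_equal(v2$velocity_mps, v1$velocity_mps, tolerance = 1e-9)
  expect_equal(v2$r2, v1$r2, tolerance = 1e-9)
})

test_that("r2 matches a hand-rolled least-squares oracle; heavy jitter excluded", {
  arr <- electrode_array(40, 40)
  ef <- simulate_ef(arr, 0:9, velocity = 0.41, noise_sd = 0.5,
                    latency_jitter_sd = 2e-4, seed = 18)   # 200 us jitter
  v <- estimate_velocity(ef)
  expect_false(is.null(v))
  lat <- unlist(lapply(v$paths, function(p) p$latency_ms)) / 1000
  dst <- unlist(lapply(v$paths, function(p) p$cumdist_um)) * 1e-6
  sxy <- sum((lat - mean(lat)) * (dst - mean(dst)))
  r2_oracle <- sxy^2 / (sum((lat - mean(lat))^2) * sum((dst - mean(dst))^2))
  expect_equal(v$r2, r2_oracle, tolerance = 1e-9)
  expect_false(v$included && v$r2 <= 0.8)
})

test_that("sampling-rate quantization bounds the noise-free estimate", {
  arr <- electrode_array(40, 40)
  ef <- simulate_ef(arr, 0:11, velocity = 0.41, noise_sd = 0, seed = 19)
  v_interp <- estimate_velocity(ef, noise_floor = 1)
  expect_equal(v_interp$velocity_mps, 0.41, tolerance = 0.02)
  v_sample <- estimate_velocity(ef, noise_floor = 1, interp = "none")
  # at sample resolution the error stays within one 50 us period per step
  step_s <- 17.5e-6 / 0.41
  expect_lt(abs(1 / v_sample$velocity_mps - 1 / 0.41) * 17.5e-6, 5e-5)
})
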