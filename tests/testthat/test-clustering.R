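test_that("snippets are 61 points, trough-normalized, filter removes DC", {
  arr <- electrode_array(10, 10)
  efs <- lapply(1:12, function(u) {
    ef <- simulate_ef(arr, 0:2, 0.4, peak_amp = 80, noise_sd = 0.5, seed = u)
    ef$unit_id <- u
    ef
  })
  sn <- prepare_snippets(efs)
  expect_equal(ncol(sn), 61L)
  expect_equal(nrow(sn), 12L)
  expect_equal(unname(apply(sn, 1, min)), rep(-1, 12))
  # trough sits at the alignment point (sample 21)
  expect_true(all(apply(sn, 1, which.min) == 21))
  # a 150 Hz high-pass removes a constant offset: filtered DC input is ~0
  bf <- signal::butter(2, 150 / 10000, type = "high")
  const <- signal::filtfilt(bf, rep(3, 2000))
  expect_lt(max(abs(const[500:1500])), 1e-6)
  # flat waveform excluded with a warning
  flat <- electrical_footprint(99L, matrix(0, 1, 100),
                               data.frame(electrode_id = 0, x = 0, y = 0),
                               20000)
  expect_warning(sn2 <- prepare_snippets(c(efs, list(flat))), "flat")
  expect_equal(nrow(sn2), 12L)
  # a 10 kHz footprint is up-sampled, snippet grid unchanged
  ef10 <- simulate_ef(arr, 0:2, 0.4, noise_sd = 0.2, fs = 10000, seed = 50)
  ef10$unit_id <- 50L
  sn3 <- prepare_snippets(list(ef10, efs[[1]], efs[[2]], efs[[3]]))
  expect_equal(ncol(sn3), 61L)
})

test_that("two waveform families separate with perfect purity", {
  f1 <- make_waveform_family(50, "biphasic", seed = 1)
  f2 <- make_waveform_family(50, "triphasic", seed = 2)
  sol <- cluster_waveforms(rbind(f1, f2), resolution = 1, seed = 1)
  expect_equal(sol$n_clusters, 2L)
  truth <- rep(1:2, each = 50)
  tab <- table(sol$labels, truth)
  expect_equal(sum(apply(tab, 2, max)), 100)            # 100% purity
  expect_gt(sol$Q, 0.3)
  # modularity recomputed from the standard formula on the same graph
  A <- igraph::as_adjacency_matrix(sol$graph, attr = "weight", sparse = FALSE)
  k <- rowSums(A); m2 <- sum(A)
  q_direct <- 0
  for (a in 1:100) for (b in 1:100)
    if (sol$labels[a] == sol$labels[b])
      q_direct <- q_direct + A[a, b] - k[a] * k[b] / m2
  expect_equal(sol$Q, q_direct / m2, tolerance = 1e-9)
})

test_that("single family collapses to one cluster with Q near zero", {
  f1 <- make_waveform_family(40, "biphasic", noise_sd = 0.02, seed = 3)
  sol <- cluster_waveforms(f1, resolution = 0.5, seed = 1)
  expect_equal(sol$n_clusters, 1L)
  expect_equal(sol$Q, 0)
  # degenerate identical snippets: single cluster
  same <- f1[rep(1, 15), ] + 0
  sol2 <- cluster_waveforms(same, resolution = 1, seed = 1)
  expect_equal(sol2$n_clusters, 1L)
  expect_error(cluster_waveforms(f1[1:5, ]), "at least 10")
})

test_that("cluster labels are permutation-invariant under best-match", {
  f1 <- make_waveform_family(30, "biphasic", seed = 4)
  f2 <- make_waveform_family(30, "triphasic", seed = 5)
  x <- rbind(f1, f2)
  sol_a <- cluster_waveforms(x, resolution = 1, seed = 1)
  perm <- sample(60)
  sol_b <- cluster_waveforms(x[perm, ], resolution = 1, seed = 1)
  # relabel b back into a's order and best-match the label names
  lb <- integer(60); lb[perm] <- sol_b$labels
  tab <- table(sol_a$labels, lb)
  expect_equal(sum(apply(tab, 1, max)), 60)
})

test_that("resolution sweep plateaus at the family count", {
  f <- rbind(make_waveform_family(35, "biphasic", noise_sd = 0.03, seed = 6),
             make_waveform_family(35, "triphasic", noise_sd = 0.03, seed = 7))
  # third family: inverted-rebound variant, distinct by construction
  f3 <- make_waveform_family(35, "biphasic", noise_sd = 0.03, seed = 8)
  f3[, 35:61] <- -0.5 * f3[, 35:61]
  f3 <- f3 / -apply(f3, 1, min)
  sw <- resolution_sweep(rbind(f, f3), resolutions = c(0.3, 0.6, 1),
                         n_iter = 3, seed = 1)
  expect_true(any(sw$mean_n_clusters == 3))
  expect_true(all(diff(sw$mean_n_clusters) >= 0))       # non-decreasing
  # single family stays at one cluster across resolutions
  sw1 <- resolution_sweep(make_waveform_family(30, "biphasic",
                                               noise_sd = 0.02, seed = 9),
                          resolutions = c(0.3, 0.6), n_iter = 2, seed = 1)
  expect_true(all(sw1$mean_n_clusters <= 1.5))
})
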