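test_that("refractory rule removes contaminated units and keeps clean ones", {
  clean <- seq(0.1, 10, by = 0.1)                      # 100 spikes, 100 ms ISIs
  # 93 well-spaced spikes plus a run of 7 spikes 0.5 ms apart: 6 violating
  # ISIs out of 100 spikes = 6% > 5%
  dirty <- sort(c(seq(20, 112, length.out = 93), 115 + (0:6) * 5e-4))
  st <- spike_table(c(rep(1L, 100), rep(2L, 100)), c(clean, dirty))
  res <- refractory_filter(st)
  expect_equal(res$report$violation_fraction, c(0, 0.06))
  expect_equal(res$report$kept, c(TRUE, FALSE))
  expect_setequal(unique(res$spikes$unit_id), 1L)
  # fraction equals a brute-force ISI scan on a random train
  set.seed(8)
  tt <- sort(runif(500, 0, 2))
  st2 <- spike_table(rep(1L, 500), tt)
  frac <- refractory_filter(st2)$report$violation_fraction
  expect_equal(frac, sum(diff(tt) < 1e-3) / 500)
})

test_that("refractory filter is idempotent and preserves spike times", {
  set.seed(2)
  st <- spike_table(rep(1:5, each = 50), runif(250, 0, 100))
  once <- refractory_filter(st)
  twice <- refractory_filter(once$spikes)
  expect_identical(once$spikes, twice$spikes)
  kept_units <- unique(once$spikes$unit_id)
  for (u in kept_units)
    expect_identical(unit_spikes(once$spikes, u), unit_spikes(st, u))
})

test_that("duplicate removal drops the weaker unit's coincident spikes", {
  arr <- electrode_array(30, 30)
  big <- simulate_ef(arr, 0:2, 0.4, peak_amp = 120, noise_sd = 0, seed = 1)
  big$unit_id <- 1L
  small <- simulate_ef(arr, c(1L, 2L, 3L), 0.4, peak_amp = 60, noise_sd = 0,
                       seed = 2)
  small$unit_id <- 2L
  far <- simulate_ef(arr, c(600L, 601L, 602L), 0.4, peak_amp = 90,
                     noise_sd = 0, seed = 3)
  far$unit_id <- 3L
  tA <- seq(1, 50)
  st <- spike_table(rep(1:3, each = 50), c(tA, tA + 2e-4, tA + 1e-4))
  out <- remove_duplicate_spikes(st, list(big, small, far))
  expect_equal(sum(out$unit_id == 2L), 0L)          # co-located, all coincident
  expect_equal(sum(out$unit_id == 3L), 50L)         # distant pair untouched
  expect_equal(sum(out$unit_id == 1L), 50L)         # winner never loses spikes
  # idempotent
  expect_equal(remove_duplicate_spikes(out, list(big, small, far)),
               out, ignore_attr = TRUE)
  expect_error(remove_duplicate_spikes(st, list(big, small)), "unit")
})

test_that("partial duplicate overlap matches a brute-force coincidence scan", {
  arr <- electrode_array(30, 30)
  a <- simulate_ef(arr, 0:2, 0.4, peak_amp = 100, noise_sd = 0, seed = 4)
  a$unit_id <- 1L
  b <- simulate_ef(arr, 1:3, 0.4, peak_amp = 50, noise_sd = 0, seed = 5)
  b$unit_id <- 2L
  set.seed(6)
  ta <- sort(runif(200, 0, 100))
  tb <- sort(c(ta[1:80] + runif(80, -4e-4, 4e-4), runif(120, 0, 100)))
  st <- spike_table(c(rep(1L, 200), rep(2L, 200)), c(ta, tb))
  out <- remove_duplicate_spikes(st, list(a, b))
  surv_oracle <- tb[vapply(tb, function(x) min(abs(ta - x)) > 5e-4,
                           logical(1))]
  expect_equal(unit_spikes(out, 2L), sort(surv_oracle))
})

test_that("spike-triggered averaging recovers templates and scales noise", {
  set.seed(9)
  fs <- 20000; nch <- 4
  ch <- data.frame(electrode_id = 0:3, x = (0:3) * 17.5, y = 0)
  tmpl <- matrix(rnorm(nch * 101), nch, 101)
  spikes <- seq(0.05, 1.9, by = 0.05)                  # 38 repeats
  clean <- matrix(0, nch, fs * 2)
  for (t0 in spikes) {
    i0 <- round(t0 * fs) + 1
    clean[, (i0 - 40):(i0 + 60)] <- clean[, (i0 - 40):(i0 + 60)] + tmpl
  }
  # noise-free repeats reproduce the template exactly
  ef0 <- spike_triggered_ef(clean, spikes, fs, ch)
  expect_equal(ef0$waveform, tmpl)
  expect_equal(ef0$n_spikes_averaged, length(spikes))
  # i.i.d. noise SD sigma averages down as sigma / sqrt(n)
  sigma <- 2
  noisy <- clean + matrix(rnorm(length(clean), 0, sigma), nch)
  ef1 <- spike_triggered_ef(noisy, spikes, fs, ch)
  resid_sd <- sd(ef1$waveform - tmpl)
  expect_lt(abs(resid_sd - sigma / sqrt(length(spikes))),
            0.35 * sigma / sqrt(length(spikes)))
  # peak channel is the argmax of |trough|
  expect_equal(ef0$peak_channel,
               unname(which.max(apply(tmpl, 1, function(w) -min(w)))) - 1L)
  # too few spikes -> skipped with a warning
  expect_warning(out <- spike_triggered_ef(noisy, spikes[1:5], fs, ch),
                 "usable")
  expect_null(out)
})
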