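test_that("profile interpolation is linear in means and SDs", {
  p <- interpolate_profile(list(peak_freqs = c(1000, 1200),
                                mean_rate = c(10, 20),
                                rate_sd = c(2, 4)), n = 600)
  expect_equal(length(p$freqs), 600)
  expect_equal(p$mean[1], 10)
  expect_equal(p$mean[600], 20)
  # midpoint of (10 @ 1000 Hz, 20 @ 1200 Hz) -> 15 @ 1100 Hz
  expect_equal(approx(p$freqs, p$mean, 1100)$y, 15, tolerance = 1e-6)
  expect_equal(approx(p$freqs, p$sd, 1100)$y, 3, tolerance = 1e-6)
  # values at the original knots equal the originals
  knots <- interpolate_profile(list(peak_freqs = c(500, 900, 1300),
                                    mean_rate = c(5, 25, 10),
                                    rate_sd = c(1, 2, 3)), n = 401)
  expect_equal(knots$mean[c(1, 201, 401)], c(5, 25, 10))
  expect_error(interpolate_profile(list(peak_freqs = 1,
                                        mean_rate = 1, rate_sd = 0)),
               "2 conditions")
})

test_that("d-prime follows the pooled-SD form", {
  expect_equal(dprime(10, 10, 3, 5), 0)
  expect_equal(dprime(10, 13, 3, 3), 1)       # |delta mu| = common SD
  expect_equal(dprime(10, 14, 2, 2), 2)       # 4 / sqrt((4 + 4)/2)
  expect_equal(dprime(14, 10, 2, 2), 2)       # symmetric in the means
  expect_true(is.infinite(dprime(1, 2, 0, 0)))
  expect_equal(dprime(1, 1, 0, 0), 0)
})

test_that("threshold percentage uses the midpoint frequency", {
  # 48 Hz at a 1200 Hz midpoint is exactly 4 percent
  expect_equal(theta_percent(1176, 1224), 4)
  expect_equal(theta_percent(1000, 1100), 100 / 10.5)
})

test_that("flat profiles with trial noise yield no threshold", {
  p <- interpolate_profile(list(peak_freqs = seq(500, 2500, 100),
                                mean_rate = rep(30, 21),
                                rate_sd = rep(5, 21)))
  res <- find_threshold(p)
  expect_false(res$found)
  expect_true(is.na(res$theta))
})

test_that("sliding search equals the brute-force oracle", {
  for (s in 1:60) {
    p <- random_interp_profile(s)
    mine <- find_threshold(p)
    orc <- oracle_threshold(p)
    expect_identical(mine$found, orc$found)
    if (mine$found) {
      expect_equal(mine$theta, orc$theta, tolerance = 1e-12)
      expect_identical(mine$separation, orc$sep)
    }
  }
})

test_that("steeper profiles give smaller thresholds at fixed SD", {
  thetas <- vapply(c(0.02, 0.04, 0.06, 0.1), function(slope) {
    m <- 20 + slope * (seq(500, 2500, length.out = 21) - 500)
    p <- interpolate_profile(list(peak_freqs = seq(500, 2500,
                                                   length.out = 21),
                                  mean_rate = m, rate_sd = rep(4, 21)))
    find_threshold(p)$theta
  }, numeric(1))
  expect_true(all(diff(thetas) < 0))
})

test_that("thresholds are invariant to rate rescaling", {
  prof <- list(peak_freqs = seq(500, 2500, 100),
               mean_rate = 30 + 20 * sin(seq(0, 3, length.out = 21)),
               rate_sd = runif(21, 2, 4))
  r1 <- find_threshold(interpolate_profile(prof))
  prof2 <- prof
  prof2$mean_rate <- prof$mean_rate * 7
  prof2$rate_sd <- prof$rate_sd * 7
  r2 <- find_threshold(interpolate_profile(prof2))
  expect_equal(r1$theta, r2$theta)
  expect_equal(r1$f_pair, r2$f_pair)
})

test_that("measured thresholds track the analytic d-prime spacing", {
  # linear profile, constant SD: d' = 1 at spacing sd / slope
  ser_f <- seq(400, 2400, length.out = 41)
  slope <- 0.02   # sp/s per Hz
  sdv <- 3
  p <- interpolate_profile(list(peak_freqs = ser_f,
                                mean_rate = 10 + slope * ser_f,
                                rate_sd = rep(sdv, 41)))
  res <- find_threshold(p)
  predicted_df <- sdv / slope            # 150 Hz
  expect_lt(abs(diff(res$f_pair) - predicted_df) / predicted_df, 0.15)
})

test_that("vector-strength thresholds require VS structure", {
  # identical spike patterns at every condition: the VS profile is
  # exactly constant, so no pair discriminates
  nrn <- synthetic_neuron(cf = 1200, profile_shape = "flat",
                          baseline = 60, profile_amplitude = 20,
                          locking = data.frame(k = 1, m = 0.5, phase = 0))
  one <- simulate_spike_trains(nrn, 1200, n_reps = 12, seed = 71)
  conds <- seq(600, 2400, by = 200)
  spikes <- do.call(rbind, lapply(conds, function(cond)
    data.frame(condition = cond, trial = one$spikes$trial,
               time_s = one$spikes$time_s)))
  tr <- spike_train_set_from_table(
    data.frame(neuron_id = "x", condition_value = spikes$condition,
               trial = spikes$trial, spike_time_s = spikes$time_s),
    n_reps = 12)
  expect_false(vs_threshold(tr)$found)
})

test_that("RI-SPIKE thresholds demand dissimilarity above baseline", {
  mk_trains <- function(phase_slope, seed) {
    conds <- seq(1000, 1600, by = 200)
    rows <- lapply(seq_along(conds), function(ci) {
      nrn <- synthetic_neuron(cf = 1200, profile_shape = "flat",
                              baseline = 250, profile_amplitude = 10,
                              spont = 0,
                              locking = data.frame(
                                k = 1, m = 1,
                                phase = phase_slope * (ci - 1)))
      tr <- simulate_spike_trains(nrn, conds[ci], n_reps = 6,
                                  duration = 0.3, seed = seed + ci)
      data.frame(condition = conds[ci], trial = tr$spikes$trial,
                 time_s = tr$spikes$time_s)
    })
    spikes <- do.call(rbind, rows)
    spike_train_set_from_table(
      data.frame(neuron_id = "x", condition_value = spikes$condition,
                 trial = spikes$trial, spike_time_s = spikes$time_s),
      n_reps = 6)
  }
  # no condition-dependence: no threshold
  expect_false(ris_threshold(mk_trains(0, seed = 300), grid_n = 150,
                             n = 200)$found)
  # sharply condition-dependent locking phase: finite, reproducible
  r1 <- ris_threshold(mk_trains(pi / 2, seed = 300), grid_n = 150,
                      n = 200)
  r2 <- ris_threshold(mk_trains(pi / 2, seed = 800), grid_n = 150,
                      n = 200)
  expect_true(r1$found && r2$found)
  expect_lt(abs(r1$theta - r2$theta) / r1$theta, 0.2)
})

test_that("threshold trends classify by the OLS slope over level", {
  expect_equal(classify_threshold_trend(c(43, 63, 83),
                                        c(5, 5, 5))$category, "unchanging")
  tr <- classify_threshold_trend(c(43, 63, 83), c(6, 4, 2))
  expect_equal(tr$slope, -0.1)
  expect_equal(tr$category, "improving")
  expect_equal(classify_threshold_trend(c(43, 63, 83),
                                        c(2, 4, 6))$category, "worsening")
  expect_error(classify_threshold_trend(c(43, 63, 83), c(1, NA, 2)),
               "missing")
  expect_error(classify_threshold_trend(c(43, 63), c(1, 2)), "3 levels")
})
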