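make_trains <- function(spikes_df, conditions, n_reps, duration = 0.3) {
  spike_train_set_from_table(
    data.frame(neuron_id = "n1", condition_value = spikes_df$condition,
               trial = spikes_df$trial, spike_time_s = spikes_df$time_s),
    conditions = conditions, n_reps = n_reps, duration = duration)
}

test_that("rate profiles count spikes in the analysis window", {
  # one trial, 3 spikes in a 0.25 s window -> 12 sp/s
  tr <- make_trains(data.frame(condition = 1000, trial = 1,
                               time_s = c(0.06, 0.1, 0.2)), 1000, 1)
  p <- compute_rate_profile(tr, window = c(0.05, 0.30))
  expect_equal(p$mean_rate, 12)
  # default window excludes the 50 ms onset
  expect_equal(eval(formals(compute_rate_profile)$window), c(0.05, 0.30))
  expect_error(compute_rate_profile(tr, window = c(0.2, 0.2)), "window")
})

test_that("rate profiles equal brute-force per-trial counting", {
  nrn <- synthetic_neuron(cf = 1200)
  tr <- simulate_spike_trains(nrn, fixture_series(), n_reps = 7, seed = 4)
  p <- compute_rate_profile(tr)
  conds <- sort(unique(tr$conditions))
  for (ci in c(1, 10, length(conds))) {
    rates <- numeric(7)
    for (trial in 1:7) {
      st <- trial_spikes(tr, conds[ci], trial)
      rates[trial] <- sum(st >= 0.05 & st < 0.30) / 0.25
    }
    expect_equal(p$mean_rate[ci], mean(rates))
    expect_equal(p$rate_sd[ci], stats::sd(rates))
  }
})

test_that("z-scoring normalizes and flags degenerate profiles", {
  prof <- rate_profile(seq(200, 2400, by = 100),
                       50 + 30 * exp(-((1:23) - 12)^2 / 18), cf = 1200)
  z <- smooth_and_zscore(prof)
  expect_lt(abs(mean(z$z)), 1e-10)
  expect_lt(abs(stats::sd(z$z) - 1), 1e-10)
  expect_false(z$degenerate)
  # smoothing preserves the argmax of a noiseless unimodal profile
  expect_equal(which.max(z$z), 12)
  flatp <- rate_profile(seq(200, 2400, by = 100), rep(40, 23), cf = 1200)
  expect_true(smooth_and_zscore(flatp)$degenerate)
  expect_error(smooth_and_zscore(rate_profile(1:4, 1:4)), "5 conditions")
})

test_that("profiles classify as peak, dip, or sloping around CF", {
  f <- seq(200, 2400, by = 50)
  bump <- 40 + 30 * exp(-log2(f / 1200)^2 / (2 * 0.25^2))
  expect_category(classify_profile(
    smooth_and_zscore(rate_profile(f, bump, cf = 1200))), "peak")
  expect_category(classify_profile(
    smooth_and_zscore(rate_profile(f, 80 - bump, cf = 1200))), "dip")
  ramp <- 10 + 0.02 * f
  expect_category(classify_profile(
    smooth_and_zscore(rate_profile(f, ramp, cf = 1200))), "sloping")
  # a peak outside +/- 1 octave of CF does not rescue a sloping profile
  far <- 40 + 30 * exp(-log2(f / 250)^2 / (2 * 0.2^2)) + 0.005 * f
  expect_category(classify_profile(
    smooth_and_zscore(rate_profile(f, far, cf = 1400))), "sloping")
})

test_that("nearest feature to CF governs when peaks and dips coexist", {
  f <- seq(200, 2400, by = 50)
  # dip exactly at CF, peak one octave below
  y <- 50 - 25 * exp(-log2(f / 1200)^2 / (2 * 0.15^2)) +
    20 * exp(-log2(f / 600)^2 / (2 * 0.15^2))
  cls <- classify_profile(smooth_and_zscore(rate_profile(f, y, cf = 1200)))
  expect_category(cls, "dip")
  expect_lt(abs(log2(cls$feature_freq / 1200)), 0.2)
  cls2 <- classify_profile(smooth_and_zscore(rate_profile(f, y, cf = 600)))
  expect_category(cls2, "peak")
})

test_that("salience Q is the feature frequency over the 0.75-z bandwidth", {
  # symmetric triangle in z peaking at 1000 Hz whose -0.75 crossings sit
  # at 750 and 1250 Hz -> Q = 1000/500 = 2; built directly as a z_profile
  f <- seq(250, 1750, by = 125)
  tri <- 3 - abs(f - 1000) / 1000 * 3  # z drops 0.75 per 250 Hz
  zp <- structure(list(peak_freqs = f, z = tri, smoothed = tri,
                       degenerate = FALSE, cf = 1000),
                  class = "z_profile")
  cls <- classify_profile(zp, cf = 1000, min_prominence = 0)
  sal <- compute_salience(zp, cls)
  expect_equal(sal$f_p, 1000)
  expect_equal(sal$bw, 500)
  expect_equal(sal$q, 2)
  expect_false(sal$bw_clamped)
  # dip profile mirrors the peak computation after inversion
  zd <- zp
  zd$z <- -tri
  clsd <- classify_profile(zd, cf = 1000, min_prominence = 0)
  expect_category(clsd, "dip")
  expect_equal(compute_salience(zd, clsd)$q, 2)
  # halving the bandwidth at fixed f_p doubles Q
  z2 <- zp
  z2$z <- 3 - abs(f - 1000) / 500 * 3
  expect_equal(compute_salience(z2, classify_profile(z2, cf = 1000,
                                                     min_prominence = 0))$q,
               4)
  expect_error(compute_salience(zp, structure(list(category = "sloping"),
                                              class = "profile_classification")),
               "sloping")
})

test_that("salience flags bandwidths clamped at the measured range", {
  f <- seq(800, 1600, by = 50)
  z <- 1.5 - abs(f - 1200) / 1000  # never drops 0.75 below the peak
  zp <- structure(list(peak_freqs = f, z = z, smoothed = z,
                       degenerate = FALSE, cf = 1200),
                  class = "z_profile")
  sal <- compute_salience(zp, classify_profile(zp, cf = 1200,
                                               min_prominence = 0))
  expect_true(sal$bw_clamped)
  expect_equal(sal$bw, 800)
})

test_that("Q is invariant to affine rescaling of the raw rates", {
  nrn <- synthetic_neuron(cf = 1200)
  tr <- simulate_spike_trains(nrn, fixture_series(), n_reps = 20, seed = 8)
  p <- compute_rate_profile(tr, cf = 1200)
  q1 <- compute_salience(smooth_and_zscore(p),
                         classify_profile(smooth_and_zscore(p)))$q
  p2 <- p
  p2$mean_rate <- 3.7 * p$mean_rate + 11
  z2 <- smooth_and_zscore(p2)
  q2 <- compute_salience(z2, classify_profile(z2))$q
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("level trends classify by the OLS slope of Q against level", {
  expect_equal(classify_level_trend(c(43, 63, 83), c(1, 1, 1))$category,
               "unchanging")
  # slope of (1,2,3) over 40 dB is 0.05/dB, hand OLS
  tr <- classify_level_trend(c(43, 63, 83), c(1, 2, 3))
  expect_equal(tr$slope, 0.05)
  expect_equal(tr$category, "sharpening")
  expect_equal(classify_level_trend(c(43, 63, 83), c(3, 2, 1))$category,
               "broadening")
  expect_equal(classify_level_trend(c(43, 63, 83),
                                    c(1, 1.2, 1.4))$category, "unchanging")
  expect_error(classify_level_trend(c(43, 63), c(1, 2)), "3 levels")
})

test_that("MTF classification follows the two-significant-rates criteria", {
  be <- classify_mtf(mtf_record(simulate_mtf_trains(
    synthetic_neuron(mtf_type = "BE", bmf = 64, mtf_pct = 80),
    n_reps = 20, seed = 31)))
  expect_category(be, "BE")
  bs <- classify_mtf(mtf_record(simulate_mtf_trains(
    synthetic_neuron(mtf_type = "BS", wmf = 64, mtf_pct = 80),
    n_reps = 20, seed = 32)))
  expect_category(bs, "BS")
  hy <- classify_mtf(mtf_record(simulate_mtf_trains(
    synthetic_neuron(mtf_type = "hybrid", bmf = 16, wmf = 256,
                     mtf_pct = 80, mtf_width = 0.6),
    n_reps = 20, seed = 33)))
  expect_category(hy, "hybrid")
  expect_error(classify_mtf(structure(list(
    trial_rates = data.frame(mod_freq = 4, trial = 1, rate = 10),
    mod_freqs = 4), class = "mtf_record")), "unmodulated")
})

test_that("flat MTF templates rarely trigger BE or BS (type-I control)", {
  flat_ok <- 0
  false_be <- 0
  for (s in 1:50) {
    cls <- classify_mtf(mtf_record(simulate_mtf_trains(
      synthetic_neuron(mtf_type = "flat"), n_reps = 5, seed = 100 + s)))
    flat_ok <- flat_ok + (cls$category == "flat")
    false_be <- false_be + (cls$category == "BE")
  }
  expect_gte(flat_ok / 50, 0.9)
  # false-BE rate bounded by twice the per-comparison alpha (plus two
  # binomial standard errors at 50 draws)
  expect_lte(false_be / 50, 2 * 0.01 + 2 * sqrt(0.02 * 0.98 / 50))
})

test_that("windowed profiles compare early and late representations", {
  # time-homogeneous neuron: early and late windows agree
  nrn <- synthetic_neuron(cf = 1200)
  dqs <- vapply(1:6, function(s) {
    tr <- simulate_spike_trains(nrn, fixture_series(), n_reps = 30,
                                seed = 200 + s)
    windowed_profiles(tr, cf = 1200)$delta_q
  }, numeric(1))
  expect_lt(abs(median(dqs, na.rm = TRUE)), 1.5)
  # decaying modulation depth changes the late-window locking but the
  # windows themselves stay as quoted
  wp <- windowed_profiles(simulate_spike_trains(nrn, fixture_series(),
                                                n_reps = 10, seed = 99),
                          cf = 1200)
  expect_equal(wp$early$profile$analysis_window, c(0.05, 0.15))
  expect_equal(wp$late$profile$analysis_window, c(0.20, 0.30))
  # a neuron whose locking decays leaves fewer late-window spikes only in
  # the modulated components; mean rate is unchanged (mean-preserving
  # modulation), but the late-window vector strength drops
  dec <- synthetic_neuron(cf = 1200, depth_decay = 0.08,
                          locking = data.frame(k = 1, m = 0.8, phase = 0))
  tr <- simulate_spike_trains(dec, 1200, n_reps = 60, duration = 0.3,
                              seed = 77)
  st <- tr$spikes$time_s
  vs_early <- vector_strength(st[st >= 0.05 & st < 0.15], 200)
  vs_late <- vector_strength(st[st >= 0.20 & st < 0.30], 200)
  expect_gt(vs_early, vs_late + 0.05)
})
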