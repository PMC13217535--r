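fs <- 24000

test_that("gammatone filter has unit gain at CF and cat-Q10 bandwidth", {
  t <- (0:(fs - 1)) / fs
  tone <- sin(2 * pi * 1200 * t)
  y <- gammatone_filter(tone, fs, 1200)
  ss <- y[2000:20000]
  expect_equal(sqrt(mean(ss^2)), sqrt(0.5), tolerance = 0.01)
  # 10 dB bandwidth approximates CF / Q10
  bw10 <- 1200 / cat_q10(1200)
  amp_at <- function(f) {
    y <- gammatone_filter(sin(2 * pi * f * t), fs, 1200)
    sqrt(mean(y[2000:20000]^2)) * sqrt(2)
  }
  edge <- amp_at(1200 + bw10 / 2)
  expect_lt(abs(20 * log10(edge) - (-10)), 1.5)
})

test_that("front end is nonnegative, spontaneous at rest, saturating", {
  cfg <- front_end_config(1200)
  silent <- timbreIC:::new_waveform(numeric(fs / 2), fs)
  r <- front_end(silent, cfg)
  expect_true(all(r >= 0))
  expect_equal(mean(r[1000:(fs / 2 - 1000)]), cfg$spont, tolerance = 1e-6)
  # beat between two tones at cf +/- 100 Hz modulates the output at
  # the 200 Hz difference frequency
  t <- (0:(fs / 2 - 1)) / fs
  beat <- timbreIC:::new_waveform(
    0.02 * (sin(2 * pi * 1100 * t) + sin(2 * pi * 1300 * t)), fs)
  rb <- front_end(beat, cfg)
  ss <- rb[3000:11000] - mean(rb[3000:11000])
  sp <- Mod(stats::fft(ss))[1:4000]
  freqs <- (0:3999) * fs / length(ss)
  band <- freqs > 50 & freqs < 600
  expect_lt(abs(freqs[band][which.max(sp[band])] - 200), 5)
  # AM fluctuation depth shrinks as transduction saturates with level
  depth_at <- function(amp) {
    w <- timbreIC:::new_waveform(
      amp * (1 + 0.5 * sin(2 * pi * 100 * t)) * sin(2 * pi * 1200 * t),
      fs)
    rr <- front_end(w, cfg)
    s <- rr[3000:11000]
    (max(s) - min(s)) / (max(s) + min(s))
  }
  d_lo <- depth_at(0.02)
  d_hi <- depth_at(2)      # 40 dB higher
  expect_lt(d_hi, d_lo)
  expect_error(front_end_config(50), "unsupported CF")
})

test_that("energy model is linear, tuned, and phase-insensitive", {
  ser <- fixture_series()
  w <- synthesize_timbre(ser$specs[[13]], fs)
  e1 <- energy_model(w, 1200)
  w2 <- w
  w2$samples <- 2 * w$samples
  expect_equal(energy_model(w2, 1200), 2 * e1, tolerance = 1e-12)
  # maximum response across the series occurs when the stimulus peak is
  # nearest CF
  prof <- model_rate_profile("energy", ser, sample_rate = fs)
  expect_equal(ser$peak_freqs[which.max(prof$mean_rate)], 1200)
  # invariant to component phase randomization at fixed magnitudes
  spec <- ser$specs[[13]]
  comp <- components(spec)
  t <- (0:(fs * 0.5 - 1)) / fs
  set.seed(3)
  x1 <- numeric(length(t))
  x2 <- numeric(length(t))
  ph <- runif(nrow(comp), 0, 2 * pi)
  for (i in seq_len(nrow(comp))) {
    x1 <- x1 + comp$amp_rel[i] * sin(2 * pi * comp$freq_hz[i] * t)
    x2 <- x2 + comp$amp_rel[i] * sin(2 * pi * comp$freq_hz[i] * t + ph[i])
  }
  e_sine <- energy_model(timbreIC:::new_waveform(x1, fs), 1200)
  e_rand <- energy_model(timbreIC:::new_waveform(x2, fs), 1200)
  expect_lt(abs(e_rand / e_sine - 1), 0.01)
})

test_that("energy-model profile shape is level-invariant", {
  p43 <- model_rate_profile("energy",
                            fixture_series(level = 43), sample_rate = fs)
  p83 <- model_rate_profile("energy",
                            fixture_series(level = 83), sample_rate = fs)
  expect_gt(cor(p43$mean_rate, p83$mean_rate), 0.95)
})

test_that("SFIE produces BE and BS modulation transfer functions", {
  mbe <- model_mtf("sfie_be", 1200, sample_rate = fs, seed = 1)
  mbs <- model_mtf("sfie_bs", 1200, sample_rate = fs, seed = 1)
  expect_identical(classify_model_mtf(mbe, n_reps = 20, seed = 11)$category,
                   "BE")
  expect_identical(classify_model_mtf(mbs, n_reps = 20, seed = 11)$category,
                   "BS")
  # the enhancement peaks within a factor of 2 of the nominal BMF band
  fm <- mbe$mod_freq[-1]
  r <- mbe$rate[-1]
  expect_true(fm[which.max(r)] >= 32 && fm[which.max(r)] <= 128)
  # zero inhibition at both stages leaves no AM tuning (the mean rate of
  # a purely excitatory chain is modulation-independent): flat
  m0 <- model_mtf("sfie_be", 1200, sample_rate = fs,
                  sfie_cfg = sfie_config(strength_cn = 0,
                                         strength_ic = 0), seed = 1)
  expect_identical(classify_model_mtf(m0, seed = 11)$category, "flat")
  expect_error(sfie_config(tau_ex_ic = 3e-3, tau_inh_ic = 2e-3),
               "slower")
})

test_that("BMSI reduces to the excitatory pathway without inhibition and
          dips below spont with broad inhibition", {
  ser <- fixture_series()
  w <- synthesize_timbre(ser$specs[[13]], fs)
  cfg0 <- bmsi_config(off_cf_inh_strengths = c(0, 0),
                      on_cf_inh_strength = 0)
  r0 <- bmsi(w, 1200, cfg0)
  fe <- front_end_config(1200)
  cn <- sfie(front_end(w, fe), sfie_config(), fs)$cn
  excite <- timbreIC:::conv_causal(cn, timbreIC:::alpha_kernel(1e-3, fs),
                                   fs)
  expect_equal(r0$rate, pmax(excite, 0), tolerance = 1e-10)
  # broad inhibition at default strengths pushes driven rates below the
  # model's spontaneous output for some shifts
  spont <- model_spont_rate("bmsi", 1200, sample_rate = fs)
  expect_gt(spont, 0)
  prof <- model_rate_profile("bmsi", ser, sample_rate = fs)
  expect_gt(sum(prof$mean_rate < spont - 1e-6), 0)
  # and the profile classifies as a peak at CF for this configuration
  cls <- classify_profile(smooth_and_zscore(prof), cf = 1200)
  expect_identical(cls$category, "peak")
  expect_error(bmsi_config(off_cf_offsets = c(0.5, 0.5)), "opposite")
})

test_that("model comparison computes R and variance explained", {
  d <- rate_profile(seq(200, 2400, 100),
                    30 + 20 * exp(-((0:22) - 11)^2 / 20), cf = 1200)
  self <- evaluate_model(d, d)
  expect_equal(self$r, 1)
  expect_equal(self$r2, 1)
  neg <- d
  neg$mean_rate <- -d$mean_rate
  expect_equal(evaluate_model(neg, d)$r, -1)
  # hand-computed Pearson R on a 10-point fixture
  m <- rate_profile(seq(100, 1000, 100), c(3, 5, 4, 8, 9, 7, 12, 11,
                                           15, 14))
  y <- rate_profile(seq(100, 1000, 100), c(2, 6, 5, 7, 10, 8, 11, 13,
                                           14, 16))
  r_hand <- sum((m$mean_rate - mean(m$mean_rate)) *
                  (y$mean_rate - mean(y$mean_rate))) /
    sqrt(sum((m$mean_rate - mean(m$mean_rate))^2) *
           sum((y$mean_rate - mean(y$mean_rate))^2))
  expect_equal(evaluate_model(m, y)$r, r_hand, tolerance = 1e-12)
  # degenerate model profile flagged
  flat <- rate_profile(seq(100, 1000, 100), rep(5, 10))
  expect_true(evaluate_model(flat, y)$degenerate)
})

test_that("model salience does not sharpen with level (median trend)", {
  slopes <- vapply(c(800, 1600), function(cf) {
    ser <- lapply(c(43, 63, 83), function(L)
      make_shift_series(cf, increment = 50, level = L))
    qs <- vapply(ser, function(s) {
      prof <- model_rate_profile("sfie_bs", s, sample_rate = fs)
      z <- smooth_and_zscore(prof)
      cls <- classify_profile(z, cf = cf)
      if (cls$category == "sloping") return(NA_real_)
      compute_salience(z, cls)$q
    }, numeric(1))
    if (anyNA(qs)) return(NA_real_)
    classify_level_trend(c(43, 63, 83), qs)$slope
  }, numeric(1))
  expect_lte(median(slopes, na.rm = TRUE), 0.03)
})
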