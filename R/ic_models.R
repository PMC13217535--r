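# Phenomenological IC model chain. The auditory-nerve front end is a
# deliberate simplification of full biophysical AN models: a fourth-order
# gammatone filter (bandwidth from cat Q10 at CF) followed by memoryless
# saturating transduction, half-wave rectification, a 600 Hz low-pass and
# a rate mapping. It preserves the property the IC models need: the depth
# of low-frequency neural fluctuations shrinks as transduction saturates
# near spectral peaks.

#' Cat Q10 tuning sharpness at a characteristic frequency
#'
#' Power-law fit to cat auditory-nerve Q10 values,
#' `Q10 = 10^(0.4708 log10(CF/1000) + 0.4664)`.
#'
#' @param cf Characteristic frequency, Hz.
#' @return Q10 (dimensionless).
#' @export
cat_q10 <- function(cf) 10^(0.4708 * log10(cf / 1000) + 0.4664)

#' Fourth-order gammatone filter
#'
#' FIR gammatone `t^3 exp(-2 pi b t) cos(2 pi cf t)` with the bandwidth
#' parameter `b` set so the 10 dB bandwidth equals `cf / q10`
#' (`b = BW10 / (2 sqrt(10^0.25 - 1))`), normalized to unit gain at cf.
#'
#' @param x Input samples.
#' @param sample_rate Hz.
#' @param cf Center frequency, Hz.
#' @param q10 Tuning sharpness; defaults to the cat value at cf.
#' @return Filtered samples (same length, causal).
#' @export
gammatone_filter <- function(x, sample_rate, cf, q10 = cat_q10(cf)) {
  b <- (cf / q10) / (2 * sqrt(10^0.25 - 1))
  t_max <- 6 / b
  t <- seq(0, t_max, by = 1 / sample_rate)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  # unit gain at cf
  gain <- abs(sum(g * exp(-2i * pi * cf * t)))
  g <- g / gain
  fft_conv(x, g)
}

# linear convolution via zero-padded FFT (power-of-2 sizes), causal,
# trimmed to length(x)
fft_conv <- function(x, k) {
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                       stats::fft(c(k, numeric(m - length(k)))),
                     inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Front-end configuration
#'
#' @param cf Characteristic frequency, Hz (must lie in \[125, 16000\]).
#' @param q10 Tuning sharpness; default cat value at cf.
#' @param ihc_saturation Pressure scale (Pa) of the saturating
#'   transduction; inputs well below it are transduced linearly, inputs
#'   above it are compressed.
#' @param lowpass_cutoff Fluctuation low-pass cutoff, Hz.
#' @param rate_scale Rate mapping, sp/s per unit transduced output.
#' @param spont Additive spontaneous rate, sp/s.
#' @return A `front_end_config`.
#' @export
front_end_config <- function(cf, q10 = cat_q10(cf), ihc_saturation = 0.05,
                             lowpass_cutoff = 600, rate_scale = 200,
                             spont = 50) {
  if (cf < 125 || cf > 16000) stop("unsupported CF: must be 125-16000 Hz")
  if (q10 <= 0 || lowpass_cutoff <= 0) stop("q10 and cutoff must be > 0")
  structure(list(cf = cf, q10 = q10, ihc_saturation = ihc_saturation,
                 lowpass_cutoff = lowpass_cutoff, rate_scale = rate_scale,
                 spont = spont), class = "front_end_config")
}

#' Simplified auditory-nerve front end
#'
#' Gammatone (cat Q10 bandwidth) -> saturating transduction
#' (`tanh(p / ihc_saturation)`) -> half-wave rectification -> 600 Hz
#' low-pass (4th-order Butterworth, zero phase) -> nonnegative rate
#' `spont + rate_scale * fluctuation`.
#'
#' @param wave A calibrated `waveform` (Pa).
#' @param cfg A [front_end_config()].
#' @return Time-varying rate, sp/s (same sampling as the input).
#' @export
front_end <- function(wave, cfg) {
  stopifnot(inherits(wave, "waveform"), inherits(cfg, "front_end_config"))
  y <- gammatone_filter(wave$samples, wave$sample_rate, cfg$cf, cfg$q10)
  v <- pmax(tanh(y / cfg$ihc_saturation), 0)
  bf <- signal::butter(4, cfg$lowpass_cutoff / (wave$sample_rate / 2))
  lp <- signal::filtfilt(bf, v)
  pmax(cfg$spont + cfg$rate_scale * lp, 0)
}

#' Energy model response to one stimulus
#'
#' RMS output of a fourth-order gammatone filter (cat Q10 bandwidth)
#' centered on CF. The raw RMS (Pa) is returned; for profile comparison it
#' is mapped affinely onto rate by [evaluate_model()].
#'
#' @param wave A `waveform`.
#' @param cf Characteristic frequency, Hz.
#' @return RMS of the filtered waveform (Pa).
#' @export
energy_model <- function(wave, cf) {
  if (cf < 125 || cf > 16000) stop("unsupported CF: must be 125-16000 Hz")
  y <- gammatone_filter(wave$samples, wave$sample_rate, cf)
  sqrt(mean(y^2))
}

#' SFIE model configuration
#'
#' Same-frequency inhibition-excitation stages (cochlear nucleus then IC):
#' each stage convolves its input with an excitatory alpha function and
#' subtracts a delayed, scaled inhibitory alpha function, then half-wave
#' rectifies. The band-suppressed output inverts the band-enhanced drive
#' against the stage's tonic excitation.
#'
#' @param tau_ex_cn,tau_inh_cn,delay_cn,strength_cn CN-stage excitation
#'   and inhibition time constants (s), inhibition delay (s) and strength.
#' @param tau_ex_ic,tau_inh_ic,delay_ic,strength_ic IC-stage parameters.
#' @param bs_strength,bs_delay Strength and delay (s) of the BE-derived
#'   inhibition that builds the BS output.
#' @return An `sfie_config`.
#' @export
sfie_config <- function(tau_ex_cn = 0.5e-3, tau_inh_cn = 2e-3,
                        delay_cn = 1e-3, strength_cn = 0.6,
                        tau_ex_ic = 1e-3, tau_inh_ic = 2e-3,
                        delay_ic = 2e-3, strength_ic = 0.9,
                        bs_strength = 2.5, bs_delay = 1e-3) {
  if (tau_inh_cn <= tau_ex_cn || tau_inh_ic <= tau_ex_ic)
    stop("inhibition must be slower than excitation (tau_inh > tau_ex)")
  if (delay_cn < 0 || delay_ic < 0 || bs_delay < 0)
    stop("delays must be >= 0")
  structure(list(tau_ex_cn = tau_ex_cn, tau_inh_cn = tau_inh_cn,
                 delay_cn = delay_cn, strength_cn = strength_cn,
                 tau_ex_ic = tau_ex_ic, tau_inh_ic = tau_inh_ic,
                 delay_ic = delay_ic, strength_ic = strength_ic,
                 bs_strength = bs_strength, bs_delay = bs_delay),
            class = "sfie_config")
}

alpha_kernel <- function(tau, sample_rate) {
  t <- seq(0, 10 * tau, by = 1 / sample_rate)
  k <- t / tau^2 * exp(-t / tau)
  k / sum(k) * sample_rate  # unit area in continuous time
}

conv_causal <- function(x, kernel, sample_rate, delay = 0) {
  n <- length(x)
  y <- fft_conv(x, kernel) / sample_rate
  d <- round(delay * sample_rate)
  if (d > 0) y <- c(numeric(d), y[seq_len(n - d)])
  y
}

sfie_stage <- function(x, tau_ex, tau_inh, delay, strength, sample_rate) {
  e <- conv_causal(x, alpha_kernel(tau_ex, sample_rate), sample_rate)
  i <- conv_causal(x, alpha_kernel(tau_inh, sample_rate), sample_rate,
                   delay)
  pmax(e - strength * i, 0)
}

#' SFIE model: band-enhanced and band-suppressed IC responses
#'
#' @param anr Front-end rate signal (sp/s), from [front_end()].
#' @param cfg An [sfie_config()].
#' @param sample_rate Sampling rate of `anr`, Hz (>= 10 kHz).
#' @return A `model_response`: list with time-varying `be` and `bs` rates
#'   (sp/s) and the configuration.
#' @export
sfie <- function(anr, cfg = sfie_config(), sample_rate) {
  if (sample_rate < 10000) stop("anr must be sampled at >= 10 kHz")
  cn <- sfie_stage(anr, cfg$tau_ex_cn, cfg$tau_inh_cn, cfg$delay_cn,
                   cfg$strength_cn, sample_rate)
  be <- sfie_stage(cn, cfg$tau_ex_ic, cfg$tau_inh_ic, cfg$delay_ic,
                   cfg$strength_ic, sample_rate)
  tonic <- conv_causal(cn, alpha_kernel(cfg$tau_ex_ic, sample_rate),
                       sample_rate)
  d <- round(cfg$bs_delay * sample_rate)
  be_del <- if (d > 0) c(numeric(d), be[seq_len(length(be) - d)]) else be
  bs <- pmax(tonic - cfg$bs_strength * be_del, 0)
  structure(list(be = be, bs = bs, cn = cn, sample_rate = sample_rate,
                 config = cfg), class = "model_response")
}

#' BMSI model configuration
#'
#' Broadband modulation-sensitive inhibition: the on-CF cell receives
#' excitation from the on-CF cochlear-nucleus stage and inhibition from
#' three band-suppressed channels tuned below, at, and above CF.
#'
#' @param sfie An [sfie_config()] shared by all channels.
#' @param off_cf_offsets Octave offsets of the off-CF channels (below,
#'   above); must have opposite signs.
#' @param off_cf_inh_strengths Inhibition strengths of the two off-CF
#'   channels.
#' @param on_cf_inh_strength Inhibition strength of the on-CF BS channel.
#' @param inh_tau,inh_delay Alpha-function time constant and delay (s) of
#'   the broad inhibition onto the on-CF cell.
#' @return A `bmsi_config`.
#' @export
bmsi_config <- function(sfie = sfie_config(),
                        off_cf_offsets = c(-0.5, 0.5),
                        off_cf_inh_strengths = c(0.3, 0.3),
                        on_cf_inh_strength = 0.3,
                        inh_tau = 2e-3, inh_delay = 2e-3) {
  if (prod(sign(off_cf_offsets)) >= 0)
    stop("off-CF offsets must have opposite signs")
  structure(list(sfie = sfie, off_cf_offsets = off_cf_offsets,
                 off_cf_inh_strengths = off_cf_inh_strengths,
                 on_cf_inh_strength = on_cf_inh_strength,
                 inh_tau = inh_tau, inh_delay = inh_delay),
            class = "bmsi_config")
}

#' BMSI model response to one stimulus
#'
#' Three front-end + SFIE band-suppressed channels (below, at, above CF)
#' inhibit the on-CF cell, whose excitation is the on-CF
#' cochlear-nucleus stage convolved with the IC excitatory alpha
#' function. Output is half-wave rectified. With all inhibition strengths
#' zero the output equals the on-CF excitatory pathway.
#'
#' @param wave A calibrated `waveform`.
#' @param cf On-CF characteristic frequency, Hz.
#' @param cfg A [bmsi_config()].
#' @param fe_args Extra arguments to [front_end_config()].
#' @return A `model_response` with the time-varying `rate` (sp/s).
#' @export
bmsi <- function(wave, cf, cfg = bmsi_config(), fe_args = list()) {
  fs <- wave$sample_rate
  sc <- cfg$sfie
  channel <- function(ch_cf) {
    fe <- do.call(front_end_config, c(list(cf = ch_cf), fe_args))
    anr <- front_end(wave, fe)
    sfie(anr, sc, fs)
  }
  cfs <- c(cf * 2^cfg$off_cf_offsets[1], cf, cf * 2^cfg$off_cf_offsets[2])
  chans <- lapply(cfs, channel)
  on_cn <- chans[[2]]$cn
  excite <- conv_causal(on_cn, alpha_kernel(sc$tau_ex_ic, fs), fs)
  inh_kernel <- alpha_kernel(cfg$inh_tau, fs)
  strengths <- c(cfg$off_cf_inh_strengths[1], cfg$on_cf_inh_strength,
                 cfg$off_cf_inh_strengths[2])
  inh <- numeric(length(excite))
  for (k in 1:3)
    if (strengths[k] > 0)
      inh <- inh + strengths[k] *
        conv_causal(chans[[k]]$bs, inh_kernel, fs, cfg$inh_delay)
  rate <- pmax(excite - inh, 0)
  structure(list(rate = rate, channels = cfs, sample_rate = fs,
                 config = cfg), class = "model_response")
}

#' Mean steady-state rate of a model response
#' @param rate Time-varying rate, sp/s.
#' @param sample_rate Hz.
#' @param window Averaging window, s.
#' @return Mean rate, sp/s.
#' @export
mean_model_rate <- function(rate, sample_rate, window = c(0.05, Inf)) {
  i0 <- max(1, round(window[1] * sample_rate))
  i1 <- min(length(rate), round(window[2] * sample_rate))
  mean(rate[i0:i1])
}

#' Model rate profile over a shift series
#'
#' Runs one of the IC models on every stimulus of a shift series and
#' returns the deterministic rate profile (trial SDs are zero; the
#' models are trial-free).
#'
#' @param model `"energy"`, `"sfie_be"`, `"sfie_bs"` or `"bmsi"`.
#' @param series A `shift_series`.
#' @param cf Characteristic frequency, Hz (defaults to the series CF).
#' @param sample_rate Synthesis/model sampling rate, Hz.
#' @param sfie_cfg,bmsi_cfg Model configurations.
#' @param fe_args Extra [front_end_config()] arguments.
#' @param window Steady-state averaging window, s.
#' @return A `rate_profile` (with `rate_sd = 0`).
#' @export
model_rate_profile <- function(model = c("energy", "sfie_be", "sfie_bs",
                                         "bmsi"),
                               series, cf = series$cf,
                               sample_rate = 24000,
                               sfie_cfg = sfie_config(),
                               bmsi_cfg = bmsi_config(sfie = sfie_cfg),
                               fe_args = list(),
                               window = c(0.05, Inf)) {
  model <- match.arg(model)
  rates <- vapply(series$specs, function(sp) {
    w <- synthesize_timbre(sp, sample_rate)
    switch(model,
      energy = energy_model(w, cf),
      sfie_be = {
        fe <- do.call(front_end_config, c(list(cf = cf), fe_args))
        mean_model_rate(sfie(front_end(w, fe), sfie_cfg,
                             sample_rate)$be, sample_rate, window)
      },
      sfie_bs = {
        fe <- do.call(front_end_config, c(list(cf = cf), fe_args))
        mean_model_rate(sfie(front_end(w, fe), sfie_cfg,
                             sample_rate)$bs, sample_rate, window)
      },
      bmsi = mean_model_rate(bmsi(w, cf, bmsi_cfg, fe_args)$rate,
                             sample_rate, window))
  }, numeric(1))
  new_rate_profile(series$peak_freqs, rates,
                   rep(0, length(rates)), 1, cf = cf, spont = NA)
}

#' Model spontaneous output rate
#'
#' Response of the model chain to silence, used as the reference for
#' below-spontaneous suppression.
#'
#' @inheritParams model_rate_profile
#' @param duration Silent stimulus duration, s.
#' @return Spontaneous output rate, sp/s.
#' @export
model_spont_rate <- function(model = c("sfie_be", "sfie_bs", "bmsi"),
                             cf, sample_rate = 24000,
                             sfie_cfg = sfie_config(),
                             bmsi_cfg = bmsi_config(sfie = sfie_cfg),
                             fe_args = list(), duration = 0.3) {
  model <- match.arg(model)
  w <- new_waveform(numeric(round(duration * sample_rate)), sample_rate)
  if (model == "bmsi")
    return(mean_model_rate(bmsi(w, cf, bmsi_cfg, fe_args)$rate,
                           sample_rate, c(0.1, Inf)))
  fe <- do.call(front_end_config, c(list(cf = cf), fe_args))
  r <- sfie(front_end(w, fe), sfie_cfg, sample_rate)
  mean_model_rate(if (model == "sfie_be") r$be else r$bs, sample_rate,
                  c(0.1, Inf))
}

#' Model modulation transfer function
#'
#' Runs a model on an AM-noise battery and returns mean steady-state
#' rates per modulation frequency (0 = unmodulated).
#'
#' @inheritParams model_rate_profile
#' @param battery A [mtf_battery()].
#' @param seed Noise-token seed (one token per condition).
#' @return data.frame with `mod_freq` and `rate`.
#' @export
model_mtf <- function(model = c("sfie_be", "sfie_bs", "bmsi", "energy"),
                      cf, battery = mtf_battery(), sample_rate = 24000,
                      sfie_cfg = sfie_config(),
                      bmsi_cfg = bmsi_config(sfie = sfie_cfg),
                      fe_args = list(), seed = 1) {
  model <- match.arg(model)
  rates <- vapply(seq_along(battery), function(i) {
    w <- synthesize_am_noise(battery[[i]], sample_rate, seed = seed)
    switch(model,
      energy = energy_model(w, cf),
      sfie_be = ,
      sfie_bs = {
        fe <- do.call(front_end_config, c(list(cf = cf), fe_args))
        r <- sfie(front_end(w, fe), sfie_cfg, sample_rate)
        mean_model_rate(if (model == "sfie_be") r$be else r$bs,
                        sample_rate)
      },
      bmsi = mean_model_rate(bmsi(w, cf, bmsi_cfg, fe_args)$rate,
                             sample_rate))
  }, numeric(1))
  fm <- vapply(battery, function(b) ifelse(is.na(b$mod_freq), 0,
                                           b$mod_freq), numeric(1))
  data.frame(mod_freq = fm, rate = rates)
}

#' Classify a deterministic model MTF with the shared classifier
#'
#' Converts deterministic model rates into seeded Poisson trial rates
#' (the trial-to-trial variability assumed throughout) and applies
#' [classify_mtf()], so models and neurons share one MTF classifier.
#'
#' @param mtf data.frame from [model_mtf()].
#' @param n_reps Simulated trials per condition (default 5, mirroring the
#'   five diotic repetitions of the MTF protocol).
#' @param duration Trial duration, s.
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @param rate_norm Rescale model rates so their mean matches this value
#'   (sp/s) before drawing Poisson counts; `NA` = use raw rates.
#' @return As [classify_mtf()].
#' @export
classify_model_mtf <- function(mtf, n_reps = 5, duration = 1, seed = 1,
                               alpha = 0.01, rate_norm = 50) {
  r <- mtf$rate
  if (!is.na(rate_norm) && mean(r) > 0) r <- r * rate_norm / mean(r)
  trial_rates <- withr::with_seed(seed, do.call(rbind,
    lapply(seq_along(r), function(i)
      data.frame(mod_freq = mtf$mod_freq[i], trial = seq_len(n_reps),
                 rate = stats::rpois(n_reps, r[i] * duration) /
                   duration))))
  rec <- structure(list(trial_rates = trial_rates,
                        mod_freqs = sort(setdiff(mtf$mod_freq, 0))),
                   class = "mtf_record")
  classify_mtf(rec, alpha)
}

#' Compare a model rate profile with a data rate profile
#'
#' The model profile is interpolated onto the data's frequency grid and
#' mapped affinely onto rate (free gain and offset, as the models'
#' output scale is arbitrary). Reports the Pearson correlation R and the
#' variance explained R^2 of the affine-mapped prediction, plus the
#' salience/classification/threshold pipeline run on the (mapped) model
#' profile. The model is deterministic, so its threshold search borrows
#' the data profile's trial SDs.
#'
#' @param model_profile,data_profile `rate_profile`s.
#' @return List with `r`, `r2`, `mapped` (model rates on the data grid),
#'   `classification`, `salience`, `threshold`.
#' @export
evaluate_model <- function(model_profile, data_profile) {
  m <- stats::approx(model_profile$peak_freqs, model_profile$mean_rate,
                     data_profile$peak_freqs, rule = 2)$y
  y <- data_profile$mean_rate
  if (stats::sd(m) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, degenerate = TRUE))
  r <- stats::cor(m, y)
  fit <- stats::lm(y ~ m)
  mapped <- unname(stats::fitted(fit))
  r2 <- 1 - sum((y - mapped)^2) / sum((y - mean(y))^2)
  mp <- new_rate_profile(data_profile$peak_freqs, mapped,
                         data_profile$rate_sd, data_profile$n_trials,
                         cf = data_profile$cf, spont = data_profile$spont)
  z <- smooth_and_zscore(mp)
  cls <- tryCatch(classify_profile(z), error = function(e) NULL)
  sal <- if (!is.null(cls) && cls$category %in% c("peak", "dip"))
    compute_salience(z, cls) else NULL
  thr <- rate_threshold(mp)
  list(r = r, r2 = r2, mapped = mapped, classification = cls,
       salience = sal, threshold = thr, degenerate = FALSE)
}
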