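#' Specify a synthetic-timbre harmonic complex
#'
#' A synthetic-timbre stimulus is a harmonic complex tone whose component
#' levels fall off linearly in dB per octave on either side of a spectral
#' peak, giving a triangular spectral envelope on a log-frequency axis. The
#' component at `peak_freq` carries relative level 0 dB and the component at
#' frequency `f` carries `-rolloff * |log2(f / peak_freq)|` dB. Components
#' are spaced `f0` Hz apart; an optional frequency `shift` moves every
#' component (and the envelope peak) by a constant Hz offset, so shifted
#' stimuli keep their 200 Hz spacing but become inharmonic.
#'
#' @param f0 Fundamental frequency / component spacing, Hz.
#' @param peak_freq Spectral peak frequency, Hz (after any shift).
#' @param rolloff Spectral slope of the envelope, dB/octave.
#' @param upper_limit Highest component frequency allowed, Hz.
#' @param level Overall sound level, dB SPL (RMS re 20 micro-Pa, measured on
#'   the steady-state portion, ramps excluded).
#' @param duration Stimulus duration, s.
#' @param ramp Raised-cosine on/off ramp duration, s.
#' @param shift Constant frequency offset applied to all components, Hz.
#' @param phase_mode Component starting phase; only `"sine"` is supported.
#'
#' @return An object of class `harmonic_complex_spec`.
#' @examples
#' spec <- harmonic_complex_spec(f0 = 200, peak_freq = 1200)
#' components(spec)[1:3, ]
#' @export
harmonic_complex_spec <- function(f0 = 200, peak_freq = 1200, rolloff = 24,
                                  upper_limit = 10000, level = 63,
                                  duration = 0.3, ramp = 0.02, shift = 0,
                                  phase_mode = "sine") {
  if (!is.finite(f0) || f0 <= 0) stop("invalid spec: f0 must be > 0")
  if (!is.finite(peak_freq) || peak_freq <= 0)
    stop("invalid spec: peak_freq must be > 0")
  if (rolloff < 0) stop("invalid spec: rolloff must be >= 0")
  if (duration <= 0 || ramp < 0 || 2 * ramp > duration)
    stop("invalid spec: need 0 <= 2*ramp <= duration")
  phase_mode <- match.arg(phase_mode, "sine")
  structure(list(f0 = f0, peak_freq = peak_freq, rolloff = rolloff,
                 upper_limit = upper_limit, level = level,
                 duration = duration, ramp = ramp, shift = shift,
                 phase_mode = phase_mode),
            class = "harmonic_complex_spec")
}

#' @export
print.harmonic_complex_spec <- function(x, ...) {
  cat(sprintf(
    "harmonic_complex_spec: f0 %g Hz, peak %g Hz, rolloff %g dB/oct,\n  %g dB SPL, %g s (+%g s ramps), shift %g Hz, %d components <= %g Hz\n",
    x$f0, x$peak_freq, x$rolloff, x$level, x$duration, x$ramp, x$shift,
    nrow(components(x)), x$upper_limit))
  invisible(x)
}

#' Component table of a harmonic complex
#'
#' Frequencies, relative levels (dB re the peak component) and starting
#' phases of every component of the stimulus. Components sit at
#' `k * f0 + shift` for integer k, restricted to (0, `upper_limit`].
#'
#' @param spec A `harmonic_complex_spec`.
#' @return A data.frame with columns `freq_hz`, `amp_rel_db`, `amp_rel`
#'   (linear, peak component = 1) and `phase_rad`.
#' @export
components <- function(spec) {
  stopifnot(inherits(spec, "harmonic_complex_spec"))
  k <- seq_len(floor((spec$upper_limit - spec$shift) / spec$f0))
  freq <- k * spec$f0 + spec$shift
  freq <- freq[freq > 0 & freq <= spec$upper_limit]
  rel_db <- -spec$rolloff * abs(log2(freq / spec$peak_freq))
  data.frame(freq_hz = freq,
             amp_rel_db = rel_db,
             amp_rel = 10^(rel_db / 20),
             phase_rad = 0)
}

PA_REF <- 20e-6  # dB SPL reference pressure, Pa

#' @keywords internal
raised_cosine_ramp <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    t <- seq_len(n_ramp) / n_ramp
    on <- 0.5 - 0.5 * cos(pi * t)
    # first sample is exactly 0
    on <- c(0, on[-n_ramp])
    env[seq_len(n_ramp)] <- on
    env[n - n_ramp + seq_len(n_ramp)] <- rev(on)
  }
  env
}

new_waveform <- function(samples, sample_rate, meta = list()) {
  structure(list(samples = samples, sample_rate = sample_rate, meta = meta),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.3f s), %.1f dB SPL\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, spl(x)))
  invisible(x)
}

#' Sound pressure level of a calibrated waveform
#'
#' RMS level in dB re 20 micro-Pa. By default the on/off ramps recorded in
#' the waveform metadata are excluded from the RMS window.
#'
#' @param wave A `waveform` (samples in Pa).
#' @param exclude_ramps Exclude ramped samples from the RMS window?
#' @return Level in dB SPL.
#' @export
spl <- function(wave, exclude_ramps = TRUE) {
  x <- wave$samples
  n_ramp <- wave$meta$n_ramp %||% 0
  if (exclude_ramps && n_ramp > 0 && length(x) > 2 * n_ramp)
    x <- x[(n_ramp + 1):(length(x) - n_ramp)]
  20 * log10(sqrt(mean(x^2)) / PA_REF)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a synthetic-timbre harmonic complex
#'
#' Deterministically renders the stimulus described by `spec`: components in
#' sine starting phase, triangular dB envelope around the spectral peak,
#' raised-cosine ramps, and an overall scale such that the steady-state RMS
#' equals `spec$level` dB SPL.
#'
#' @param spec A [harmonic_complex_spec()].
#' @param sample_rate Sampling rate, Hz; must be at least twice the highest
#'   component frequency.
#' @return A `waveform` (samples in Pa) whose `meta$components` holds the
#'   component table with calibrated peak amplitudes (`amp_pa`).
#' @examples
#' w <- synthesize_timbre(harmonic_complex_spec())
#' spl(w)
#' @export
synthesize_timbre <- function(spec, sample_rate = 48000) {
  stopifnot(inherits(spec, "harmonic_complex_spec"))
  comp <- components(spec)
  if (nrow(comp) == 0) stop("invalid spec: no components below upper_limit")
  if (sample_rate < 2 * max(comp$freq_hz))
    stop("aliasing: sample_rate below twice the highest component frequency")
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (i in seq_len(nrow(comp)))
    x <- x + comp$amp_rel[i] * sin(2 * pi * comp$freq_hz[i] * t +
                                     comp$phase_rad[i])
  # calibrate on the steady-state (unramped) portion
  n_ramp <- round(spec$ramp * sample_rate)
  steady <- if (n > 2 * n_ramp) x[(n_ramp + 1):(n - n_ramp)] else x
  target_rms <- PA_REF * 10^(spec$level / 20)
  scale <- target_rms / sqrt(mean(steady^2))
  x <- x * scale * raised_cosine_ramp(n, n_ramp)
  comp$amp_pa <- comp$amp_rel * scale
  new_waveform(x, sample_rate,
               meta = list(spec = spec, components = comp, n_ramp = n_ramp))
}

#' Build a shifted synthetic-timbre stimulus series
#'
#' The reference stimulus has its spectral peak at the multiple of `f0`
#' nearest to the neuron's characteristic frequency. The whole spectrum is
#' then shifted in constant-Hz increments so that the peak covers six
#' harmonics above and below the reference, floored at 200 Hz at the
#' low-frequency end.
#'
#' @param cf Characteristic frequency of the neuron, Hz.
#' @param f0 Component spacing, Hz.
#' @param increment Shift increment, Hz; must lie in \[35, 50\].
#' @param n_harmonics Harmonic span on each side of the reference peak.
#' @param floor_hz Lowest allowed peak frequency, Hz.
#' @param ... Further arguments to [harmonic_complex_spec()] (level,
#'   duration, rolloff, ...).
#' @return An object of class `shift_series`: list of specs plus
#'   `peak_freqs`, `cf`, and `reference_peak`.
#' @examples
#' s <- make_shift_series(cf = 1326, f0 = 200)
#' s$reference_peak   # 1400: nearest multiple of 200 to 1326
#' range(s$peak_freqs)
#' @export
make_shift_series <- function(cf, f0 = 200, increment = 40,
                              n_harmonics = 6, floor_hz = 200, ...) {
  if (cf <= 0) stop("cf must be positive")
  if (increment < 35 || increment > 50)
    stop("increment must lie in [35, 50] Hz")
  ref_peak <- max(1, round(cf / f0)) * f0
  shifts <- seq(-n_harmonics * f0, n_harmonics * f0, by = increment)
  peaks <- ref_peak + shifts
  keep <- peaks >= floor_hz
  if (!any(keep)) stop("degenerate series: floored peak range is empty")
  shifts <- shifts[keep]
  peaks <- peaks[keep]
  specs <- lapply(shifts, function(s)
    harmonic_complex_spec(f0 = f0, peak_freq = ref_peak + s, shift = s, ...))
  structure(list(specs = specs, peak_freqs = peaks, shifts = shifts,
                 cf = cf, f0 = f0, reference_peak = ref_peak),
            class = "shift_series")
}

#' @export
print.shift_series <- function(x, ...) {
  cat(sprintf(
    "shift_series: cf %g Hz, reference peak %g Hz, %d stimuli, peaks %g-%g Hz\n",
    x$cf, x$reference_peak, length(x$peak_freqs), min(x$peak_freqs),
    max(x$peak_freqs)))
  invisible(x)
}

#' Specify sinusoidally amplitude-modulated Gaussian noise
#'
#' @param carrier_band Two-element band edges, Hz.
#' @param mod_freq Modulation frequency, Hz; `NA` or 0 means unmodulated.
#' @param mod_depth Modulation depth, 0-1.
#' @param spectrum_level Spectrum level of the unmodulated carrier,
#'   dB SPL per Hz.
#' @param duration Duration, s.
#' @param ramp Raised-cosine ramp, s.
#' @return An `am_noise_spec`.
#' @export
am_noise_spec <- function(carrier_band = c(100, 10000), mod_freq = NA,
                          mod_depth = 1, spectrum_level = 33,
                          duration = 1, ramp = 0.05) {
  if (mod_depth < 0 || mod_depth > 1)
    stop("invalid spec: mod_depth must lie in [0, 1]")
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1])
    stop("invalid spec: bad carrier band")
  structure(list(carrier_band = carrier_band, mod_freq = mod_freq,
                 mod_depth = mod_depth, spectrum_level = spectrum_level,
                 duration = duration, ramp = ramp),
            class = "am_noise_spec")
}

#' Modulation-frequency battery for MTF measurement
#'
#' Modulation frequencies from `from` to `to` Hz at `steps_per_octave`
#' logarithmic steps per octave, preceded by the unmodulated reference
#' condition (`mod_freq = NA`).
#'
#' @param from,to Modulation frequency range, Hz.
#' @param steps_per_octave Frequencies per octave.
#' @param ... Passed to [am_noise_spec()].
#' @return List of `am_noise_spec`s; the first is the unmodulated reference.
#' @export
mtf_battery <- function(from = 2, to = 600, steps_per_octave = 3, ...) {
  fm <- from * 2^(seq(0, log2(to / from), by = 1 / steps_per_octave))
  c(list(am_noise_spec(mod_freq = NA, ...)),
    lapply(fm, function(f) am_noise_spec(mod_freq = f, ...)))
}

#' Synthesize an AM-noise token
#'
#' Seeded, reproducible Gaussian noise band-limited to the carrier band
#' (FFT brick-wall), scaled so the unmodulated carrier sits at the
#' configured spectrum level, then multiplied by
#' `1 + mod_depth * sin(2 pi mod_freq t)` and ramped. Depth 0 or
#' `mod_freq = NA` reproduces the unmodulated token bit-for-bit at the same
#' seed.
#'
#' @param spec An [am_noise_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed for the noise token.
#' @return A `waveform` in Pa.
#' @export
synthesize_am_noise <- function(spec, sample_rate = 48000, seed = 1) {
  stopifnot(inherits(spec, "am_noise_spec"))
  if (spec$carrier_band[2] >= sample_rate / 2)
    stop("aliasing: carrier band exceeds Nyquist")
  n <- round(spec$duration * sample_rate)
  x <- withr::with_seed(seed, stats::rnorm(n))
  # brick-wall bandpass by zeroing FFT bins outside the carrier band
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)  # mirrored bin frequencies
  keep <- f >= spec$carrier_band[1] & f <= spec$carrier_band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  bw <- diff(spec$carrier_band)
  target_rms <- PA_REF * 10^((spec$spectrum_level + 10 * log10(bw)) / 20)
  x <- x * target_rms / sqrt(mean(x^2))
  if (!is.na(spec$mod_freq) && spec$mod_freq > 0 && spec$mod_depth > 0) {
    t <- (seq_len(n) - 1) / sample_rate
    x <- x * (1 + spec$mod_depth * sin(2 * pi * spec$mod_freq * t))
  }
  n_ramp <- round(spec$ramp * sample_rate)
  x <- x * raised_cosine_ramp(n, n_ramp)
  new_waveform(x, sample_rate, meta = list(spec = spec, n_ramp = n_ramp,
                                           seed = seed))
}

#' Synthesize a raised-cosine ramped pure tone
#'
#' @param freq Tone frequency, Hz.
#' @param level Level, dB SPL (steady-state RMS).
#' @param duration Duration, s.
#' @param ramp Raised-cosine ramp, s.
#' @param sample_rate Sampling rate, Hz.
#' @return A `waveform` in Pa.
#' @export
synthesize_pure_tone <- function(freq, level = 70, duration = 0.2,
                                 ramp = 0.01, sample_rate = 48000) {
  if (freq >= sample_rate / 2) stop("aliasing: freq above Nyquist")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  amp <- sqrt(2) * PA_REF * 10^(level / 20)  # peak amp for target RMS
  n_ramp <- round(ramp * sample_rate)
  x <- amp * sin(2 * pi * freq * t) * raised_cosine_ramp(n, n_ramp)
  new_waveform(x, sample_rate,
               meta = list(freq = freq, level = level, n_ramp = n_ramp))
}

#' Pure-tone frequency battery
#'
#' Geometrically spaced tone frequencies used to estimate characteristic
#' frequency: `from` to `to` Hz at `steps_per_octave` steps per octave.
#'
#' @param from,to Frequency range, Hz.
#' @param steps_per_octave Tones per octave.
#' @return Numeric vector of frequencies, Hz.
#' @export
pure_tone_battery <- function(from = 250, to = 16000, steps_per_octave = 5) {
  from * 2^(seq(0, log2(to / from), by = 1 / steps_per_octave))
}
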