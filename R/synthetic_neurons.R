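#' Specify a synthetic IC-like neuron
#'
#' Ground-truth neuron whose mean rate versus stimulus spectral-peak
#' frequency follows a closed-form profile on a log2-frequency axis:
#' a Gaussian bump (`peak`), an inverted bump (`dip`), a linear-in-octaves
#' ramp (`sloping`), or a constant (`flat`), on top of the spontaneous
#' rate. Instantaneous rate is modulated at integer multiples of the
#' stimulus fundamental with per-harmonic depths (`locking`), and the
#' modulation-transfer-function class (`mtf_type`) controls responses to
#' amplitude-modulated noise.
#'
#' @param cf Characteristic frequency, Hz; profile features are centered on
#'   `profile_center` (defaults to `cf`).
#' @param spont Spontaneous rate, sp/s.
#' @param profile_shape One of `"peak"`, `"dip"`, `"sloping"`, `"flat"`.
#' @param profile_center Center of the bump/dip, Hz.
#' @param profile_width Width (Gaussian SD) of the bump/dip, octaves.
#'   The default (`NULL`) is tuning-matched: half the cat-Q10 10-dB
#'   bandwidth at CF expressed in octaves, floored at 0.2, so that
#'   high-CF neurons have realistically narrow profiles in octaves.
#' @param profile_amplitude Bump/dip amplitude (and flat elevation), sp/s.
#' @param baseline Driven baseline rate added to `spont` for all shapes,
#'   sp/s.
#' @param baseline_slope Sloping-baseline slope, sp/s per octave
#'   (re `profile_center`).
#' @param locking Data frame with columns `k` (harmonic index of f0), `m`
#'   (modulation depth, 0-1) and `phase` (rad); `sum(m)` must be <= 1.
#' @param mtf_type `"BE"`, `"BS"`, `"hybrid"` or `"flat"`.
#' @param bmf,wmf Best/worst modulation frequency, Hz.
#' @param mtf_pct Percent rate change at BMF/WMF relative to the
#'   unmodulated rate.
#' @param mtf_width MTF tuning width, octaves.
#' @param depth_decay Exponential time constant (s) over which locking
#'   depths decay during the stimulus; `Inf` = time-homogeneous.
#' @return A `synthetic_neuron`.
#' @examples
#' nrn <- synthetic_neuron(cf = 1200, profile_shape = "peak")
#' truth_rate(nrn, c(600, 1200, 2400))
#' @export
synthetic_neuron <- function(cf = 1200, spont = 10,
                             profile_shape = c("peak", "dip", "sloping",
                                               "flat"),
                             profile_center = cf, profile_width = NULL,
                             profile_amplitude = 30, baseline = 30,
                             baseline_slope = 15,
                             locking = data.frame(k = 1, m = 0.4, phase = 0),
                             mtf_type = c("BS", "BE", "hybrid", "flat"),
                             bmf = 64, wmf = 64, mtf_pct = 50,
                             mtf_width = 0.8, depth_decay = Inf) {
  profile_shape <- match.arg(profile_shape)
  mtf_type <- match.arg(mtf_type)
  if (spont < 0) stop("spont must be >= 0")
  if (is.null(profile_width)) {
    bw10 <- cf / cat_q10(cf)
    profile_width <- max(0.2, 0.5 * log2((cf + bw10 / 2) /
                                           max(cf - bw10 / 2, 1)))
  }
  if (nrow(locking) > 0 && sum(locking$m) > 1 + 1e-12)
    stop("invalid spec: sum of locking depths exceeds 1 (negative rate)")
  nrn <- structure(list(cf = cf, spont = spont,
                        profile_shape = profile_shape,
                        profile_center = profile_center,
                        profile_width = profile_width,
                        profile_amplitude = profile_amplitude,
                        baseline = baseline,
                        baseline_slope = baseline_slope,
                        locking = locking, mtf_type = mtf_type,
                        bmf = bmf, wmf = wmf, mtf_pct = mtf_pct,
                        mtf_width = mtf_width, depth_decay = depth_decay),
                   class = "synthetic_neuron")
  if (profile_shape == "dip" &&
      spont + baseline - profile_amplitude < 0)
    stop("invalid spec: dip profile goes negative")
  nrn
}

#' @export
print.synthetic_neuron <- function(x, ...) {
  cat(sprintf(
    "synthetic_neuron: cf %g Hz, spont %g sp/s, %s profile, %s MTF\n",
    x$cf, x$spont, x$profile_shape, x$mtf_type))
  invisible(x)
}

#' Ground-truth mean rate of a synthetic neuron
#'
#' Closed-form mean rate (sp/s) at a given stimulus spectral-peak
#' frequency; the analytic quantity that rate-profile analyses should
#' recover.
#'
#' @param neuron A [synthetic_neuron()].
#' @param peak_freq Spectral-peak frequency (vectorized), Hz.
#' @return Mean rate(s), sp/s.
#' @export
truth_rate <- function(neuron, peak_freq) {
  stopifnot(inherits(neuron, "synthetic_neuron"))
  x <- log2(peak_freq / neuron$profile_center)  # octaves re center
  base <- neuron$spont + neuron$baseline
  r <- switch(neuron$profile_shape,
    flat = rep(base + neuron$profile_amplitude, length(x)),
    peak = base + neuron$profile_amplitude * exp(-x^2 /
             (2 * neuron$profile_width^2)),
    dip = base - neuron$profile_amplitude * exp(-x^2 /
             (2 * neuron$profile_width^2)),
    sloping = base + neuron$baseline_slope * x)
  pmax(r, 0)
}

#' @keywords internal
#' Inhomogeneous Poisson spike times on [0, duration] by thinning.
rpoisson_inhom <- function(rate_fn, duration, rate_max) {
  if (rate_max <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * duration)
  t <- sort(stats::runif(n, 0, duration))
  t[stats::runif(n) < rate_fn(t) / rate_max]
}

#' Simulate trial-wise spike trains for a shift series
#'
#' Each condition (stimulus spectral-peak frequency) drives an
#' inhomogeneous Poisson process with rate
#' `lambda(t) = truth_rate * (1 + sum_k m_k cos(2 pi k f0 t + phi_k))`,
#' optionally with depths decaying over the stimulus (`depth_decay`), and
#' an optional absolute dead time. Fully reproducible given `seed`.
#'
#' @param neuron A [synthetic_neuron()].
#' @param series A [make_shift_series()] result (or a numeric vector of
#'   peak frequencies, in which case `f0` is taken from the neuron's
#'   stimulus default of 200 Hz).
#' @param n_reps Trials per condition.
#' @param duration Stimulus duration, s.
#' @param seed Integer seed.
#' @param dead_time Absolute refractory period, s (0 disables).
#' @param f0 Fundamental used for the locking harmonics, Hz (ignored when
#'   `series` is a `shift_series`).
#' @return A `spike_train_set`: data frame `spikes` (condition, trial,
#'   time_s) plus the condition axis and duration.
#' @export
simulate_spike_trains <- function(neuron, series, n_reps = 30,
                                  duration = 0.3, seed = 1,
                                  dead_time = 0, f0 = 200) {
  stopifnot(inherits(neuron, "synthetic_neuron"), n_reps >= 1)
  if (inherits(series, "shift_series")) {
    peaks <- series$peak_freqs
    f0 <- series$f0
  } else peaks <- as.numeric(series)
  lk <- neuron$locking
  mod_of <- function(t) {
    mod <- rep(1, length(t))
    if (nrow(lk) > 0) {
      decay <- if (is.finite(neuron$depth_decay))
        exp(-t / neuron$depth_decay) else 1
      for (j in seq_len(nrow(lk)))
        mod <- mod + decay * lk$m[j] *
          cos(2 * pi * lk$k[j] * f0 * t + lk$phase[j])
    }
    mod
  }
  mod_max <- 1 + if (nrow(lk) > 0) sum(lk$m) else 0
  withr::with_seed(seed, {
    out <- vector("list", length(peaks))
    for (ci in seq_along(peaks)) {
      r0 <- truth_rate(neuron, peaks[ci])
      # thinning, vectorized over all trials of this condition
      counts <- stats::rpois(n_reps, r0 * mod_max * duration)
      t_all <- stats::runif(sum(counts), 0, duration)
      trial_all <- rep(seq_len(n_reps), counts)
      keep <- stats::runif(length(t_all)) < mod_of(t_all) / mod_max
      t_all <- t_all[keep]
      trial_all <- trial_all[keep]
      ord <- order(trial_all, t_all)
      t_all <- t_all[ord]
      trial_all <- trial_all[ord]
      if (dead_time > 0 && length(t_all) > 1) {
        keep <- logical(length(t_all))
        last <- -Inf
        last_tr <- -1L
        for (i in seq_along(t_all)) {
          if (trial_all[i] != last_tr || t_all[i] - last >= dead_time) {
            keep[i] <- TRUE
            last <- t_all[i]
            last_tr <- trial_all[i]
          }
        }
        t_all <- t_all[keep]
        trial_all <- trial_all[keep]
      }
      out[[ci]] <- list(condition = rep(peaks[ci], length(t_all)),
                        trial = trial_all, time_s = t_all)
    }
  })
  spikes <- data.frame(
    condition = unlist(lapply(out, `[[`, "condition")),
    trial = unlist(lapply(out, `[[`, "trial")),
    time_s = unlist(lapply(out, `[[`, "time_s")))
  new_spike_train_set(spikes, conditions = peaks, n_reps = n_reps,
                      duration = duration,
                      condition_type = "peak_freq_hz")
}

new_spike_train_set <- function(spikes, conditions, n_reps, duration,
                                condition_type) {
  structure(list(spikes = spikes, conditions = conditions,
                 n_reps = n_reps, duration = duration,
                 condition_type = condition_type),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "spike_train_set: %d conditions (%s) x %d trials, %.3f s, %d spikes\n",
    length(x$conditions), x$condition_type, x$n_reps, x$duration,
    nrow(x$spikes)))
  invisible(x)
}

#' Spike times of one trial
#' @param trains A `spike_train_set`.
#' @param condition Condition value.
#' @param trial Trial number.
#' @return Numeric vector of spike times, s.
#' @export
trial_spikes <- function(trains, condition, trial) {
  s <- trains$spikes
  s$time_s[s$condition == condition & s$trial == trial]
}

#' @keywords internal
#' Mean rate template of the configured MTF type at modulation freq fm.
mtf_template_rate <- function(neuron, fm) {
  unmod <- neuron$spont + neuron$baseline
  if (is.na(fm)) return(unmod)
  g <- function(f0) exp(-log2(fm / f0)^2 / (2 * neuron$mtf_width^2))
  delta <- switch(neuron$mtf_type,
    flat = 0,
    BE = neuron$mtf_pct / 100 * g(neuron$bmf),
    BS = -neuron$mtf_pct / 100 * g(neuron$wmf),
    hybrid = neuron$mtf_pct / 100 * (g(neuron$bmf) - g(neuron$wmf)))
  max(unmod * (1 + delta), 0)
}

#' Simulate spike trains for an MTF battery
#'
#' Trial rates follow the neuron's MTF template (Gaussian enhancement
#' and/or suppression in log modulation frequency around BMF/WMF); spikes
#' are homogeneous Poisson within each trial. The condition axis stores the
#' modulation frequency, with `NA` coded as 0 for the unmodulated
#' reference.
#'
#' @param neuron A [synthetic_neuron()].
#' @param battery List of [am_noise_spec()]s including the unmodulated
#'   reference (see [mtf_battery()]).
#' @param n_reps Trials per condition.
#' @param seed Integer seed.
#' @return A `spike_train_set` with `condition_type = "mod_freq_hz"`.
#' @export
simulate_mtf_trains <- function(neuron, battery = mtf_battery(),
                                n_reps = 5, seed = 1) {
  stopifnot(inherits(neuron, "synthetic_neuron"))
  fms <- vapply(battery, function(b) b$mod_freq, numeric(1))
  if (!any(is.na(fms)))
    stop("battery must include the unmodulated reference condition")
  dur <- battery[[1]]$duration
  conds <- ifelse(is.na(fms), 0, fms)
  withr::with_seed(seed, {
    out <- list()
    for (ci in seq_along(battery)) {
      r <- mtf_template_rate(neuron, fms[ci])
      for (tr in seq_len(n_reps)) {
        n <- stats::rpois(1, r * dur)
        if (n > 0)
          out[[length(out) + 1L]] <-
            data.frame(condition = conds[ci], trial = tr,
                       time_s = sort(stats::runif(n, 0, dur)))
      }
    }
  })
  spikes <- if (length(out)) do.call(rbind, out) else
    data.frame(condition = numeric(0), trial = integer(0),
               time_s = numeric(0))
  new_spike_train_set(spikes, conditions = conds, n_reps = n_reps,
                      duration = dur, condition_type = "mod_freq_hz")
}

#' Generate a population of synthetic neurons
#'
#' Characteristic frequencies are log-uniform over `cf_range` (emulating a
#' recorded IC population spanning roughly 320-9,236 Hz) and shapes/MTF
#' types are drawn from the supplied proportions.
#'
#' @param n Number of neurons.
#' @param cf_range CF range, Hz.
#' @param shape_probs Named proportions over peak/dip/sloping.
#' @param mtf_probs Named proportions over BE/BS/hybrid/flat.
#' @param seed Integer seed.
#' @param ... Further arguments to [synthetic_neuron()].
#' @return List of `synthetic_neuron`s.
#' @export
synthetic_population <- function(n = 20, cf_range = c(320, 9236),
                                 shape_probs = c(peak = 0.81, dip = 0.10,
                                                 sloping = 0.09),
                                 mtf_probs = c(BE = 0.239, BS = 0.548,
                                               hybrid = 0.128,
                                               flat = 0.085),
                                 seed = 1, ...) {
  withr::with_seed(seed, {
    cfs <- 2^stats::runif(n, log2(cf_range[1]), log2(cf_range[2]))
    shapes <- sample(names(shape_probs), n, replace = TRUE,
                     prob = shape_probs)
    mtfs <- sample(names(mtf_probs), n, replace = TRUE, prob = mtf_probs)
  })
  lapply(seq_len(n), function(i)
    synthetic_neuron(cf = cfs[i], profile_shape = shapes[i],
                     mtf_type = mtfs[i], ...))
}
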