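#' Period histogram of spike times
#'
#' Spike phases are folded modulo one period of the analysis frequency,
#' binned, and normalized so the fullest bin equals 1.
#'
#' @param spikes Spike times, s.
#' @param freq Analysis frequency, Hz (200 Hz here folds one cycle of the
#'   component spacing).
#' @param n_bins Bins per period.
#' @return A `period_histogram`: `breaks` (phase, cycles), `counts`,
#'   `normalized`, `empty` flag.
#' @export
period_histogram <- function(spikes, freq = 200, n_bins = 32) {
  if (freq <= 0) stop("freq must be positive")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  if (length(spikes) == 0) {
    return(structure(list(breaks = breaks, counts = rep(0L, n_bins),
                          normalized = rep(0, n_bins), freq = freq,
                          empty = TRUE), class = "period_histogram"))
  }
  phase <- (spikes * freq) %% 1
  counts <- tabulate(pmin(floor(phase * n_bins) + 1L, n_bins), n_bins)
  structure(list(breaks = breaks, counts = counts,
                 normalized = counts / max(counts), freq = freq,
                 empty = FALSE),
            class = "period_histogram")
}

#' @export
plot.period_histogram <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$normalized, names.arg = round(mids, 2), space = 0,
                    xlab = sprintf("Phase (cycles of %g Hz)", x$freq),
                    ylab = "Normalized count", ...)
  invisible(x)
}

#' Vector strength of phase locking
#'
#' Resultant length of unit phasors at the spike phases:
#' `VS = |mean(exp(2 pi i f t_spikes))|`, in \[0, 1\]; 1 means perfect
#' locking, 0 a uniform phase distribution. For a raised-cosine rate
#' modulation of depth m, VS converges to m/2.
#'
#' @param spikes Spike times, s.
#' @param freq Analysis frequency, Hz.
#' @return VS in \[0, 1\], or `NA` with zero spikes.
#' @export
vector_strength <- function(spikes, freq) {
  n <- length(spikes)
  if (n == 0) return(NA_real_)
  ph <- 2 * pi * freq * spikes
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}

#' Rayleigh test for significant phase locking
#'
#' Asymptotic p-value for the Rayleigh statistic `2 n VS^2` (chi-squared
#' with 2 df under uniformity), `p = exp(-n VS^2)`. A warning attribute is
#' set for small samples (n < 10) where the asymptotic p is unreliable.
#'
#' @param spikes Spike times, s.
#' @param freq Analysis frequency, Hz.
#' @return p-value, with attributes `statistic` (2 n VS^2), `n`, and
#'   `small_sample`.
#' @export
rayleigh_significance <- function(spikes, freq) {
  n <- length(spikes)
  if (n == 0) return(structure(NA_real_, statistic = NA_real_, n = 0L,
                               small_sample = TRUE))
  vs <- vector_strength(spikes, freq)
  p <- exp(-n * vs^2)
  structure(p, statistic = 2 * n * vs^2, n = n, small_sample = n < 10)
}

#' Vector-strength profile across stimulus conditions
#'
#' Pooled-spike vector strength at each condition for the fundamental and
#' its integer multiples (`k * f0`), with Rayleigh p-values per cell.
#'
#' @param trains A `spike_train_set` (condition axis = spectral peak
#'   frequency).
#' @param f0 Fundamental frequency, Hz.
#' @param harmonics Integer multiples of `f0` to analyze.
#' @param window Analysis window, s.
#' @return A `vs_profile`: matrices `vs` and `p`
#'   (condition x harmonic), `conditions`, `freqs`.
#' @export
vs_profile <- function(trains, f0 = 200, harmonics = 1:6,
                       window = c(0.05, 0.30)) {
  stopifnot(inherits(trains, "spike_train_set"))
  conds <- sort(unique(trains$conditions))
  freqs <- harmonics * f0
  vs <- p <- matrix(NA_real_, length(conds), length(freqs),
                    dimnames = list(NULL, paste0(freqs, "Hz")))
  for (ci in seq_along(conds)) {
    st <- trains$spikes
    sp <- st$time_s[st$condition == conds[ci] & st$time_s >= window[1] &
                      st$time_s < window[2]]
    for (k in seq_along(freqs)) {
      vs[ci, k] <- vector_strength(sp, freqs[k])
      p[ci, k] <- as.numeric(rayleigh_significance(sp, freqs[k]))
    }
  }
  structure(list(vs = vs, p = p, conditions = conds, freqs = freqs,
                 f0 = f0), class = "vs_profile")
}

#' Classify a vector-strength profile as peak, dip, or flat
#'
#' Applies the same smoothed/z-scored prominence machinery as the rate
#' classifier to the VS-versus-peak-frequency profile at the fundamental;
#' profiles with neither a peak nor a dip near CF are `flat`.
#'
#' @param vsp A [vs_profile()].
#' @param cf Characteristic frequency, Hz.
#' @param harmonic Which harmonic column to classify (1 = f0).
#' @return As [classify_profile()], with `sloping` relabelled `flat`.
#' @export
classify_vs_profile <- function(vsp, cf, harmonic = 1) {
  stopifnot(inherits(vsp, "vs_profile"))
  prof <- list(peak_freqs = vsp$conditions, mean_rate = vsp$vs[, harmonic],
               cf = cf)
  cls <- classify_profile(smooth_and_zscore(prof), cf = cf)
  if (cls$category == "sloping") cls$category <- "flat"
  cls
}

#' Prevalence of significant phase locking across conditions
#'
#' Counts conditions with Rayleigh p below `alpha` at each analysis
#' frequency, and reports whether locking at >= `min_conditions`
#' conditions (the prevalence rule) holds.
#'
#' @param vsp A [vs_profile()].
#' @param alpha Rayleigh significance level.
#' @param min_conditions Minimum number of conditions.
#' @return data.frame with `freq`, `n_significant`, `prevalent`.
#' @export
locking_prevalence <- function(vsp, alpha = 0.05, min_conditions = 20) {
  n_sig <- colSums(vsp$p < alpha, na.rm = TRUE)
  data.frame(freq = vsp$freqs, n_significant = as.integer(n_sig),
             prevalent = n_sig >= min_conditions)
}

# --- rate-independent SPIKE distance -----------------------------------

# Time-resolved spike-train dissimilarity. For each train n at time t:
# xP = t - preceding spike, xF = following spike - t, xISI = xP + xF, and
# dtP/dtF are the distances from the preceding/following spike to the
# nearest spike of the other train. The per-train dissimilarity is
#   S_n(t) = (dtP_n * xF_n + dtF_n * xP_n) / xISI_n,
# and the rate-independent profile drops the cross-rate weighting of the
# standard SPIKE profile:
#   S_RI(t) = (S1(t) + S2(t)) / (xISI1(t) + xISI2(t)),
# which coincides with the standard profile when local rates are equal.
# Both trains are augmented with auxiliary spikes at 0 and T (edge
# correction), and the time average is taken on a dense uniform grid.

nearest_spike_dist <- function(x, s) {
  j <- findInterval(x, s)
  lo <- ifelse(j >= 1, x - s[pmax(j, 1)], Inf)
  hi <- ifelse(j < length(s), s[pmin(j + 1, length(s))] - x, Inf)
  pmin(lo, hi)
}

#' Rate-independent SPIKE distance between two spike trains
#'
#' @param t1,t2 Spike times, s.
#' @param t_end Recording end, s (start is 0).
#' @param grid_n Grid points for the time average.
#' @return Dissimilarity in \[0, 1\]; 0 for identical trains.
#' @export
ris_distance <- function(t1, t2, t_end, grid_n = 500) {
  s1 <- sort(unique(c(0, t1, t_end)))
  s2 <- sort(unique(c(0, t2, t_end)))
  # midpoints of grid_n equal intervals: strictly inside (0, t_end)
  t <- (seq_len(grid_n) - 0.5) * t_end / grid_n
  side <- function(sa, sb) {
    ia <- findInterval(t, sa)
    tP <- sa[ia]
    tF <- sa[ia + 1]
    xP <- t - tP
    xF <- tF - t
    dtP <- nearest_spike_dist(tP, sb)
    dtF <- nearest_spike_dist(tF, sb)
    list(S = (dtP * xF + dtF * xP) / (tF - tP), xISI = tF - tP)
  }
  a <- side(s1, s2)
  b <- side(s2, s1)
  mean((a$S + b$S) / (a$xISI + b$xISI))
}

#' Condition-by-condition rate-independent spike-distance matrix
#'
#' Off-diagonal entries hold the mean pairwise RI-SPIKE distance between
#' trials of two conditions; diagonal entries hold the within-condition
#' baseline (mean distance between different trials of the same
#' condition). Conditions with fewer than 2 trials are excluded with a
#' warning.
#'
#' @param trains A `spike_train_set`.
#' @param grid_n Grid resolution for each pairwise distance.
#' @param max_pairs Maximum trial pairs sampled per condition pair
#'   (deterministic subsample of the pair list; `Inf` = all pairs).
#' @return A `ris_matrix`: symmetric `distance` matrix with conditions as
#'   dimnames, plus `conditions`.
#' @export
ris_distance_matrix <- function(trains, grid_n = 300, max_pairs = Inf) {
  stopifnot(inherits(trains, "spike_train_set"))
  conds <- sort(unique(trains$conditions))
  sp <- trains$spikes
  by_trial <- lapply(conds, function(cond)
    lapply(seq_len(trains$n_reps), function(tr)
      sp$time_s[sp$condition == cond & sp$trial == tr]))
  n_spk <- vapply(by_trial, function(l) sum(lengths(l) > 0), numeric(1))
  usable <- vapply(by_trial, function(l) length(l) >= 2, logical(1))
  if (any(!usable)) {
    warning("excluding conditions with fewer than 2 trials")
    conds <- conds[usable]
    by_trial <- by_trial[usable]
  }
  nc <- length(conds)
  D <- matrix(NA_real_, nc, nc, dimnames = list(conds, conds))
  t_end <- trains$duration
  for (i in seq_len(nc)) for (j in i:nc) {
    ta <- by_trial[[i]]
    tb <- by_trial[[j]]
    pairs <- if (i == j) utils::combn(length(ta), 2) else
      as.matrix(expand.grid(seq_along(ta), seq_along(tb)))
    if (i != j) pairs <- t(pairs)
    if (ncol(pairs) > max_pairs)
      pairs <- pairs[, round(seq(1, ncol(pairs), length.out = max_pairs)),
                     drop = FALSE]
    d <- vapply(seq_len(ncol(pairs)), function(k)
      ris_distance(ta[[pairs[1, k]]], tb[[pairs[2, k]]], t_end, grid_n),
      numeric(1))
    D[i, j] <- D[j, i] <- mean(d)
  }
  structure(list(distance = D, conditions = conds),
            class = "ris_matrix")
}
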