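#' Interpolate a profile onto a dense frequency grid
#'
#' Means and trial SDs are linearly interpolated onto `n` equally spaced
#' frequencies between the lowest and highest condition frequency
#' (default 600 steps), the grid used by the threshold search.
#'
#' @param profile A `rate_profile` (or any list with `peak_freqs`,
#'   `mean_rate`, `rate_sd`).
#' @param n Number of grid points.
#' @return An `interp_profile`: `freqs`, `mean`, `sd`.
#' @export
interpolate_profile <- function(profile, n = 600) {
  f <- profile$peak_freqs
  if (length(f) < 2) stop("need at least 2 conditions to interpolate")
  grid <- seq(min(f), max(f), length.out = n)
  structure(list(
    freqs = grid,
    mean = stats::approx(f, profile$mean_rate, grid)$y,
    sd = stats::approx(f, profile$rate_sd, grid)$y),
    class = "interp_profile")
}

#' Adjusted d-prime between two rate distributions
#'
#' `d' = |mu2 - mu1| / sqrt((sd1^2 + sd2^2) / 2)` (pooled-SD form).
#'
#' @param mu1,mu2 Means, sp/s.
#' @param sd1,sd2 Trial SDs, sp/s.
#' @return d-prime (dimensionless); `Inf` when both SDs are zero and the
#'   means differ.
#' @export
dprime <- function(mu1, mu2, sd1, sd2) {
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  ifelse(pooled == 0, ifelse(mu1 == mu2, 0, Inf),
         abs(mu2 - mu1) / pooled)
}

#' Discrimination threshold in percent of frequency
#'
#' `Theta = df / f_mid * 100`, where `df` is the spectral-peak frequency
#' difference of the discriminated pair and `f_mid` the midpoint
#' frequency.
#'
#' @param f_lo,f_hi The two spectral-peak frequencies, Hz.
#' @return Threshold, percent of frequency.
#' @export
theta_percent <- function(f_lo, f_hi) {
  (f_hi - f_lo) / ((f_lo + f_hi) / 2) * 100
}

#' Sliding-separation threshold search on an interpolated profile
#'
#' For separation i = 1: find the steepest-slope pair of grid points
#' `(n, n + 1)` (largest absolute rate difference per Hz; ties broken by
#' the lowest frequency) and compute its [dprime()]. If d' >= 1, the
#' threshold is `Theta = df / f_mid * 100` for that pair. Otherwise widen
#' the separation to i = 2, 3, ..., `max_sep`, re-finding the steepest
#' pair at each separation, until a d' >= 1 is found; `found = FALSE` if
#' no separation yields one.
#'
#' @param p An [interpolate_profile()] result.
#' @param max_sep Maximum grid-point separation searched.
#' @param criterion d-prime criterion.
#' @return A `threshold_result`: `theta` (percent), `f_pair` (Hz),
#'   `dprime`, `separation`, `found`, `source`.
#' @export
find_threshold <- function(p, max_sep = 100, criterion = 1) {
  stopifnot(inherits(p, "interp_profile"))
  N <- length(p$freqs)
  for (i in seq_len(min(max_sep, N - 1))) {
    lo <- seq_len(N - i)
    hi <- lo + i
    slope <- abs(p$mean[hi] - p$mean[lo]) / (p$freqs[hi] - p$freqs[lo])
    n <- which.max(slope)  # first max = lowest frequency on ties
    dp <- dprime(p$mean[n], p$mean[n + i], p$sd[n], p$sd[n + i])
    if (is.finite(dp) && dp >= criterion || is.infinite(dp)) {
      return(new_threshold_result(
        theta = theta_percent(p$freqs[n], p$freqs[n + i]),
        f_pair = c(p$freqs[n], p$freqs[n + i]), dprime = dp,
        separation = i, found = TRUE, source = "rate"))
    }
  }
  new_threshold_result(NA_real_, c(NA_real_, NA_real_), NA_real_,
                       NA_integer_, FALSE, "rate")
}

new_threshold_result <- function(theta, f_pair, dprime, separation, found,
                                 source) {
  structure(list(theta = theta, f_pair = f_pair, dprime = dprime,
                 separation = separation, found = found, source = source),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$found)
    cat(sprintf(
      "threshold (%s): %.3f%% (pair %.1f-%.1f Hz, d' = %.2f)\n",
      x$source, x$theta, x$f_pair[1], x$f_pair[2], x$dprime))
  else cat(sprintf("threshold (%s): not found\n", x$source))
  invisible(x)
}

#' Rate-based discrimination threshold for a profile
#'
#' Convenience wrapper: 600-step interpolation followed by the sliding
#' threshold search.
#'
#' @param profile A `rate_profile`.
#' @param ... Passed to [find_threshold()].
#' @return A `threshold_result`.
#' @export
rate_threshold <- function(profile, ...) {
  find_threshold(interpolate_profile(profile), ...)
}

#' Vector-strength-based discrimination threshold
#'
#' Per-trial vector strength at `harmonic * f0` gives a mean and SD per
#' condition; the same 600-step interpolation and sliding search as the
#' rate threshold is then applied to the VS profile.
#'
#' @param trains A `spike_train_set`.
#' @param f0 Fundamental frequency, Hz.
#' @param harmonic Harmonic multiple analyzed.
#' @param window Analysis window, s.
#' @param ... Passed to [find_threshold()].
#' @return A `threshold_result` with `source = "vector_strength"`.
#' @export
vs_threshold <- function(trains, f0 = 200, harmonic = 1,
                         window = c(0.05, 0.30), ...) {
  stopifnot(inherits(trains, "spike_train_set"))
  conds <- sort(unique(trains$conditions))
  freq <- harmonic * f0
  sp <- trains$spikes
  m <- s <- numeric(length(conds))
  for (ci in seq_along(conds)) {
    v <- vapply(seq_len(trains$n_reps), function(tr) {
      st <- sp$time_s[sp$condition == conds[ci] & sp$trial == tr &
                        sp$time_s >= window[1] & sp$time_s < window[2]]
      vector_strength(st, freq)
    }, numeric(1))
    v <- v[!is.na(v)]
    m[ci] <- if (length(v)) mean(v) else 0
    s[ci] <- if (length(v) > 1) stats::sd(v) else 0
  }
  res <- find_threshold(interpolate_profile(
    list(peak_freqs = conds, mean_rate = m, rate_sd = s)), ...)
  res$source <- "vector_strength"
  res
}

#' RI-SPIKE-distance-based discrimination threshold
#'
#' The within-condition baseline distances (matrix diagonal) provide the
#' reference distribution (mu1, sd1) and cross-condition distances the
#' comparison (mu2, sd2). Baselines and cross-distances are linearly
#' interpolated onto the 600-step frequency grid (cross-distances
#' bilinearly over both frequency axes), and the sliding search looks for
#' the pair whose dissimilarity most exceeds its baseline; the threshold
#' is reached only when that excess is significant at d' >= 1.
#'
#' @param trains A `spike_train_set`.
#' @param mat Optional precomputed [ris_distance_matrix()]-style result
#'   with both means and SDs (see `ris_distance_stats`).
#' @param n Grid size.
#' @param max_sep Maximum grid separation.
#' @param criterion d-prime criterion.
#' @param ... Passed to [ris_distance_stats()].
#' @return A `threshold_result` with `source = "ris"`.
#' @export
ris_threshold <- function(trains, mat = NULL, n = 600, max_sep = 100,
                          criterion = 1, ...) {
  if (is.null(mat)) mat <- ris_distance_stats(trains, ...)
  conds <- mat$conditions
  grid <- seq(min(conds), max(conds), length.out = n)
  base_mu <- stats::approx(conds, diag(mat$mean), grid)$y
  base_sd <- stats::approx(conds, diag(mat$sd), grid)$y
  interp2 <- function(M, fa, fb) {
    ia <- findInterval(fa, conds, rightmost.closed = TRUE)
    ib <- findInterval(fb, conds, rightmost.closed = TRUE)
    ia <- pmin(ia, length(conds) - 1)
    ib <- pmin(ib, length(conds) - 1)
    wa <- (fa - conds[ia]) / (conds[ia + 1] - conds[ia])
    wb <- (fb - conds[ib]) / (conds[ib + 1] - conds[ib])
    M[cbind(ia, ib)] * (1 - wa) * (1 - wb) +
      M[cbind(ia + 1, ib)] * wa * (1 - wb) +
      M[cbind(ia, ib + 1)] * (1 - wa) * wb +
      M[cbind(ia + 1, ib + 1)] * wa * wb
  }
  for (i in seq_len(min(max_sep, n - 1))) {
    lo <- seq_len(n - i)
    hi <- lo + i
    mu2 <- interp2(mat$mean, grid[lo], grid[hi])
    sd2 <- interp2(mat$sd, grid[lo], grid[hi])
    mu1 <- (base_mu[lo] + base_mu[hi]) / 2
    sd1 <- sqrt((base_sd[lo]^2 + base_sd[hi]^2) / 2)
    excess <- mu2 - mu1
    k <- which.max(excess)
    if (excess[k] > 0) {
      dp <- dprime(mu1[k], mu2[k], sd1[k], sd2[k])
      if (is.finite(dp) && dp >= criterion) {
        return(new_threshold_result(
          theta = theta_percent(grid[k], grid[k + i]),
          f_pair = c(grid[k], grid[k + i]), dprime = dp,
          separation = i, found = TRUE, source = "ris"))
      }
    }
  }
  new_threshold_result(NA_real_, c(NA_real_, NA_real_), NA_real_,
                       NA_integer_, FALSE, "ris")
}

#' RI-SPIKE distance matrix with means and SDs
#'
#' As [ris_distance_matrix()] but keeping the SD of pairwise distances in
#' each cell, which the threshold d-prime needs.
#'
#' @inheritParams ris_distance_matrix
#' @return List with `mean` and `sd` matrices and `conditions`.
#' @export
ris_distance_stats <- function(trains, grid_n = 300, max_pairs = Inf) {
  stopifnot(inherits(trains, "spike_train_set"))
  conds <- sort(unique(trains$conditions))
  sp <- trains$spikes
  by_trial <- lapply(conds, function(cond)
    lapply(seq_len(trains$n_reps), function(tr)
      sp$time_s[sp$condition == cond & sp$trial == tr]))
  nc <- length(conds)
  M <- S <- matrix(NA_real_, nc, nc, dimnames = list(conds, conds))
  for (i in seq_len(nc)) for (j in i:nc) {
    ta <- by_trial[[i]]
    tb <- by_trial[[j]]
    pairs <- if (i == j) utils::combn(length(ta), 2) else
      t(as.matrix(expand.grid(seq_along(ta), seq_along(tb))))
    if (ncol(pairs) > max_pairs)
      pairs <- pairs[, round(seq(1, ncol(pairs), length.out = max_pairs)),
                     drop = FALSE]
    d <- vapply(seq_len(ncol(pairs)), function(k)
      ris_distance(ta[[pairs[1, k]]], tb[[pairs[2, k]]],
                   trains$duration, grid_n), numeric(1))
    M[i, j] <- M[j, i] <- mean(d)
    S[i, j] <- S[j, i] <- stats::sd(d)
  }
  list(mean = M, sd = S, conditions = conds)
}

#' Classify the trend of discrimination threshold over sound level
#'
#' OLS slope of Theta (percent) against level (dB SPL): slope > 0.03/dB
#' is `worsening`, slope < -0.03/dB `improving`, otherwise `unchanging`.
#'
#' @param levels Sound levels, dB SPL.
#' @param theta Thresholds (percent) at those levels; any `NA` (threshold
#'   not found) is an error.
#' @param slope_bound Classification bound, percent per dB.
#' @return List with `category` and `slope`.
#' @export
classify_threshold_trend <- function(levels, theta, slope_bound = 0.03) {
  if (length(levels) < 3 || length(theta) != length(levels))
    stop("need thresholds at >= 3 levels")
  if (anyNA(theta)) stop("threshold missing at some level")
  slope <- unname(stats::coef(stats::lm(theta ~ levels))[2])
  category <- if (slope > slope_bound) "worsening"
  else if (slope < -slope_bound) "improving"
  else "unchanging"
  list(category = category, slope = slope)
}
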