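# Independent oracles and small fixture builders shared across tests.

# Brute-force threshold search written as a plain double loop, kept
# deliberately naive and separate from the vectorized implementation:
# scan separations i = 1..max_sep in order; at each i find the pair
# (n, n+i) with the steepest absolute slope (first/lowest frequency on
# ties); stop at the first pair whose d-prime reaches the criterion.
oracle_threshold <- function(p, max_sep = 100, criterion = 1) {
  N <- length(p$freqs)
  for (i in seq_len(min(max_sep, N - 1))) {
    best_n <- 0L
    best_slope <- -Inf
    for (n in seq_len(N - i)) {
      s <- abs(p$mean[n + i] - p$mean[n]) / (p$freqs[n + i] - p$freqs[n])
      if (s > best_slope) {
        best_slope <- s
        best_n <- n
      }
    }
    mu1 <- p$mean[best_n]
    mu2 <- p$mean[best_n + i]
    pooled <- sqrt((p$sd[best_n]^2 + p$sd[best_n + i]^2) / 2)
    dp <- if (pooled == 0) {
      if (mu1 == mu2) 0 else Inf
    } else abs(mu2 - mu1) / pooled
    if (dp >= criterion) {
      df <- p$freqs[best_n + i] - p$freqs[best_n]
      fm <- (p$freqs[best_n + i] + p$freqs[best_n]) / 2
      return(list(found = TRUE, theta = df / fm * 100, n = best_n,
                  sep = i))
    }
  }
  list(found = FALSE, theta = NA_real_, n = NA_integer_,
       sep = NA_integer_)
}

# random interpolated profile: a smooth random shape with positive SDs,
# occasionally flat/noisy so that some searches fail
random_interp_profile <- function(seed, n_knots = 10, n = 600) {
  withr::with_seed(seed, {
    f <- seq(500, 2500, length.out = n_knots)
    flat <- stats::runif(1) < 0.1
    m <- if (flat) rep(30, n_knots) else
      30 + cumsum(stats::rnorm(n_knots, 0, 8))
    s <- stats::runif(n_knots, if (flat) 20 else 1, if (flat) 30 else 6)
  })
  interpolate_profile(list(peak_freqs = f, mean_rate = m, rate_sd = s),
                      n = n)
}

# magnitude spectrum of a waveform (amplitude per sinusoid component)
wave_spectrum <- function(wave) {
  n <- length(wave$samples)
  amp <- 2 * abs(stats::fft(wave$samples)) / n
  freq <- (seq_len(n) - 1) * wave$sample_rate / n
  keep <- freq < wave$sample_rate / 2
  data.frame(freq = freq[keep], amp = amp[keep])
}

# small standard fixtures
fixture_series <- function(cf = 1200, increment = 50, ...)
  make_shift_series(cf, increment = increment, ...)

expect_category <- function(object, expected) {
  expect_identical(object$category, expected)
}
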