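#' Gaussian and difference-of-Gaussians spectral receptive fields
#'
#' A Gaussian receptive field weights stimulus components by
#' `strength * exp(-(f - center)^2 / (2 * bandwidth^2))` on a linear
#' frequency axis (configurable to log2 frequency). A DoG subtracts a
#' second, inhibitory Gaussian from the excitatory one.
#'
#' @param center Center frequency, Hz.
#' @param bandwidth Gaussian SD, Hz (octaves when `log_axis = TRUE`).
#' @param strength Nonnegative weight per unit component amplitude.
#' @param log_axis Evaluate the Gaussian on a log2-frequency axis?
#' @return A `gaussian_rf`.
#' @export
gaussian_rf <- function(center, bandwidth, strength, log_axis = FALSE) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (strength < 0) stop("strength must be >= 0")
  structure(list(center = center, bandwidth = bandwidth,
                 strength = strength, log_axis = log_axis),
            class = "gaussian_rf")
}

#' @rdname gaussian_rf
#' @param excitatory,inhibitory Two `gaussian_rf`s; the inhibitory one is
#'   subtracted and the resulting rate prediction half-wave rectified.
#' @export
dog_rf <- function(excitatory, inhibitory) {
  stopifnot(inherits(excitatory, "gaussian_rf"),
            inherits(inhibitory, "gaussian_rf"))
  structure(list(excitatory = excitatory, inhibitory = inhibitory),
            class = "dog_rf")
}

#' Receptive-field weight at given frequencies
#' @param rf A `gaussian_rf` or `dog_rf`.
#' @param freq Frequencies, Hz.
#' @return Weights (negative values possible for a DoG).
#' @export
rf_weight <- function(rf, freq) {
  if (inherits(rf, "dog_rf"))
    return(rf_weight(rf$excitatory, freq) - rf_weight(rf$inhibitory, freq))
  x <- if (rf$log_axis) log2(freq / rf$center) else freq - rf$center
  b <- if (rf$log_axis) rf$bandwidth else rf$bandwidth
  rf$strength * exp(-x^2 / (2 * b^2))
}

#' Predict the mean rate for one stimulus from a receptive field
#'
#' Sum of stimulus spectral components, each weighted by the receptive
#' field at the component frequency, plus the spontaneous rate. DoG
#' predictions are half-wave rectified so rates cannot go negative.
#'
#' @param rf A `gaussian_rf` or `dog_rf`.
#' @param comp Component table (columns `freq_hz` and an amplitude
#'   column).
#' @param spont Spontaneous rate, sp/s.
#' @param amp_col Which amplitude column to use (linear by default).
#' @return Predicted mean rate, sp/s.
#' @export
predict_rate <- function(rf, comp, spont = 0, amp_col = "amp_rel") {
  if (nrow(comp) == 0) stop("component table is empty")
  drive <- sum(rf_weight(rf, comp$freq_hz) * comp[[amp_col]])
  if (inherits(rf, "dog_rf")) max(drive + spont, 0) else drive + spont
}

#' Predicted rate profile over a shift series
#' @param rf Receptive field.
#' @param series A `shift_series`.
#' @param spont Spontaneous rate, sp/s.
#' @return Numeric vector of predicted rates, one per stimulus.
#' @export
predict_profile <- function(rf, series, spont = 0) {
  vapply(series$specs, function(sp)
    predict_rate(rf, components(sp), spont), numeric(1))
}

rf_from_par <- function(par, model, log_axis = FALSE) {
  if (model == "gaussian")
    gaussian_rf(par[1], par[2], par[3], log_axis)
  else
    dog_rf(gaussian_rf(par[1], par[2], par[3], log_axis),
           gaussian_rf(par[4], par[5], par[6], log_axis))
}

#' Fit a spectral receptive field to a rate profile
#'
#' Constrained nonlinear least squares (box-constrained quasi-Newton with
#' a deterministic multistart grid): centers bounded to the stimulated
#' frequency range plus/minus one octave, bandwidths positive, strengths
#' nonnegative. The best-MSE fit over all starts is returned with R^2 and
#' adjusted R^2 (`1 - (1 - R2) (n - 1) / (n - k - 1)`, k = 3 for the
#' Gaussian, 6 for the DoG).
#'
#' @param profile A `rate_profile`.
#' @param series The `shift_series` that produced it.
#' @param model `"gaussian"` or `"dog"`.
#' @param spont Spontaneous rate added to predictions, sp/s (defaults to
#'   the profile's, else 0).
#' @param log_axis Fit the Gaussians on a log2-frequency axis?
#' @return An `rf_fit`: `rf`, `par`, `mse`, `rss`, `r2`, `adj_r2`, `k`,
#'   `n`, `fitted`, and for DoGs `strength_ratio` and `bandwidth_ratio`
#'   (inhibitory / excitatory).
#' @export
fit_rf <- function(profile, series, model = c("gaussian", "dog"),
                   spont = NULL, log_axis = FALSE) {
  model <- match.arg(model)
  y <- profile$mean_rate
  n <- length(y)
  if (n < ifelse(model == "gaussian", 8, 12))
    stop("too few conditions for a stable ", model, " fit")
  if (is.null(spont)) spont <- if (is.na(profile$spont)) 0 else
    profile$spont
  comps <- lapply(series$specs, components)
  # pad component tables into matrices for vectorized objective/gradient
  nmax <- max(vapply(comps, nrow, integer(1)))
  Fm <- vapply(comps, function(cmp) c(cmp$freq_hz,
                                      rep(1, nmax - nrow(cmp))),
               numeric(nmax))
  Am <- vapply(comps, function(cmp) c(cmp$amp_rel,
                                      rep(0, nmax - nrow(cmp))),
               numeric(nmax))
  Xm <- if (log_axis) log2(Fm) else Fm
  gauss_terms <- function(c0, b0, s0) {
    x0 <- if (log_axis) log2(c0) else c0
    d <- Xm - x0
    g <- Am * exp(-d^2 / (2 * b0^2))
    drive <- s0 * colSums(g)
    # partials of drive wrt (center on its axis, bandwidth, strength)
    list(drive = drive,
         d_x0 = s0 * colSums(g * d) / b0^2,
         d_b0 = s0 * colSums(g * d^2) / b0^3,
         d_s0 = colSums(g),
         x0 = x0, c0 = c0)
  }
  chain_center <- function(term)  # d x0 / d center on the Hz axis
    if (log_axis) 1 / (term$c0 * log(2)) else 1
  predict_par <- function(par) {
    drive <- gauss_terms(par[1], par[2], par[3])$drive
    if (model == "dog") {
      drive <- drive - gauss_terms(par[4], par[5], par[6])$drive
      pmax(drive + spont, 0)
    } else drive + spont
  }
  grad <- function(par) {
    e <- gauss_terms(par[1], par[2], par[3])
    if (model == "dog") {
      h <- gauss_terms(par[4], par[5], par[6])
      raw <- e$drive - h$drive + spont
      pred <- pmax(raw, 0)
      act <- as.numeric(raw > 0)
      resid <- -2 * (y - pred) * act / length(y)
      c(sum(resid * e$d_x0) * chain_center(e),
        sum(resid * e$d_b0), sum(resid * e$d_s0),
        -sum(resid * h$d_x0) * chain_center(h),
        -sum(resid * h$d_b0), -sum(resid * h$d_s0))
    } else {
      resid <- -2 * (y - (e$drive + spont)) / length(y)
      c(sum(resid * e$d_x0) * chain_center(e),
        sum(resid * e$d_b0), sum(resid * e$d_s0))
    }
  }
  obj <- function(par) mean((y - predict_par(par))^2)
  frange <- range(series$peak_freqs)
  c_lo <- frange[1] / 2
  c_hi <- frange[2] * 2
  span <- diff(frange)
  # bandwidths narrower than the condition spacing are unidentifiable
  spacing <- stats::median(diff(series$peak_freqs))
  bw_lo <- if (log_axis) spacing / frange[2] / log(2) else spacing
  bw_hi <- if (log_axis) 4 else span * 2
  s_hi <- max(1e3, 20 * max(abs(y - spont)))
  centers <- seq(frange[1], frange[2], length.out = 5)
  bws <- if (log_axis) c(0.2, 0.5, 1) else span * c(0.05, 0.15, 0.4)
  strengths <- max(1, diff(range(y))) * c(0.5, 2)
  starts <- expand.grid(c = centers, b = bws, s = strengths)
  lower_g <- c(c_lo, bw_lo, 0)
  upper_g <- c(c_hi, bw_hi, s_hi)
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    p0 <- c(starts$c[r], starts$b[r], starts$s[r])
    if (model == "dog") {
      p0 <- c(p0, starts$c[r], starts$b[r] * 2, starts$s[r] * 0.5)
      lower <- c(lower_g, lower_g)
      upper <- c(upper_g, upper_g)
    } else {
      lower <- lower_g
      upper <- upper_g
    }
    fit <- tryCatch(
      stats::optim(p0, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, model = model),
                     class = "rf_fit"))
  }
  fitted <- predict_par(best$par)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  k <- if (model == "gaussian") 3 else 6
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  out <- list(converged = TRUE, model = model,
              rf = rf_from_par(best$par, model, log_axis),
              par = best$par, mse = best$value, rss = rss, r2 = r2,
              adj_r2 = adj_r2, k = k, n = n, fitted = fitted,
              spont = spont)
  if (model == "dog") {
    out$strength_ratio <- best$par[6] / best$par[3]
    out$bandwidth_ratio <- best$par[5] / best$par[2]
  }
  structure(out, class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  if (!x$converged) {
    cat("rf_fit: failed\n")
    return(invisible(x))
  }
  cat(sprintf("rf_fit (%s): R2 = %.3f, adj R2 = %.3f, MSE = %.2f\n",
              x$model, x$r2, x$adj_r2, x$mse))
  if (x$model == "dog")
    cat(sprintf("  strength ratio %.2f, bandwidth ratio %.2f\n",
                x$strength_ratio, x$bandwidth_ratio))
  invisible(x)
}

#' One-sided F test: does the DoG fit better than the Gaussian?
#'
#' Nested-model F statistic from the residual sums of squares,
#' `F = ((RSS_g - RSS_d) / (k_d - k_g)) / (RSS_d / (n - k_d))`, with
#' one-sided p-value; when the DoG does not improve the fit the p-value
#' is 1.
#'
#' @param gauss,dog `rf_fit`s of the two models on identical data.
#' @param n Number of conditions (defaults to the fits' n).
#' @return List with `f`, `p`, `df1`, `df2`.
#' @export
compare_models <- function(gauss, dog, n = gauss$n) {
  stopifnot(gauss$model == "gaussian", dog$model == "dog",
            gauss$n == dog$n)
  df1 <- dog$k - gauss$k
  df2 <- n - dog$k
  if (dog$rss >= gauss$rss)
    return(list(f = 0, p = 1, df1 = df1, df2 = df2))
  f <- ((gauss$rss - dog$rss) / df1) / (dog$rss / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
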