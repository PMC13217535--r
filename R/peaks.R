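# Local-maximum detection with topographic prominence, matching the
# standard definition: the prominence of a peak is its height above the
# higher of the two base levels, where each base is the minimum of the
# signal between the peak and the nearest point on that side that exceeds
# the peak height (or the signal edge).

#' Find local maxima and their prominences
#'
#' @param x Numeric vector.
#' @param min_prominence Keep only peaks with at least this prominence.
#' @return data.frame with columns `index`, `value`, `prominence`.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3)
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  # local maxima; for plateaus, take the first sample of the plateau
  is_peak <- logical(n)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j < n && x[j + 1] < x[i]) is_peak[i] <- TRUE
    }
  }
  idx <- which(is_peak)
  prom <- vapply(idx, function(i) {
    v <- x[i]
    lmin <- v
    j <- i - 1
    while (j >= 1 && x[j] <= v) { lmin <- min(lmin, x[j]); j <- j - 1 }
    left_base <- if (j >= 1) lmin else min(x[1:i])
    rmin <- v
    j <- i + 1
    while (j <= n && x[j] <= v) { rmin <- min(rmin, x[j]); j <- j + 1 }
    right_base <- if (j <= n) rmin else min(x[i:n])
    v - max(left_base, right_base)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], value = x[idx[keep]],
             prominence = prom[keep])
}
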