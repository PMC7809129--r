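# Local-extremum search with topographic prominence.
#
# Small, dependency-free replacement for the usual signal-processing peak
# finders. Plateaus are collapsed to their middle sample. Prominence follows
# the standard definition: height of the peak above the higher of the two
# key saddles reached before higher terrain (or the series edge).

# Indices of local maxima of x (plateau-aware). Returns integer vector.
local_maxima_idx <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  out <- integer(0)
  for (j in 2:(k - 1L)) {
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      out <- c(out, starts[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  out
}

# Prominence of each peak index in x.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until strictly higher terrain
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) { if (x[i] < lmin) lmin <- x[i]; i <- i - 1L }
    # walk right
    rmin <- h
    i <- p + 1L
    n <- length(x)
    while (i <= n && x[i] <= h) { if (x[i] < rmin) rmin <- x[i]; i <- i + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Find local peaks of a signal
#'
#' Plateau-aware local maxima filtered by topographic prominence and,
#' optionally, by a minimum separation (higher peaks win ties, as in the
#' usual signal-processing convention).
#'
#' @param x Numeric signal.
#' @param prominence Minimum prominence (same units as `x`); `0` keeps all.
#' @param min_distance Minimum index separation between kept peaks;
#'   `0` disables the filter.
#' @return Integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, prominence = 0, min_distance = 0) {
  p <- local_maxima_idx(x)
  if (length(p) == 0L) return(p)
  if (prominence > 0) p <- p[peak_prominence(x, p) >= prominence]
  if (min_distance > 0 && length(p) > 1L) {
    ord <- p[order(x[p], decreasing = TRUE)]
    keep <- integer(0)
    for (i in ord) {
      if (all(abs(keep - i) >= min_distance)) keep <- c(keep, i)
    }
    p <- sort(keep)
  }
  p
}

# Local minima: peaks of -x.
find_troughs <- function(x, prominence = 0, min_distance = 0) {
  find_peaks(-x, prominence = prominence, min_distance = min_distance)
}
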