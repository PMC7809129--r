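# Per-stride spatial parameters.

#' Stride length from a stride-frame trajectory
#'
#' Forward (y) displacement between the stride's bounding mid-stances,
#' i.e. the difference of the stride-frame y coordinate between the last
#' and first row.
#'
#' @param p_p n x 3 stride-frame trajectory spanning the closed segment.
#' @return Stride length in metres.
#' @export
stride_length <- function(p_p) {
  p_p <- matrix(p_p, ncol = 3)
  p_p[nrow(p_p), 2] - p_p[1, 2]
}

#' Shank vertical displacement within a stride
#'
#' Maximum vertical (x) excursion above the stride's starting height,
#' taken over the interior samples of the segment.
#'
#' @param p_p n x 3 stride-frame trajectory spanning the closed segment.
#' @return Vertical displacement in metres (>= 0 for trajectories that
#'   start at their mid-stance height).
#' @export
shank_vertical_displacement <- function(p_p) {
  p_p <- matrix(p_p, ncol = 3)
  n <- nrow(p_p)
  if (n < 3L) return(0)
  max(p_p[2:(n - 1L), 1] - p_p[1, 1])
}

#' Stride duration and velocity from heel-strike timing
#'
#' Duration is the interval between the stride's two heel strikes;
#' velocity is stride length divided by duration.
#'
#' @param hs_i,hs_j Sample indices of the bounding heel strikes
#'   (`hs_j > hs_i`).
#' @param dt Sampling interval, seconds.
#' @param length Stride length, metres.
#' @return List with `duration` (s) and `velocity` (m/s).
#' @export
stride_timing <- function(hs_i, hs_j, dt, length) {
  if (hs_j <= hs_i) stop("non-positive stride duration")
  duration <- (hs_j - hs_i) * dt
  list(duration = duration, velocity = length / duration)
}
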