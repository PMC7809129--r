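# Velocity integration, mid-stance update velocity (inverted pendulum or
# zero-velocity baseline), and linear drift removal.

#' Trapezoidal integration of linear acceleration to velocity
#'
#' `v(k) = v(k-1) + (a(k) + a(k-1)) / 2 * dt`, starting from `v0`.
#'
#' @param a_lin n x 3 matrix of lab-frame linear acceleration, m/s^2.
#' @param dt Sampling interval, seconds.
#' @param v0 Initial velocity 3-vector, m/s.
#' @return n x 3 matrix of velocity, m/s (row 1 equals `v0`).
#' @export
integrate_velocity <- function(a_lin, dt, v0 = c(0, 0, 0)) {
  a_lin <- matrix(a_lin, ncol = 3)
  n <- nrow(a_lin)
  out <- matrix(0, n, 3)
  for (j in 1:3) {
    out[, j] <- v0[j] + cumtrapz(a_lin[, j], dt)
  }
  out
}

#' Inverted-pendulum update velocity at mid-stance
#'
#' At mid-stance the shank is modelled as rotating about the stationary
#' malleolus, so the sensor velocity is the tangential velocity
#' `w_lab x r_lab`. The lever arm points from the malleolus to the sensor
#' along the accelerometer direction (pure gravity at mid-stance), rotated
#' into the lab frame; by the gravity-alignment construction this equals
#' `r * c(1, 0, 0)`.
#'
#' @param q_se_at_ms Unit quaternion at mid-stance (gravity-aligned).
#' @param w_s_at_ms Sensor-frame angular velocity at mid-stance, rad/s.
#' @param a_s_at_ms Sensor-frame accelerometer at mid-stance, m/s^2.
#' @param r Sensor-to-malleolus distance, metres (> 0).
#' @return Update velocity 3-vector, m/s.
#' @export
ipm_update_velocity <- function(q_se_at_ms, w_s_at_ms, a_s_at_ms, r) {
  if (r <= 0) stop("r must be > 0")
  nrm <- sqrt(sum(a_s_at_ms^2))
  if (nrm == 0) stop("zero-norm accelerometer vector at mid-stance")
  w_lab <- quat_rotate(q_se_at_ms, w_s_at_ms)
  r_lab <- r * quat_rotate(q_se_at_ms, a_s_at_ms / nrm)
  cross3(w_lab, r_lab)
}

#' Zero-velocity update (baseline)
#'
#' The baseline method re-initialises the integrated velocity to zero at
#' each mid-stance.
#'
#' @return `c(0, 0, 0)`.
#' @export
zupt_update_velocity <- function() c(0, 0, 0)

#' Remove linear drift from a velocity segment
#'
#' Models the drift over one stride segment as a straight line in the
#' sample index, anchored so that the corrected velocity equals the update
#' velocities at both segment boundaries:
#' slope `alpha = ((v_raw_end - v_end) - (v_raw_start - v_start)) / m`,
#' intercept `beta = v_raw_start - v_start`, where `m` is the number of
#' steps in the segment; the corrected series is
#' `v_raw(k) - alpha * (k - k_start) - beta`.
#'
#' @param v_raw (m + 1) x 3 matrix of raw integrated velocity over the
#'   closed segment `[ms(i), ms(i+1)]`.
#' @param v_update_start,v_update_end Update velocities at the two segment
#'   boundaries, m/s.
#' @return List with `v_corr` ((m + 1) x 3), `alpha` (3-vector, m/s per
#'   sample) and `beta` (3-vector, m/s).
#' @export
remove_drift <- function(v_raw, v_update_start, v_update_end) {
  v_raw <- matrix(v_raw, ncol = 3)
  n <- nrow(v_raw)
  if (n < 2L) stop("segment must span at least 2 samples")
  m <- n - 1L
  beta <- v_raw[1L, ] - v_update_start
  alpha <- ((v_raw[n, ] - v_update_end) - beta) / m
  k <- 0:m
  v_corr <- v_raw - outer(k, alpha) - matrix(beta, n, 3, byrow = TRUE)
  list(v_corr = v_corr, alpha = alpha, beta = beta)
}
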