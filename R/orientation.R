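# Orientation estimation: gravity alignment at each mid-stance, forward
# quaternion integration of the gyroscope within each stride segment.

#' Shortest-arc quaternion aligning the accelerometer with gravity
#'
#' At mid-stance the accelerometer is assumed to read pure gravity, so the
#' sensor-to-lab rotation is the shortest arc mapping the normalized
#' reading onto the lab gravity direction `c(1, 0, 0)`. The rotation axis
#' is the normalized cross product of the two directions; half-angle terms
#' come from the dot product.
#'
#' @param a_s_at_ms Sensor-frame accelerometer 3-vector at mid-stance
#'   (any non-zero magnitude).
#' @param degenerate_tol Below this cross-product norm the axis is
#'   undefined: aligned input returns identity, antipodal input a 180
#'   degree rotation about the fixed fallback axis `c(0, 1, 0)`.
#' @return Unit quaternion `q` with
#'   `quat_rotate(q, a_s_at_ms / ||a_s_at_ms||) == c(1, 0, 0)`.
#' @export
quat_from_gravity <- function(a_s_at_ms, degenerate_tol = 1e-8) {
  nrm <- sqrt(sum(a_s_at_ms^2))
  if (nrm == 0) stop("zero-norm accelerometer vector")
  g <- frame_convention()$gravity_lab
  ahat <- a_s_at_ms / nrm
  d <- sum(ahat * g)
  axis <- cross3(ahat, g)
  an <- sqrt(sum(axis^2))
  if (an < degenerate_tol) {
    if (d > 0) return(quat_identity())
    return(quaternion(0, 0, 1, 0))   # antipodal: 180 deg about fallback axis
  }
  cs <- sqrt(0.5 * (1 + d))
  sn <- sqrt(0.5 * (1 - d))
  quaternion(cs, axis[1] / an * sn, axis[2] / an * sn, axis[3] / an * sn)
}

#' Propagate orientation by gyro integration
#'
#' First-order update with renormalization:
#' `q(k) = normalize(q(k-1) + 0.5 * q(k-1) (0, w(k)) dt)`,
#' using the angular velocity of the sample being stepped to.
#'
#' @param q0 Unit quaternion at the first sample.
#' @param w_s m x 3 matrix of sensor-frame angular velocity for the m
#'   samples following the initial one (rad/s).
#' @param dt Sampling interval, seconds.
#' @return `(m + 1) x 4` matrix of unit quaternions; row 1 is `q0`.
#' @export
propagate_orientation <- function(q0, w_s, dt) {
  w_s <- matrix(w_s, ncol = 3)
  m <- nrow(w_s)
  out <- matrix(NA_real_, m + 1L, 4L)
  q <- as.numeric(q0)
  out[1L, ] <- q
  for (k in seq_len(m)) {
    qd <- 0.5 * quat_multiply(q, c(0, w_s[k, ]))
    q <- q + qd * dt
    q <- q / sqrt(sum(q * q))
    out[k + 1L, ] <- q
  }
  out
}

#' Lab-frame and linear acceleration from an orientation track
#'
#' Rotates each accelerometer sample into the lab frame and subtracts the
#' gravity vector `g_mag * c(1, 0, 0)`.
#'
#' @param q_se n x 4 matrix of unit quaternions (sensor to lab).
#' @param a_s n x 3 matrix of sensor-frame accelerometer samples, m/s^2.
#' @return List with `a_lab` and `a_lin`, both n x 3 matrices.
#' @export
lab_linear_acceleration <- function(q_se, a_s) {
  q_se <- matrix(q_se, ncol = 4)
  a_s <- matrix(a_s, ncol = 3)
  if (nrow(q_se) != nrow(a_s)) stop("length mismatch")
  fc <- frame_convention()
  grav <- fc$g_mag * fc$gravity_lab
  a_lab <- t(vapply(seq_len(nrow(a_s)),
                    function(k) quat_rotate(q_se[k, ], a_s[k, ]),
                    numeric(3)))
  list(a_lab = a_lab, a_lin = sweep(a_lab, 2, grav))
}
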