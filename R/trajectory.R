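# Position integration and the per-stride coordinate frame.

#' Trapezoidal integration of velocity to position
#'
#' @param v_corr n x 3 matrix of corrected velocity, m/s.
#' @param dt Sampling interval, seconds.
#' @param p0 Initial position 3-vector, metres.
#' @return n x 3 matrix of position.
#' @export
integrate_position <- function(v_corr, dt, p0 = c(0, 0, 0)) {
  v_corr <- matrix(v_corr, ncol = 3)
  out <- matrix(0, nrow(v_corr), 3)
  for (j in 1:3) out[, j] <- p0[j] + cumtrapz(v_corr[, j], dt)
  out
}

#' Stride-aligned coordinate frame
#'
#' Builds the rotation from the lab frame into the stride frame `P` whose
#' y axis is the normalized displacement between the two bounding
#' mid-stances, z is the normalized cross product of the vertical
#' `c(1, 0, 0)` with y, and x completes the right-handed triad (`y x z`).
#' Because the basis is orthonormal, the rotation solving
#' `I = R_ep %*% P_e` is the transpose of the basis matrix.
#'
#' @param p_e n x 3 matrix of lab-frame positions.
#' @param ms_i,ms_j Row indices of the stride's bounding mid-stances.
#' @return Object of class `stride_frame`: `R_ep` (3 x 3), basis vectors
#'   `x_e`, `y_e`, `z_e`.
#' @export
stride_frame_rotation <- function(p_e, ms_i, ms_j) {
  d <- p_e[ms_j, ] - p_e[ms_i, ]
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("coincident mid-stance positions")
  y_e <- d / nd
  up <- frame_convention()$gravity_lab
  zc <- cross3(up, y_e)
  nz <- sqrt(sum(zc^2))
  if (nz < 1e-12)
    stop("degenerate stride frame: displacement parallel to the vertical")
  z_e <- zc / nz
  x_e <- cross3(y_e, z_e)
  P <- unname(cbind(x_e, y_e, z_e))
  # orthonormality guard before solving by transposition
  if (max(abs(crossprod(P) - diag(3))) > 1e-9)
    stop("stride frame basis is not orthonormal")
  structure(list(R_ep = t(P), x_e = x_e, y_e = y_e, z_e = z_e),
            class = "stride_frame")
}

#' Transform a stride trajectory into its stride frame
#'
#' Applies `p_p(k) = R_ep %*% (p_e(k) - p_e(k_start))`; the origin shift
#' makes the per-stride trajectory start at zero, which leaves all spatial
#' parameters (differences) unchanged.
#'
#' @param p_e n x 3 matrix of lab positions spanning the stride (row 1 is
#'   the stride's first mid-stance sample).
#' @param frame A [stride_frame_rotation()] result.
#' @return n x 3 matrix of stride-frame positions (columns: vertical x,
#'   forward y, lateral z).
#' @export
transform_stride <- function(p_e, frame) {
  p_e <- matrix(p_e, ncol = 3)
  shifted <- sweep(p_e, 2, p_e[1, ])
  shifted %*% t(frame$R_ep)
}
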