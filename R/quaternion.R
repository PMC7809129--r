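# Quaternion primitives.
#
# Quaternions are plain numeric vectors of length 4 in [w, x, y, z] order
# (scalar part first). q and -q encode the same rotation; user-facing
# constructors canonicalise to w >= 0.

#' Frame conventions used throughout the package
#'
#' The laboratory frame has its x axis along the vertical
#' (superior/inferior) direction, so the gravity direction used for
#' mid-stance alignment is the unit vector `c(1, 0, 0)`. Gravity magnitude
#' is the standard value 9.80665 m/s^2. Sensor axes follow the shank
#' mounting: x inferior/superior (along the shank, pointing to the knee),
#' y posterior/anterior, z medial/lateral (perpendicular to the sagittal
#' plane).
#'
#' @return A list with elements `gravity_lab` (unit 3-vector) and `g_mag`
#'   (m/s^2).
#' @export
frame_convention <- function() {
  list(gravity_lab = c(1, 0, 0), g_mag = 9.80665)
}

#' Construct a quaternion
#'
#' @param w Scalar part.
#' @param x,y,z Vector part components.
#' @param canonical If `TRUE` (default), flip sign so that `w >= 0`
#'   (q and -q are the same rotation).
#' @return Numeric vector `c(w, x, y, z)` of class `quaternion`.
#' @export
quaternion <- function(w, x = 0, y = 0, z = 0, canonical = TRUE) {
  q <- c(w, x, y, z)
  if (length(q) != 4L || anyNA(q)) stop("quaternion needs 4 finite components")
  if (canonical && q[1] < 0) q <- -q
  structure(q, class = "quaternion")
}

#' Identity quaternion
#' @return The identity rotation `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() quaternion(1, 0, 0, 0)

#' Quaternion norm
#' @param q Quaternion `[w, x, y, z]`.
#' @return Euclidean norm of the 4-vector.
#' @export
quat_norm <- function(q) sqrt(sum(q * q))

#' Normalize a quaternion to unit norm
#' @param q Quaternion.
#' @return Unit quaternion (same class as input).
#' @export
quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion conjugate
#' @param q Quaternion `[w, x, y, z]`.
#' @return `[w, -x, -y, -z]`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Hamilton product of two quaternions
#'
#' @param p,q Quaternions `[w, x, y, z]`.
#' @return The Hamilton product `p %*% q` as a length-4 numeric vector.
#'   The product norm equals the product of the norms.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes the vector part of `q (0, u) q*`, i.e. the rotation of `u`
#' from the sensor frame into the frame the quaternion targets.
#'
#' @param q Unit quaternion (checked to within `tol`).
#' @param u Numeric 3-vector.
#' @param tol Unit-norm tolerance, default `1e-6`.
#' @return Rotated 3-vector; the Euclidean norm of `u` is preserved.
#' @export
quat_rotate <- function(q, u, tol = 1e-6) {
  if (abs(quat_norm(q) - 1) > tol) {
    stop("quat_rotate expects a unit quaternion (|norm - 1| = ",
         format(abs(quat_norm(q) - 1)), ")")
  }
  # expanded q (0,u) q* for speed and accuracy
  w <- q[1]; v <- q[2:4]
  t2 <- cross3(v, u)
  u + 2 * (w * t2 + cross3(v, t2))
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix `R` with `R %*% u == quat_rotate(q, u)`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Axis-angle construction of a unit quaternion
#' @param axis 3-vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  quaternion(cos(angle / 2),
             axis[1] / n * sin(angle / 2),
             axis[2] / n * sin(angle / 2),
             axis[3] / n * sin(angle / 2),
             canonical = FALSE)
}

# cross product of two 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
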