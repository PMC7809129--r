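# IMU recording container and delimited-text I/O.

#' Construct an IMU recording
#'
#' A uniformly sampled six-axis recording from one shank-mounted sensor.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing on
#'   a uniform grid.
#' @param a_s n x 3 matrix of sensor-frame specific force (accelerometer),
#'   m/s^2.
#' @param w_s n x 3 matrix of sensor-frame angular velocity (gyroscope),
#'   rad/s.
#' @param side `"left"` or `"right"` label.
#' @param dt Sampling interval in seconds; inferred from `t` when `NULL`.
#' @param tol Uniform-grid tolerance in seconds (default `1e-9`).
#' @return An object of class `imu_recording` with fields `t`, `a_s`,
#'   `w_s`, `dt`, `side`, `n`.
#' @export
imu_recording <- function(t, a_s, w_s, side = "right", dt = NULL,
                          tol = 1e-9) {
  a_s <- as.matrix(a_s); w_s <- as.matrix(w_s)
  n <- length(t)
  if (n < 2L) stop("recording needs at least 2 samples")
  if (nrow(a_s) != n || nrow(w_s) != n || ncol(a_s) != 3L || ncol(w_s) != 3L)
    stop("a_s and w_s must be n x 3 with n == length(t)")
  if (anyNA(t) || anyNA(a_s) || anyNA(w_s)) {
    bad <- which(is.na(t) | rowSums(is.na(a_s)) > 0 | rowSums(is.na(w_s)) > 0)
    stop("NaN/NA values at row ", bad[1])
  }
  d <- diff(t)
  if (is.null(dt)) dt <- stats::median(d)
  bad <- which(abs(d - dt) > tol)
  if (length(bad) > 0)
    stop("non-uniform timestamps: first bad interval at row ", bad[1] + 1L,
         " (dt = ", format(d[bad[1]]), ", expected ", format(dt), ")")
  side <- match.arg(side, c("left", "right"))
  structure(list(t = as.numeric(t), a_s = unname(a_s), w_s = unname(w_s),
                 dt = dt, side = side, n = n),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s shank, %d samples @ %.6g Hz (%.2f s)\n",
              x$side, x$n, 1 / x$dt, x$t[x$n] - x$t[1]))
  invisible(x)
}

#' Read an IMU recording from CSV
#'
#' Expects a comma-separated file with header and seven numeric columns
#' `t,ax,ay,az,gx,gy,gz` ("." decimal). Accelerometer columns are m/s^2;
#' gyroscope columns are deg/s by default (typical commercial IMU export)
#' and are converted to rad/s.
#'
#' @param path File path.
#' @param dt_expected Expected sampling interval in seconds; inferred when
#'   `NULL`. Non-uniform or duplicated timestamps are a hard error naming
#'   the first bad row.
#' @param gyro_units `"deg"` (default) or `"rad"`.
#' @param side Shank side label.
#' @return An [imu_recording].
#' @export
read_imu_csv <- function(path, dt_expected = NULL,
                         gyro_units = c("deg", "rad"), side = "right") {
  gyro_units <- match.arg(gyro_units)
  d <- utils::read.csv(path, header = TRUE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (ncol(d) < 7L)
    stop("expected 7 columns t,ax,ay,az,gx,gy,gz in ", path)
  if (!all(need %in% names(d))) names(d)[1:7] <- need
  w <- as.matrix(d[, c("gx", "gy", "gz")])
  if (gyro_units == "deg") w <- w * pi / 180
  imu_recording(t = d$t,
                a_s = as.matrix(d[, c("ax", "ay", "az")]),
                w_s = w, side = side, dt = dt_expected)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_csv()] (always writes gyro in the requested units).
#'
#' @param rec An [imu_recording].
#' @param path Output file path.
#' @param gyro_units Units for the gyro columns on disk.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path, gyro_units = c("deg", "rad")) {
  gyro_units <- match.arg(gyro_units)
  w <- rec$w_s
  if (gyro_units == "deg") w <- w * 180 / pi
  d <- data.frame(t = rec$t,
                  ax = rec$a_s[, 1], ay = rec$a_s[, 2], az = rec$a_s[, 3],
                  gx = w[, 1], gy = w[, 2], gz = w[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write per-stride results to CSV
#'
#' Columns: `side, stride_index, ms_start_s, ms_end_s, hs_s, to_s,
#' stride_length_m, vertical_disp_m, duration_s, velocity_mps`.
#'
#' @param strides Stride table as returned by [reconstruct_gait()]
#'   (`$strides`) or [simulate_walk()] (`$truth_params`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stride_csv <- function(strides, path) {
  cols <- c("side", "stride_index", "ms_start_s", "ms_end_s", "hs_s", "to_s",
            "stride_length_m", "vertical_disp_m", "duration_s",
            "velocity_mps")
  miss <- setdiff(cols, names(strides))
  if (length(miss) > 0) stop("stride table missing columns: ",
                             paste(miss, collapse = ", "))
  utils::write.csv(strides[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-stride result CSV written by [write_stride_csv()]
#' @param path File path.
#' @return A `data.frame` of stride results.
#' @export
read_stride_csv <- function(path) {
  utils::read.csv(path, header = TRUE)
}
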