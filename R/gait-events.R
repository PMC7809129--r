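# Gait event detection from the sagittal angular velocity.
#
# Events per gait cycle, in temporal order:
#   SMF  shank-max-forward  : local maximum of the integrated tilt angle
#   HS   heel strike        : first peak of omega_z after SMF
#   MS   mid-stance         : maximum of omega_z strictly between HS and TO
#   TO   toe off            : minimum of omega_z between HS and SMB
#   SMB  shank-max-backward : local minimum of the integrated tilt angle
# Strides are the half-open intervals between successive mid-stances.

# cumulative trapezoidal integral, zero at the first sample
cumtrapz <- function(x, dt) {
  c(0, cumsum((x[-1] + x[-length(x)]) / 2) * dt)
}

#' Sagittal shank tilt angle by gyro integration
#'
#' Cumulative trapezoidal integral of the sagittal angular velocity
#' `w_s[, 3]`, starting at zero. No detrending is applied here; the event
#' detector detrends its own copy.
#'
#' @param rec An [imu_recording].
#' @param flip_z Negate the z gyro first (mirror-mounted sensor).
#' @return Numeric vector `theta_z` (radians), same length as the recording.
#' @export
tilt_angle_series <- function(rec, flip_z = FALSE) {
  wz <- if (flip_z) -rec$w_s[, 3] else rec$w_s[, 3]
  cumtrapz(wz, rec$dt)
}

#' Detection configuration for gait events
#'
#' @param prominence_rad_s Minimum topographic prominence (rad/s) for
#'   omega_z peaks (heel-strike search). Default 0.2.
#' @param theta_prominence_rad Minimum prominence (rad) for tilt-angle
#'   extrema (SMF/SMB). Default 0.05.
#' @param min_distance_s Minimum separation between tilt extrema of the
#'   same kind, seconds. `NULL` (default) uses 0.25 x the median spacing of
#'   the prominence-filtered tilt maxima.
#' @param flip_z Negate omega_z before detection. Mounting-dependent: with
#'   the sensor z axis along the lab z axis (the simulator's convention,
#'   see the methods vignette) the printed rules apply to `-w_s[, 3]`, so
#'   the default is `TRUE`. Use `FALSE` for the mirror mounting.
#' @param detrend_tilt Remove a least-squares line from the tilt angle
#'   before the extremum search (gyro bias makes the raw integral drift).
#'   Default `TRUE`.
#' @return A list of class `gait_event_config`.
#' @export
gait_event_config <- function(prominence_rad_s = 0.2,
                              theta_prominence_rad = 0.05,
                              min_distance_s = NULL,
                              flip_z = TRUE,
                              detrend_tilt = TRUE) {
  stopifnot(prominence_rad_s >= 0, theta_prominence_rad >= 0)
  structure(list(prominence_rad_s = prominence_rad_s,
                 theta_prominence_rad = theta_prominence_rad,
                 min_distance_s = min_distance_s,
                 flip_z = isTRUE(flip_z),
                 detrend_tilt = isTRUE(detrend_tilt)),
            class = "gait_event_config")
}

#' Detect gait events and segment the recording into strides
#'
#' @param rec An [imu_recording].
#' @param tilt Optional precomputed tilt series (from
#'   [tilt_angle_series()] with the same `flip_z`); computed when `NULL`.
#' @param cfg A [gait_event_config()].
#' @return An object of class `stride_segmentation`: integer index vectors
#'   `smf_idx`, `smb_idx`, `hs_idx`, `to_idx`, `ms_idx`, a two-column
#'   matrix `segments` of half-open `[ms(i), ms(i+1))` sample-index pairs,
#'   the number of dropped cycles `dropped`, and `dt`.
#' @export
detect_gait_events <- function(rec, tilt = NULL, cfg = gait_event_config()) {
  wz <- if (cfg$flip_z) -rec$w_s[, 3] else rec$w_s[, 3]
  if (is.null(tilt)) tilt <- cumtrapz(wz, rec$dt)
  theta <- tilt
  if (cfg$detrend_tilt) {
    k <- seq_along(theta)
    theta <- stats::residuals(stats::lm.fit(cbind(1, k), theta))
  }

  # SMF/SMB: tilt extrema
  smf_raw <- find_peaks(theta, prominence = cfg$theta_prominence_rad)
  if (length(smf_raw) == 0L) {
    warning("no shank-max-forward events found; empty segmentation")
    return(empty_segmentation(rec$dt))
  }
  min_dist <- cfg$min_distance_s
  if (is.null(min_dist)) {
    min_dist <- if (length(smf_raw) > 1L)
      0.25 * stats::median(diff(smf_raw)) * rec$dt else 0
  }
  md <- round(min_dist / rec$dt)
  smf <- find_peaks(theta, cfg$theta_prominence_rad, md)
  smb <- find_troughs(theta, cfg$theta_prominence_rad, md)
  if (length(smb) == 0L) {
    warning("no shank-max-backward events found; empty segmentation")
    return(empty_segmentation(rec$dt))
  }

  # HS: first prominent omega peak after each SMF
  wpk <- find_peaks(wz, prominence = cfg$prominence_rad_s)
  hs <- integer(0)
  for (s in smf) {
    cand <- wpk[wpk > s]
    if (length(cand) > 0L) hs <- c(hs, cand[1])
  }
  hs <- sort(unique(hs))

  # cycles: HS -> TO (min before next SMB) -> MS (max strictly between)
  to <- integer(0); ms <- integer(0); dropped <- 0L
  for (h in hs) {
    nb <- smb[smb > h]
    if (length(nb) == 0L) next   # incomplete trailing cycle, not an error
    b <- nb[1]
    if (b - h < 3L) { dropped <- dropped + 1L; next }
    win <- (h + 1L):(b - 1L)
    t_i <- win[which.min(wz[win])]
    if (t_i - h < 2L) { dropped <- dropped + 1L; next }
    mwin <- (h + 1L):(t_i - 1L)
    m_i <- mwin[which.max(wz[mwin])]
    to <- c(to, t_i); ms <- c(ms, m_i)
  }
  if (dropped > 0L)
    message(dropped, " gait cycle(s) dropped (HS/TO ordering unsatisfied)")
  ms <- sort(unique(ms))

  seg <- if (length(ms) >= 2L)
    cbind(start = ms[-length(ms)], end = ms[-1]) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  structure(list(smf_idx = smf, smb_idx = smb, hs_idx = hs,
                 to_idx = sort(unique(to)), ms_idx = ms,
                 segments = seg, dropped = dropped, dt = rec$dt),
            class = "stride_segmentation")
}

empty_segmentation <- function(dt) {
  structure(list(smf_idx = integer(0), smb_idx = integer(0),
                 hs_idx = integer(0), to_idx = integer(0),
                 ms_idx = integer(0),
                 segments = matrix(integer(0), ncol = 2,
                                   dimnames = list(NULL, c("start", "end"))),
                 dropped = 0L, dt = dt),
            class = "stride_segmentation")
}

#' @export
print.stride_segmentation <- function(x, ...) {
  cat(sprintf(
    "<stride_segmentation> %d mid-stances, %d segments, %d HS, %d TO\n",
    length(x$ms_idx), nrow(x$segments), length(x$hs_idx), length(x$to_idx)))
  invisible(x)
}

#' Stride segments between successive mid-stances
#'
#' @param seg A `stride_segmentation` (or any list with `ms_idx`).
#' @return Two-column integer matrix of half-open `[ms(i), ms(i+1))`
#'   pairs; zero rows when fewer than two mid-stances exist.
#' @export
segment_strides <- function(seg) {
  ms <- seg$ms_idx
  if (length(ms) < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ms[-length(ms)], end = ms[-1])
}
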