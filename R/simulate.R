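# Walking-shank simulator with full ground truth.
#
# Planar sagittal model. Lab frame: x up, y forward, z lateral. The shank
# is a segment from the malleolus to the sensor at distance r; its tilt
# psi (0 = vertical, positive = sensor forward of the malleolus) follows a
# C1 piecewise-cosine angular-rate profile built so that the printed event
# rules (SMF/SMB from the tilt integral, HS/TO/MS from the rate) pick out
# the constructed events. During stance the malleolus is fixed (the
# inverted-pendulum assumption holds exactly, with only a small centripetal
# residual at mid-stance); during swing it advances by one stride length on
# a smooth lifted path (quintic smoothstep forward, cubed-sine lift), so
# velocity and acceleration are continuous at every phase join.
#
# Sensor mounting: x along the shank (to the knee), y anterior, z along
# the lab z axis, i.e. the sensor-to-lab rotation is a pure rotation about
# z by psi. With this mounting the mid-stance gravity alignment recovers
# the true orientation exactly (no unobservable yaw offset), which makes
# all lab-frame intermediates comparable with ground truth; the detection
# signal is then -w_s[, 3] (hence `flip_z = TRUE` by default downstream).

QUIET_STAND_S <- 1.0   # standing prefix, excluded from stride counting
MS_PLATEAU_PHASE <- 0.02   # half-width of the zero plateau when the shank
                           # is constructed exactly still at mid-stance

#' Simulator configuration
#'
#' Defaults describe normal adult gait: 1.2 m strides of 1.1 s with a 60%
#' stance phase, sensor 5 cm above the malleolus, shank tilt excursion of
#' about +/- 0.6 rad, 100 Hz sampling, noiseless sensors.
#'
#' @param n_strides Number of complete strides (mid-stance to mid-stance).
#' @param stride_length_m Commanded stride length, metres.
#' @param stride_duration_s Gait cycle duration, seconds.
#' @param stance_fraction Stance fraction of the cycle, in (0.1, 0.9).
#' @param r_m Sensor-to-malleolus distance, metres.
#' @param shank_tilt_amplitude_rad Half peak-to-peak sagittal tilt, rad.
#' @param fs_hz Sampling rate, Hz.
#' @param swing_lift_m Peak malleolus lift during swing, metres.
#' @param ms_rate_scale Scale on the mid-stance angular rate. 1 (default)
#'   gives a small non-zero shank rate at mid-stance (the regime where the
#'   pendulum update beats the zero-velocity update); 0 inserts a short
#'   zero-rate plateau so the shank is exactly still at mid-stance.
#' @param cycle_variability Standard deviation of the multiplicative
#'   stride-to-stride jitter on the mid-stance rate (default 0.1, i.e.
#'   about 10% variability, as in healthy gait; multipliers are clipped to
#'   keep the mid-stance the unique rate maximum of its stance phase).
#'   Set 0 for perfectly periodic cycles.
#' @param accel_sigma,gyro_sigma White-noise standard deviations
#'   (m/s^2, rad/s).
#' @param accel_bias,gyro_bias Constant per-axis biases (3-vectors).
#' @param seed Integer seed for the noise stream.
#' @return A list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_strides = 10L,
                            stride_length_m = 1.2,
                            stride_duration_s = 1.1,
                            stance_fraction = 0.6,
                            r_m = 0.05,
                            shank_tilt_amplitude_rad = 0.6,
                            fs_hz = 100,
                            swing_lift_m = 0.08,
                            ms_rate_scale = 1,
                            cycle_variability = 0.1,
                            accel_sigma = 0, gyro_sigma = 0,
                            accel_bias = c(0, 0, 0),
                            gyro_bias = c(0, 0, 0),
                            seed = 1L) {
  cfg <- list(n_strides = as.integer(n_strides),
              stride_length_m = stride_length_m,
              stride_duration_s = stride_duration_s,
              stance_fraction = stance_fraction,
              r_m = r_m,
              shank_tilt_amplitude_rad = shank_tilt_amplitude_rad,
              fs_hz = fs_hz,
              swing_lift_m = swing_lift_m,
              ms_rate_scale = ms_rate_scale,
              cycle_variability = cycle_variability,
              accel_sigma = accel_sigma, gyro_sigma = gyro_sigma,
              accel_bias = accel_bias, gyro_bias = gyro_bias,
              seed = as.integer(seed))
  class(cfg) <- "gait_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  s <- cfg$stance_fraction
  if (!(s > 0.1 && s < 0.9)) stop("stance_fraction must be in (0.1, 0.9)")
  if (cfg$fs_hz <= 0) stop("fs_hz must be > 0")
  if (cfg$r_m <= 0) stop("r_m must be > 0")
  if (cfg$n_strides < 1L) stop("n_strides must be >= 1")
  if (cfg$stride_duration_s <= 0) stop("stride_duration_s must be > 0")
  if (cfg$shank_tilt_amplitude_rad <= 0)
    stop("shank_tilt_amplitude_rad must be > 0")
  if (cfg$accel_sigma < 0 || cfg$gyro_sigma < 0)
    stop("noise sigmas must be >= 0")
  if (!(cfg$ms_rate_scale >= 0 && cfg$ms_rate_scale <= 1))
    stop("ms_rate_scale must be in [0, 1]")
  if (cfg$cycle_variability < 0) stop("cycle_variability must be >= 0")
  invisible(cfg)
}

# ---- piecewise-cosine rate profile --------------------------------------

# Relative template of the detection-convention rate (-psi_dot), in units
# of the overall amplitude A, for one cycle with mid-stance at phase 0.
# Values at the labelled nodes; the swing-peak value is solved so each
# cycle integrates to zero (periodic tilt). The mid-stance value may vary
# cycle to cycle (stride-to-stride variability) but must stay in (-0.4, 0)
# so that it remains the unique signed maximum between HS and TO.
template_rel_nodes <- function(s, ms_scale) {
  list(ms = c(0, -0.3 * ms_scale),
       to = c(s / 2, -2.8),
       peak = c(0.5, NA),                     # solved
       postmin = c(1 - s / 2 - 0.1 * (1 - s), -1.2),
       hs = c(1 - s / 2, -0.4),
       dip = c(1 - s / 2 + 0.2 * s, -1.5))
}

# segment integral of the cosine interpolant = mean value * width
seg_area <- function(ph, va) sum((va[-1] + va[-length(va)]) / 2 * diff(ph))

# Build the absolute node table (time in phase units relative to MS0) for
# standing + lead-in + n_strides cycles + tail; amplitude 1.
# `ms_values` carries the per-cycle mid-stance rate values (length
# n_strides + 1, for MS 0..n), allowing stride-to-stride variability; the
# swing-peak value of each cycle is solved so that the cycle's tilt
# integral is zero (periodic tilt despite the variability).
build_profile_nodes <- function(cfg, ms_values = NULL) {
  s <- cfg$stance_fraction
  n <- cfg$n_strides
  tmpl <- template_rel_nodes(s, cfg$ms_rate_scale)
  plateau <- cfg$ms_rate_scale == 0
  pw <- MS_PLATEAU_PHASE
  if (is.null(ms_values)) ms_values <- rep(tmpl$ms[2], n + 1L)

  ms_nodes <- function(j) {           # phase(s) and value(s) of MS node j
    if (plateau) list(ph = c(j - pw, j + pw), va = c(0, 0))
    else list(ph = j, va = ms_values[j + 1L])
  }

  # interior node run of cycle j (between MS j-1 and MS j), with the
  # swing peak as a free value p
  interior_run <- function(j, p) {
    list(ph = (j - 1) + c(tmpl$to[1], tmpl$peak[1], tmpl$postmin[1],
                          tmpl$hs[1], tmpl$dip[1]),
         va = c(tmpl$to[2], p, tmpl$postmin[2], tmpl$hs[2], tmpl$dip[2]))
  }

  # solve the swing peak of cycle j so the cycle (from the node closing
  # MS j-1 to the node opening MS j) integrates to zero; affine in p.
  # The tail (j = n + 1) closes on a virtual nominal mid-stance.
  solve_peak <- function(j) {
    m0 <- ms_nodes(j - 1)
    mj <- if (j > n) list(ph = j, va = tmpl$ms[2]) else ms_nodes(j)
    cyc_int <- function(p) {
      ir <- interior_run(j, p)
      seg_area(c(m0$ph[length(m0$ph)], ir$ph, mj$ph[1]),
               c(m0$va[length(m0$va)], ir$va, mj$va[1]))
    }
    i0 <- cyc_int(0); i1 <- cyc_int(1)
    -i0 / (i1 - i0)
  }

  # lead-in from quiet standing to MS0: initial forward sway (solved
  # amplitude b so the lead-in tilt integral is zero), then the
  # post-SMF / HS / dip signature of a terminal swing, pivoting in place
  lead_start <- -(s / 2 + 0.34)
  lead_run <- function(b) {
    ph <- c(lead_start, lead_start + 0.15, -s / 2 - 0.04, -s / 2,
            -s / 2 + 0.2 * s)
    va <- c(0, b, -1.2, -0.4, -1.5)
    m0 <- ms_nodes(0)
    list(ph = c(ph, m0$ph), va = c(va, m0$va))
  }
  lead_int <- function(b) { lr <- lead_run(b); seg_area(lr$ph, lr$va) }
  l0 <- lead_int(0); l1 <- lead_int(1)
  b <- -l0 / (l1 - l0)

  lr <- lead_run(b)
  ph <- lr$ph; va <- lr$va
  for (j in seq_len(n + 1L)) {
    ir <- interior_run(j, solve_peak(j))
    ph <- c(ph, ir$ph); va <- c(va, ir$va)
    if (j <= n) {
      msj <- ms_nodes(j)
      ph <- c(ph, msj$ph); va <- c(va, msj$va)
    }
  }

  if (any(diff(ph) <= 0))
    stop("profile nodes not strictly increasing; stance_fraction makes ",
         "the stance/swing profile non-C1 at a phase join")
  list(phase = ph, value = va, lead_start = lead_start, lead_peak = b)
}

# closed-form evaluation of the cosine interpolant and its derivative and
# integral on an arbitrary time grid
profile_eval <- function(tq, tau, val) {
  K <- length(tau)
  w <- diff(tau)
  dv <- diff(val)
  # node integrals of the interpolant
  Th <- c(0, cumsum((val[-K] + val[-1]) / 2 * w))
  j <- findInterval(tq, tau, rightmost.closed = TRUE)
  j[j < 1L] <- 1L; j[j > K - 1L] <- K - 1L
  u <- tq - tau[j]
  tt <- pmin(pmax(u / w[j], 0), 1)
  omega <- val[j] + dv[j] * (1 - cos(pi * tt)) / 2
  domega <- dv[j] * pi * sin(pi * tt) / (2 * w[j])
  theta <- Th[j] + val[j] * u + dv[j] / 2 * (u - w[j] / pi * sin(pi * tt))
  list(omega = omega, domega = domega, theta = theta)
}

# sign-change times of the interpolant (tilt extrema): exact within each
# cosine segment
profile_zero_crossings <- function(tau, val) {
  K <- length(tau)
  out <- data.frame(t = numeric(0), falling = logical(0))
  for (j in seq_len(K - 1L)) {
    v0 <- val[j]; v1 <- val[j + 1L]
    if (v0 == 0 || v0 * v1 >= 0) next
    ct <- 1 + 2 * v0 / (v1 - v0)
    tt <- acos(pmin(pmax(ct, -1), 1)) / pi
    out <- rbind(out, data.frame(t = tau[j] + tt * (tau[j + 1L] - tau[j]),
                                 falling = v0 > 0))
  }
  out
}

# quintic smoothstep and derivatives (zero 1st/2nd derivative at 0 and 1)
sstep <- function(x) x^3 * (10 - 15 * x + 6 * x^2)
sstep1 <- function(x) 30 * x^2 - 60 * x^3 + 30 * x^4
sstep2 <- function(x) 60 * x - 180 * x^2 + 120 * x^3

#' Simulate a walking trial with full ground truth
#'
#' Generates the sensor streams (gyro, accelerometer with gravity) of a
#' shank-mounted IMU during walking, together with the true sensor
#' trajectory, velocity, gait events and per-stride parameters. A 1 s
#' quiet-standing prefix precedes the first mid-stance; the recording ends
#' shortly after the heel strike following the last counted mid-stance so
#' every stride has a defined duration. Noise/bias from the configuration
#' is applied with [add_sensor_noise()] (ground truth is recorded before
#' noise).
#'
#' @param cfg A [gait_sim_config()].
#' @return Object of class `synthetic_trial`: `rec` ([imu_recording]),
#'   `truth_p`, `truth_v`, `truth_a` (n x 3 lab-frame sensor kinematics),
#'   `truth_psi` (shank tilt), `truth_events` (sample indices and times of
#'   SMF/SMB/HS/TO/MS), `truth_params` (per-stride table), `config`.
#' @export
simulate_walk <- function(cfg = gait_sim_config()) {
  validate_sim_config(cfg)
  s <- cfg$stance_fraction
  T <- cfg$stride_duration_s
  L <- cfg$stride_length_m
  n <- cfg$n_strides
  r <- cfg$r_m
  dt <- 1 / cfg$fs_hz
  fc <- frame_convention()

  # single RNG stream: cycle-variability draws first, then sensor noise
  set.seed(cfg$seed)
  ms_values <- NULL
  if (cfg$ms_rate_scale > 0 && cfg$cycle_variability > 0) {
    mult <- 1 + cfg$cycle_variability * stats::rnorm(n + 1L)
    mult <- pmin(pmax(mult, 0.2), 1.3)
    ms_values <- -0.3 * cfg$ms_rate_scale * mult
  }
  prof <- build_profile_nodes(cfg, ms_values)
  t_ms0 <- QUIET_STAND_S - prof$lead_start * T
  tau <- c(0, t_ms0 + prof$phase * T)     # absolute node times, s
  val <- c(0, prof$value)                 # standing prefix value 0

  # amplitude: scale so the tilt spans +/- shank_tilt_amplitude_rad
  ph_dense <- seq(0, 1, length.out = 2001)
  th_dense <- profile_eval(t_ms0 + ph_dense * T, tau, val)$theta
  rng <- max(th_dense) - min(th_dense)
  A <- 2 * cfg$shank_tilt_amplitude_rad / rng
  val <- val * A

  t_end <- tau[length(tau)]
  t <- seq(0, t_end, by = dt)
  N <- length(t)

  pe <- profile_eval(t, tau, val)
  theta_ms0 <- profile_eval(t_ms0, tau, val)$theta
  psi <- -(pe$theta - theta_ms0)
  psid <- -pe$omega
  psidd <- -pe$domega

  # malleolus schedule: swing j occupies u in [j-1, j-1+(1-s)] where
  # u = (t - t_ms0)/T - s/2
  u <- (t - t_ms0) / T - s / 2
  j <- floor(u) + 1
  frac <- u - (j - 1)
  w_sw <- (1 - s) * T
  ttau <- pmin(pmax(frac / (1 - s), 0), 1)
  active <- j >= 1 & j <= (n + 1) & frac >= 0 & frac <= (1 - s)
  prog <- pmin(pmax((j - 1) + sstep(ttau), 0), n + 1)
  m_y <- L * prog
  m_x <- ifelse(active, cfg$swing_lift_m * sin(pi * ttau)^3, 0)
  m_yd <- ifelse(active, L * sstep1(ttau) / w_sw, 0)
  m_ydd <- ifelse(active, L * sstep2(ttau) / w_sw^2, 0)
  sp <- sin(pi * ttau); cp <- cos(pi * ttau)
  m_xd <- ifelse(active, cfg$swing_lift_m * 3 * pi * sp^2 * cp / w_sw, 0)
  m_xdd <- ifelse(active,
                  cfg$swing_lift_m * 3 * pi^2 *
                    (2 * sp * cp^2 - sp^3) / w_sw^2, 0)

  cpsi <- cos(psi); spsi <- sin(psi)
  truth_p <- cbind(m_x + r * cpsi, m_y + r * spsi, 0)
  truth_v <- cbind(m_xd - r * psid * spsi, m_yd + r * psid * cpsi, 0)
  truth_a <- cbind(m_xdd - r * psidd * spsi - r * psid^2 * cpsi,
                   m_ydd + r * psidd * cpsi - r * psid^2 * spsi, 0)

  # sensor streams: rotation sensor->lab is Rz(psi)
  f_x <- truth_a[, 1] + fc$g_mag
  f_y <- truth_a[, 2]
  a_s <- cbind(cpsi * f_x + spsi * f_y, -spsi * f_x + cpsi * f_y, 0)
  w_s <- cbind(0, 0, psid)
  rec <- imu_recording(t = t, a_s = a_s, w_s = w_s, side = "right", dt = dt)

  # ground-truth events
  t_ms <- t_ms0 + (0:n) * T
  t_hs <- t_ms0 + c(-s / 2 * T, ((1:(n + 1)) - s / 2) * T)
  t_to <- t_ms0 + ((1:(n + 1)) - 1 + s / 2) * T
  zc <- profile_zero_crossings(tau, val)
  t_smf <- zc$t[zc$falling]
  t_smb <- zc$t[!zc$falling]
  to_idx <- function(tv) as.integer(round(tv / dt)) + 1L
  truth_events <- list(
    ms_idx = to_idx(t_ms), hs_idx = to_idx(t_hs), to_idx = to_idx(t_to),
    smf_idx = to_idx(t_smf), smb_idx = to_idx(t_smb),
    ms_t = t_ms, hs_t = t_hs, to_t = t_to, smf_t = t_smf, smb_t = t_smb)

  # per-stride truth from the sampled true trajectory
  msi <- truth_events$ms_idx
  hsi <- truth_events$hs_idx[-1]          # HS of cycles 1..n+1
  toi <- truth_events$to_idx
  truth_params <- empty_stride_table(n)
  for (i in seq_len(n)) {
    k0 <- msi[i]; k1 <- msi[i + 1]
    len <- truth_p[k1, 2] - truth_p[k0, 2]
    vert <- max(truth_p[(k0 + 1):(k1 - 1), 1] - truth_p[k0, 1])
    dur <- (hsi[i + 1] - hsi[i]) * dt
    truth_params[i, ] <- data.frame(
      side = "right", stride_index = i,
      ms_start_s = t[k0], ms_end_s = t[k1],
      hs_s = t[hsi[i]], to_s = t[toi[i]],
      stride_length_m = len, vertical_disp_m = vert,
      duration_s = dur, velocity_mps = len / dur)
  }

  trial <- structure(list(rec = rec, truth_p = truth_p, truth_v = truth_v,
                          truth_a = truth_a, truth_psi = psi,
                          truth_events = truth_events,
                          truth_params = truth_params, config = cfg),
                     class = "synthetic_trial")
  if (cfg$accel_sigma > 0 || cfg$gyro_sigma > 0 ||
      any(cfg$accel_bias != 0) || any(cfg$gyro_bias != 0)) {
    trial <- add_sensor_noise(trial, accel_sigma = cfg$accel_sigma,
                              gyro_sigma = cfg$gyro_sigma,
                              accel_bias = cfg$accel_bias,
                              gyro_bias = cfg$gyro_bias, seed = NULL)
  }
  trial
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %d strides of %.2f m / %.2f s, %d samples @ %g Hz\n",
    x$config$n_strides, x$config$stride_length_m,
    x$config$stride_duration_s, x$rec$n, x$config$fs_hz))
  invisible(x)
}

#' Add sensor noise and bias to a synthetic trial
#'
#' Adds i.i.d. Gaussian noise and a constant bias to each sensor channel
#' of the recording. Ground-truth fields are untouched. The accelerometer
#' noise matrix is drawn first, then the gyroscope matrix, from a single
#' stream seeded with `seed`.
#'
#' @param trial A [simulate_walk()] result.
#' @param accel_sigma,gyro_sigma Standard deviations (m/s^2, rad/s), >= 0.
#' @param accel_bias,gyro_bias Constant per-axis biases (3-vectors).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The trial with a noisy `rec`.
#' @export
add_sensor_noise <- function(trial, accel_sigma = 0, gyro_sigma = 0,
                             accel_bias = c(0, 0, 0),
                             gyro_bias = c(0, 0, 0), seed = NULL) {
  if (accel_sigma < 0 || gyro_sigma < 0) stop("noise sigmas must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rec <- trial$rec
  n <- rec$n
  na <- matrix(stats::rnorm(3 * n), n, 3)
  ng <- matrix(stats::rnorm(3 * n), n, 3)
  rec$a_s <- rec$a_s + accel_sigma * na +
    matrix(accel_bias, n, 3, byrow = TRUE)
  rec$w_s <- rec$w_s + gyro_sigma * ng +
    matrix(gyro_bias, n, 3, byrow = TRUE)
  trial$rec <- rec
  trial
}
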