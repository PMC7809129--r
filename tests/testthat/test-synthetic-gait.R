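test_that("simulator honours the commanded stride parameters", {
  trial <- simulate_walk(quick_cfg(stride_length_m = 1.2,
                                   stride_duration_s = 1.1))
  tp <- trial$truth_params
  expect_equal(nrow(tp), 5L)
  expect_equal(tp$stride_length_m, rep(1.2, 5), tolerance = 1e-9)
  expect_equal(tp$duration_s, rep(1.1, 5), tolerance = 1e-9)
  expect_equal(tp$velocity_mps, rep(1.2 / 1.1, 5), tolerance = 1e-9)
  expect_true(all(tp$vertical_disp_m > 0))
  expect_length(trial$truth_events$ms_idx, 6L)
  # events are ordered: hs(i) < ms(i) < to(i+1)
  ev <- trial$truth_events
  expect_true(all(ev$hs_t[-1] - (ev$ms_t + 0) <
                    trial$config$stride_duration_s))
  expect_true(all(ev$hs_t[1:6] < ev$ms_t))
  expect_true(all(ev$ms_t < ev$to_t[1:6] + 1e-12))
})

test_that("same seed gives bit-identical trials", {
  cfg <- gait_sim_config(n_strides = 3L, accel_sigma = 0.05,
                         gyro_sigma = 0.01, seed = 42L)
  t1 <- simulate_walk(cfg)
  t2 <- simulate_walk(cfg)
  expect_identical(t1$rec$a_s, t2$rec$a_s)
  expect_identical(t1$rec$w_s, t2$rec$w_s)
  expect_identical(t1$truth_p, t2$truth_p)
})

test_that("the malleolus is stationary during every stance pivot", {
  trial <- simulate_walk(quick_cfg())
  m <- trial$truth_p -
    trial$config$r_m * cbind(cos(trial$truth_psi),
                             sin(trial$truth_psi), 0)
  ev <- trial$truth_events
  dt <- trial$rec$dt
  # stance spans heel strike to the next toe off
  for (j in seq_along(ev$to_t)) {
    k <- which(trial$rec$t >= ev$hs_t[j] + dt &
                 trial$rec$t <= ev$to_t[j] - dt)
    expect_lt(max(abs(sweep(m[k, , drop = FALSE], 2, m[k[1], ]))), 1e-12)
  }
})

test_that("truth kinematics are self-consistent (derivatives integrate
           back; finite differences match)", {
  trial <- simulate_walk(quick_cfg(n_strides = 2L, fs_hz = 1000))
  dt <- trial$rec$dt
  v_num <- integrate_velocity(trial$truth_a, dt, trial$truth_v[1, ])
  expect_lt(max(abs(v_num - trial$truth_v)), 1e-3)
  p_num <- integrate_position(trial$truth_v, dt, trial$truth_p[1, ])
  expect_lt(max(abs(p_num - trial$truth_p)), 1e-3)
  n <- trial$rec$n
  v_fd <- (trial$truth_p[3:n, ] - trial$truth_p[1:(n - 2), ]) / (2 * dt)
  expect_lt(max(abs(v_fd - trial$truth_v[2:(n - 1), ])), 1e-3)
})

test_that("sensor noise has the requested statistics and biases drift
           the tilt integral", {
  clean <- simulate_walk(gait_sim_config(n_strides = 35L, fs_hz = 1000,
                                         cycle_variability = 0))
  noisy <- add_sensor_noise(clean, accel_sigma = 0.05, seed = 9L)
  d <- noisy$rec$a_s - clean$rec$a_s
  expect_gt(length(d), 1e5)
  expect_equal(stats::sd(d), 0.05, tolerance = 0.05 * 0.05)
  expect_identical(noisy$truth_p, clean$truth_p)

  # zero noise is the identity
  same <- add_sensor_noise(clean, 0, 0, c(0, 0, 0), c(0, 0, 0), seed = 1)
  expect_identical(same$rec$a_s, clean$rec$a_s)

  # constant gyro bias appears as a linear tilt drift on the quiet prefix
  small <- simulate_walk(quick_cfg(n_strides = 2L))
  biased <- add_sensor_noise(small, gyro_bias = c(0, 0, 0.01))
  th <- tilt_angle_series(biased$rec, flip_z = FALSE)
  pre <- which(biased$rec$t <= 0.9)
  slope <- stats::coef(stats::lm(th[pre] ~ biased$rec$t[pre]))[2]
  expect_equal(unname(slope), 0.01, tolerance = 1e-6)
  expect_error(add_sensor_noise(small, accel_sigma = -1), "sigmas")
})

test_that("configuration validation rejects impossible worlds", {
  expect_error(gait_sim_config(stance_fraction = 0.05), "stance_fraction")
  expect_error(gait_sim_config(fs_hz = 0), "fs_hz")
  expect_error(gait_sim_config(r_m = -0.1), "r_m")
  expect_error(gait_sim_config(n_strides = 0), "n_strides")
  expect_error(gait_sim_config(accel_sigma = -0.1), "sigmas")
  expect_error(gait_sim_config(ms_rate_scale = 2), "ms_rate_scale")
})
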