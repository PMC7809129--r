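test_that("integrate_velocity is exact for constant and linear rates", {
  n <- 101; dt <- 0.01
  v <- integrate_velocity(matrix(rep(c(0, 1, 0), each = n), n, 3), dt)
  expect_equal(v[n, ], c(0, 1, 0), tolerance = 1e-12)
  v0 <- c(0.3, -0.2, 1)
  vz <- integrate_velocity(matrix(0, n, 3), dt, v0)
  expect_true(all(abs(sweep(vz, 2, v0)) < 1e-15))
  ramp <- cbind(seq(0, 2, length.out = n), 0, 0)
  vr <- integrate_velocity(ramp, dt)
  expect_equal(vr[n, 1], 1.0, tolerance = 1e-12)
})

test_that("ipm_update_velocity is the tangential velocity", {
  r <- 0.05; w <- 2.0; g <- 9.80665
  # identity attitude, rotation about z, lever along lab x
  v <- ipm_update_velocity(quat_identity(), c(0, 0, w), c(g, 0, 0), r)
  expect_equal(v, c(0, w * r, 0), tolerance = 1e-12)
  expect_equal(ipm_update_velocity(quat_identity(), c(0, 0, 0),
                                   c(g, 0, 0), r), c(0, 0, 0))
  expect_error(ipm_update_velocity(quat_identity(), c(0, 0, 1),
                                   c(g, 0, 0), -1), "r must be")
  expect_equal(zupt_update_velocity(), c(0, 0, 0))
})

test_that("update velocity matches the simulator's true sensor velocity
           at mid-stance", {
  # cycle duration 1.0 s puts every mid-stance exactly on the sample grid
  trial <- simulate_walk(quick_cfg(stride_duration_s = 1.0))
  for (k in trial$truth_events$ms_idx) {
    q <- quat_from_gravity(trial$rec$a_s[k, ])
    v <- ipm_update_velocity(q, trial$rec$w_s[k, ], trial$rec$a_s[k, ],
                             trial$config$r_m)
    expect_equal(v, trial$truth_v[k, ], tolerance = 1e-6)
  }
})

test_that("remove_drift anchors both endpoints and kills linear drift", {
  # pure linear drift, zero update velocities -> exact zero output
  k <- 0:10
  v_raw <- cbind(0.01 * k, 0, 0)
  out <- remove_drift(v_raw, c(0, 0, 0), c(0, 0, 0))
  expect_equal(out$alpha, c(0.01, 0, 0), tolerance = 1e-15)
  expect_equal(out$beta, c(0, 0, 0))
  expect_true(all(abs(out$v_corr) < 1e-15))
  # drift-free input with matching updates is returned unchanged
  v2 <- matrix(stats::rnorm(33), 11, 3)
  v2[1, ] <- c(1, 2, 3); v2[11, ] <- c(4, 5, 6)
  out2 <- remove_drift(v2, c(1, 2, 3), c(4, 5, 6))
  expect_equal(out2$alpha, c(0, 0, 0))
  expect_equal(out2$v_corr, v2)
  expect_error(remove_drift(v2[1, , drop = FALSE], c(0, 0, 0),
                            c(0, 0, 0)), "at least 2")
})

test_that("arbitrary linear drift is removed exactly when updates equal
           the true endpoint velocities (property)", {
  set.seed(301)
  for (i in 1:50) {
    m <- sample(5:200, 1)
    k <- 0:m
    v_true <- matrix(stats::rnorm(3 * (m + 1)), ncol = 3)
    alpha <- stats::rnorm(3, sd = 0.01)
    beta <- stats::rnorm(3, sd = 0.1)
    v_raw <- v_true + outer(k, alpha) +
      matrix(beta, m + 1, 3, byrow = TRUE)
    out <- remove_drift(v_raw, v_true[1, ], v_true[m + 1, ])
    expect_equal(out$v_corr, v_true, tolerance = 1e-12)
    expect_equal(out$v_corr[1, ], v_true[1, ], tolerance = 1e-12)
    expect_equal(out$v_corr[m + 1, ], v_true[m + 1, ], tolerance = 1e-12)
  }
})

test_that("the drift model reproduces its endpoint mismatches", {
  set.seed(302)
  m <- 77
  v_raw <- matrix(stats::rnorm(3 * (m + 1)), ncol = 3)
  vs <- stats::rnorm(3); ve <- stats::rnorm(3)
  out <- remove_drift(v_raw, vs, ve)
  expect_equal(out$beta, v_raw[1, ] - vs, tolerance = 1e-15)
  expect_equal(out$alpha * m + out$beta, v_raw[m + 1, ] - ve,
               tolerance = 1e-12)
})
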