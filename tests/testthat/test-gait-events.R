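# independent cosine interpolator used to build signals with hand-placed
# extrema (extrema fall exactly on the node samples)
cos_interp <- function(t, node_t, node_v) {
  sapply(t, function(x) {
    j <- max(1, min(findInterval(x, node_t), length(node_t) - 1))
    tau <- (x - node_t[j]) / (node_t[j + 1] - node_t[j])
    tau <- min(max(tau, 0), 1)
    node_v[j] + (node_v[j + 1] - node_v[j]) * (1 - cos(pi * tau)) / 2
  })
}

test_that("tilt_angle_series integrates the sagittal rate", {
  t <- seq(0, 1, by = 0.01)
  mk <- function(wz) imu_recording(t, gravity_accel(101),
                                   cbind(0, 0, wz))
  expect_equal(tilt_angle_series(mk(rep(0, 101))), rep(0, 101))
  th <- tilt_angle_series(mk(rep(1, 101)))
  expect_equal(th[101], 1.0, tolerance = 1e-9)
  expect_equal(th[1], 0)
  th2 <- tilt_angle_series(mk(sin(2 * pi * t)))
  expect_lt(abs(th2[101]), 1e-4)
  # flip_z negates
  expect_equal(tilt_angle_series(mk(rep(1, 101)), flip_z = TRUE)[101], -1,
               tolerance = 1e-9)
})

test_that("detection recovers hand-placed extrema exactly", {
  # three cycles of the canonical shank signature plus lead-in and tail
  nt <- c(0, 0.30, 0.45, 0.60, 0.65, 0.75, 1.00)
  nv <- c(0, 0,    1.0,  -1.2, -0.4, -1.5, -0.3)
  for (k in 0:2) {
    base <- 1.0 + 1.1 * k
    nt <- c(nt, base + c(0.33, 0.55, 0.73, 0.77, 0.90),
            if (k < 2) base + 1.1)
    nv <- c(nv, c(-2.8, 6.0, -1.2, -0.4, -1.5), if (k < 2) -0.3)
  }
  t <- seq(0, max(nt), by = 0.01)
  wz <- cos_interp(t, nt, nv)
  rec <- imu_recording(t, gravity_accel(length(t)),
                       cbind(0, 0, wz))
  seg <- detect_gait_events(rec, cfg = gait_event_config(flip_z = FALSE))
  idx <- function(x) as.integer(round(x / 0.01)) + 1L
  expect_equal(seg$ms_idx, idx(c(1.0, 2.1, 3.2)))
  expect_equal(seg$hs_idx, idx(c(0.65, 1.77, 2.87, 3.97)))
  expect_equal(seg$to_idx, idx(c(1.33, 2.43, 3.53)))
  expect_equal(nrow(seg$segments), 2L)
})

test_that("detection is invariant to a constant time offset", {
  trial <- simulate_walk(quick_cfg())
  rec2 <- trial$rec
  rec2$t <- rec2$t + 1234.5
  s1 <- detect_gait_events(trial$rec)
  s2 <- detect_gait_events(rec2)
  expect_identical(s1$ms_idx, s2$ms_idx)
  expect_identical(s1$hs_idx, s2$hs_idx)
  expect_identical(s1$to_idx, s2$to_idx)
})

test_that("flat signal yields an empty segmentation with a warning", {
  t <- seq(0, 3, by = 0.01)
  rec <- imu_recording(t, gravity_accel(length(t)),
                       matrix(0, length(t), 3))
  expect_warning(seg <- detect_gait_events(rec), "no shank-max-forward")
  expect_length(seg$ms_idx, 0)
  expect_equal(nrow(seg$segments), 0L)
})

test_that("segment_strides forms half-open mid-stance pairs", {
  seg <- list(ms_idx = c(100L, 210L, 330L))
  s <- segment_strides(seg)
  expect_equal(unname(s), cbind(c(100L, 210L), c(210L, 330L)))
  expect_equal(nrow(segment_strides(list(ms_idx = 50L))), 0L)
})

test_that("each detected segment contains exactly one stance phase", {
  trial <- simulate_walk(quick_cfg(n_strides = 6L))
  seg <- detect_gait_events(trial$rec)
  for (i in seq_len(nrow(seg$segments))) {
    k0 <- seg$segments[i, 1]; k1 <- seg$segments[i, 2]
    expect_equal(sum(seg$hs_idx >= k0 & seg$hs_idx < k1), 1L)
    expect_equal(sum(seg$to_idx >= k0 & seg$to_idx < k1), 1L)
    expect_equal(sum(trial$truth_events$to_idx >= k0 &
                       trial$truth_events$to_idx < k1), 1L)
  }
})
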