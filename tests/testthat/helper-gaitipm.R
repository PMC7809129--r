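# Shared fixtures and independent oracles.

# random unit quaternion
rand_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# independent oracle: Hamilton product via the 4x4 left-multiplication
# matrix of p
quat_mult_oracle <- function(p, q) {
  L <- matrix(c(p[1], -p[2], -p[3], -p[4],
                p[2],  p[1], -p[4],  p[3],
                p[3],  p[4],  p[1], -p[2],
                p[4], -p[3],  p[2],  p[1]), 4, 4, byrow = TRUE)
  as.numeric(L %*% q)
}

# independent oracle: Rodrigues rotation of u about unit axis by angle
rodrigues <- function(axis, angle, u) {
  k <- axis / sqrt(sum(axis^2))
  u * cos(angle) + cross3_oracle(k, u) * sin(angle) +
    k * sum(k * u) * (1 - cos(angle))
}

cross3_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# small, fast simulator configs for tests
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_strides = 5L, cycle_variability = 0)
  defaults[names(args)] <- args
  do.call(gait_sim_config, defaults)
}

# n x 3 accelerometer matrix reading pure gravity (sensor upright)
gravity_accel <- function(n) cbind(rep(9.80665, n), 0, 0)

# write a minimal IMU CSV; returns the path
write_test_imu_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
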