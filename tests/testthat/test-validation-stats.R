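mk_strides <- function(ms, len, vel = len / 1.1) {
  data.frame(ms_start_s = ms, stride_length_m = len, velocity_mps = vel)
}

test_that("pair_strides matches by mid-stance time with exclusions", {
  a <- mk_strides(c(1, 2.1, 3.2), c(1.2, 1.3, 1.1))
  p <- pair_strides(a, a, tol_s = 0.1)
  expect_equal(nrow(p$est), 3L)
  expect_equal(p$n_unmatched_est, 0L)

  b <- a[-2, ]
  expect_message(p2 <- pair_strides(a, b, tol_s = 0.1), "unmatched")
  expect_equal(nrow(p2$est), 2L)
  expect_equal(p2$n_unmatched_est, 1L)

  # jitter below tolerance still matches fully
  set.seed(501)
  cj <- a
  cj$ms_start_s <- cj$ms_start_s + stats::runif(3, -0.05, 0.05)
  p3 <- pair_strides(a, cj, tol_s = 0.1)
  expect_equal(nrow(p3$est), 3L)
  expect_equal(p3$est$stride_length_m, p3$ref$stride_length_m)

  expect_warning(pair_strides(a[0, ], a, tol_s = 0.1), "empty")
})

test_that("agreement reproduces hand-computed statistics", {
  est <- mk_strides(1:4, c(1.0, 2.0, 3.0, 4.0))
  ref <- mk_strides(1:4, c(1.1, 1.9, 3.0, 4.2))
  st <- agreement(list(est = est, ref = ref), "stride_length_m")
  expect_equal(st$n, 4L)
  expect_equal(st$mean_error, -0.05)
  expect_equal(st$mean_abs_error, 0.10)
  expect_equal(st$ba_bias, -0.05)
  expect_equal(st$ba_loa_high - st$ba_loa_low, 2 * 1.96 * st$sd_error,
               tolerance = 1e-9)
  expect_true(st$pearson_r >= -1 && st$pearson_r <= 1)

  # identical non-constant series: zero error, r = 1
  st2 <- agreement(list(est = est, ref = est), "stride_length_m")
  expect_equal(st2$mean_error, 0)
  expect_equal(st2$pearson_r, 1)
  # constant series: r undefined and flagged
  cst <- mk_strides(1:4, rep(1.2, 4))
  st3 <- agreement(list(est = cst, ref = cst), "stride_length_m")
  expect_false(st3$r_defined)
  expect_true(is.na(st3$pearson_r))
})

test_that("agreement is antisymmetric and scale-equivariant", {
  set.seed(502)
  est <- mk_strides(1:30, stats::rnorm(30, 1.25, 0.1))
  ref <- mk_strides(1:30, est$stride_length_m + stats::rnorm(30, 0, 0.02))
  a1 <- agreement(list(est = est, ref = ref), "stride_length_m")
  a2 <- agreement(list(est = ref, ref = est), "stride_length_m")
  expect_equal(a1$mean_error, -a2$mean_error)
  expect_equal(a1$mean_abs_error, a2$mean_abs_error)
  cc <- 2.5
  es <- est; rs <- ref
  es$stride_length_m <- cc * es$stride_length_m
  rs$stride_length_m <- cc * rs$stride_length_m
  a3 <- agreement(list(est = es, ref = rs), "stride_length_m")
  expect_equal(a3$ba_bias, cc * a1$ba_bias)
  expect_equal(a3$ba_loa_high, cc * a1$ba_loa_high)
  expect_equal(a3$pearson_r, a1$pearson_r, tolerance = 1e-12)
})

test_that("Monte-Carlo bias and limits of agreement are recovered", {
  set.seed(503)
  n <- 1e4
  ref <- mk_strides(seq_len(n), stats::rnorm(n, 1.25, 0.1))
  est <- ref
  est$stride_length_m <- ref$stride_length_m +
    stats::rnorm(n, 0.006, 0.025)
  st <- agreement(list(est = est, ref = ref), "stride_length_m")
  expect_lt(abs(st$ba_bias - 0.006), 0.001)
  width <- st$ba_loa_high - st$ba_loa_low
  expect_lt(abs(width - 2 * 1.96 * 0.025), 0.02 * 2 * 1.96 * 0.025)
})

test_that("zero reference values are excluded from the relative metric", {
  est <- mk_strides(1:3, c(1.0, 2.0, 3.0))
  ref <- mk_strides(1:3, c(0.0, 2.0, 3.0))
  expect_message(st <- agreement(list(est = est, ref = ref),
                                 "stride_length_m"), "zero reference")
  expect_equal(st$mean_rel_abs_error_pct, 0)
  expect_equal(st$n, 3L)
})
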