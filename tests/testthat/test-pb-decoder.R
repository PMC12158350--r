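enc_pair <- function(v1, v2, sampling = sampling_config(),
                     cfg = encoder_config()) {
  combine_signals(
    encode_signal(sample_sinusoid(v1, sampling), cfg, amplitude = v1$r),
    encode_signal(sample_sinusoid(v2, sampling), cfg, amplitude = v2$r))
}

test_that("decode_values reads the shifted sum profile off the bits", {
  cfg <- encoder_config()
  zero <- combine_signals(
    encode_signal(sample_sinusoid(polar_vector(0, 0)), cfg),
    encode_signal(sample_sinusoid(polar_vector(0, 0)), cfg))
  expect_true(all(decode_values(zero)$values == 0))

  const <- decode_values(enc_pair(polar_vector(3, 0), polar_vector(3, pi)))
  expect_lte(max(abs(const$values - 3)), 1 / cfg$k + 1e-12)

  w <- decode_values(enc_pair(polar_vector(3, 0), polar_vector(4, pi / 2)))
  expect_equal(max(w$values) - min(w$values), 5, tolerance = 2 / (5 * cfg$k))
})

test_that("locate_peak finds on-grid peaks exactly in both modes", {
  s <- sample_sinusoid(polar_vector(2, pi / 2))
  for (mode in c("refined", "argmax")) {
    pk <- locate_peak(s, mode)
    expect_equal(pk$peak_index, 90L)
    expect_equal(pk$theta_offset, pi / 2, tolerance = 1e-9)
  }
  expect_error(locate_peak(sample_sinusoid(polar_vector(0, 0))), "constant")
})

test_that("refined mode reaches sub-sample phase accuracy off grid", {
  cfg <- sampling_config(360)
  s <- sample_sinusoid(polar_vector(5, 1.0), cfg)
  expect_lt(angular_error(locate_peak(s, "refined")$theta_offset, 1.0), 1e-6)
  expect_lt(angular_error(locate_peak(s, "argmax")$theta_offset, 1.0),
            cfg$delta_theta / 2 + 1e-9)
})

test_that("argmax ties straddling the true peak resolve to their circular mean", {
  cfg <- sampling_config(360)
  # true phase exactly between grid points 0 and 1: samples 1 and 2 tie
  theta <- cfg$delta_theta / 2
  s <- sample_sinusoid(polar_vector(1, theta), cfg)
  expect_equal(sort(which(s$values >= max(s$values) - 1e-12)), c(1L, 2L))
  pk <- locate_peak(s, "argmax")
  expect_equal(pk$theta_offset, theta, tolerance = 1e-9)

  # tie wrapping across the 0/2*pi boundary
  theta_wrap <- 2 * pi - cfg$delta_theta / 2
  s2 <- sample_sinusoid(polar_vector(1, theta_wrap), cfg)
  pk2 <- locate_peak(s2, "argmax")
  expect_lt(angular_error(pk2$theta_offset, theta_wrap), 1e-9)
})

test_that("decode_signal recovers the vector sum within quantization", {
  k <- 20
  dtheta <- 2 * pi / 360
  d <- decode_signal(enc_pair(polar_vector(3, 0), polar_vector(4, pi / 2)))
  expect_lt(abs(d$r - 5), 2 / k)
  expect_lt(angular_error(d$theta, 0.92730), dtheta / 2)

  # identity: v + zero vector
  v <- polar_vector(6.4, 2.2)
  di <- decode_signal(enc_pair(v, polar_vector(0, 0)))
  expect_lt(abs(di$r - v$r), 2 / k)
  expect_lt(angular_error(di$theta, v$theta), dtheta / 2)

  # collinear doubling
  dc <- decode_signal(enc_pair(polar_vector(4.1, 0.9), polar_vector(4.1, 0.9)))
  expect_lt(abs(dc$r - 8.2), 2 / k)
  expect_lt(angular_error(dc$theta, 0.9), dtheta / 2)

  # degenerate (cancelled) profile decodes to the zero vector
  dz <- decode_signal(enc_pair(polar_vector(2, 1), polar_vector(2, 1 + pi)))
  expect_lte(dz$r, 2 / k)
})

test_that("decoded sums track the closed-form oracle over random pairs", {
  k <- 20
  dtheta <- 2 * pi / 360
  pairs <- random_polar_pairs(300, seed = 13)
  for (i in seq_len(nrow(pairs))) {
    v1 <- polar_vector(pairs$r1[i], pairs$theta1[i])
    v2 <- polar_vector(pairs$r2[i], pairs$theta2[i])
    truth <- vector_sum(v1, v2)
    d <- decode_signal(enc_pair(v1, v2))
    expect_lt(abs(d$r - truth$r), 2 / k + 1e-9)
    if (truth$r > 0.5) {
      expect_lt(angular_error(d$theta, truth$theta), dtheta / 2 + 1e-9)
    }
  }
})

test_that("decoding is rotation-equivariant and scale-covariant", {
  v1 <- polar_vector(3.7, 0.6)
  v2 <- polar_vector(5.1, 2.8)
  base <- decode_signal(enc_pair(v1, v2))
  for (delta in c(0.3, 1.7, 4.4)) {
    rot <- decode_signal(enc_pair(polar_vector(v1$r, v1$theta + delta),
                                  polar_vector(v2$r, v2$theta + delta)))
    expect_lt(angular_error(rot$theta, base$theta + delta),
              2 * pi / 360 + 1e-9)
    expect_lt(abs(rot$r - base$r), 2 / 20 + 1e-9)
  }
  half <- decode_signal(enc_pair(polar_vector(v1$r / 2, v1$theta),
                                 polar_vector(v2$r / 2, v2$theta)))
  expect_lt(abs(2 * half$r - base$r), 2 * (2 / 20) + 1e-9)
})
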