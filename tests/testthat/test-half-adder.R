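test_that("half_adder interleaves OR and AND lines", {
  expect_identical(half_adder(c(1L, 0L), c(1L, 0L)), c(1L, 1L, 0L, 0L))
  expect_identical(half_adder(c(1L, 1L, 0L), c(1L, 0L, 0L)),
                   c(1L, 1L, 1L, 0L, 0L, 0L))
  # all-zero input is the identity in popcount
  x <- c(1L, 1L, 0L, 0L)
  expect_equal(sum(half_adder(x, rep(0L, 4))), sum(x))
  expect_error(half_adder(c(1L, 0L), c(1L, 0L, 0L)), "length")
})

test_that("output popcount is additive for every bit pattern at M = 3", {
  codes <- expand.grid(replicate(3, 0:1, simplify = FALSE))
  for (i in seq_len(nrow(codes))) {
    for (j in seq_len(nrow(codes))) {
      x1 <- as.integer(codes[i, ])
      x2 <- as.integer(codes[j, ])
      expect_equal(sum(half_adder(x1, x2)), sum(x1) + sum(x2))
    }
  }
})

test_that("popcount additivity holds for random thermometer pairs at M = 200", {
  set.seed(99)
  for (rep in 1:50) {
    a <- sample(0:200, 1)
    b <- sample(0:200, 1)
    x1 <- as.integer(seq_len(200) <= a)
    x2 <- as.integer(seq_len(200) <= b)
    expect_equal(sum(half_adder(x1, x2)), a + b)
  }
})

test_that("combine_signals decodes to the sum of the shifted inputs", {
  cfg <- encoder_config()
  enc <- function(r, th) {
    encode_signal(sample_sinusoid(polar_vector(r, th)), cfg, amplitude = r)
  }

  # identity element
  h0 <- combine_signals(enc(4, 1.2), enc(0, 0))
  w0 <- decode_values(h0)$values
  shifted <- (sample_sinusoid(polar_vector(4, 1.2))$values + 4) / 2
  expect_lte(max(abs(w0 - shifted)), 1 / cfg$k + 1e-12)

  # antiparallel vectors: sinusoids cancel, shifts add to a constant 3
  hc <- combine_signals(enc(3, 0), enc(3, pi))
  wc <- decode_values(hc)$values
  expect_lte(max(abs(wc - 3)), 1 / cfg$k + 1e-12)

  # generic pair matches the sinusoid-domain oracle
  h <- combine_signals(enc(3, 0), enc(4, pi / 2))
  w <- decode_values(h)$values
  oracle <- (sinusoid_sum(sample_sinusoid(polar_vector(3, 0)),
                          sample_sinusoid(polar_vector(4, pi / 2)))$values +
               7) / 2
  expect_lte(max(abs(w - oracle)), 1 / cfg$k + 1e-12)

  # commutativity in decoded value
  h_rev <- combine_signals(enc(4, pi / 2), enc(3, 0))
  expect_equal(decode_values(h_rev)$values, w)

  expect_error(
    combine_signals(enc(1, 0),
                    encode_signal(sample_sinusoid(polar_vector(1, 0)),
                                  encoder_config(k = 10))),
    "mismatch")
})

test_that("fold_signals sums many vectors under an enlarged ceiling", {
  n <- 20L
  cfg <- encoder_config(range_max = 10 * n, k = 5)
  sampling <- sampling_config(360)
  unit <- encode_signal(sample_sinusoid(polar_vector(1, 0), sampling), cfg,
                        amplitude = 1)

  expect_identical(fold_signals(list(unit)), unit)

  dec <- decode_signal(fold_signals(rep(list(unit), n)))
  expect_equal(dec$r, n, tolerance = n / cfg$k)
  expect_lt(angular_error(dec$theta, 0), 2 * pi / 360)

  # random fold matches the closed-form running sum
  set.seed(5)
  vs <- lapply(1:n, function(i) polar_vector(runif(1, 0, 10),
                                             runif(1, 0, 2 * pi)))
  truth <- Reduce(vector_sum, vs)
  signals <- lapply(vs, function(v)
    encode_signal(sample_sinusoid(v, sampling), cfg, amplitude = v$r))
  dec2 <- decode_signal(fold_signals(signals))
  expect_lt(abs(dec2$r - truth$r), n / cfg$k)
  expect_lt(angular_error(dec2$theta, truth$theta), 2 * pi / 360)
})

test_that("network_shape reports the layer lane counts", {
  shp <- network_shape()
  expect_equal(c(shp$n_input, shp$n_hidden, shp$n_output),
               c(720L, 360L, 360L))
  expect_equal(shp$n_input, 2L * shp$n_hidden)
  expect_equal(shp$bits_input, 720L * 200L)
})
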