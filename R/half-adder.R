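#' Half-adder activation on a pair of binary codes
#'
#' The hidden-layer (ellipsoid-body) activation. For two M-bit inputs
#' it emits a 2M-bit output with, per input position `i` (0-based
#' output offsets): even offset `2i` = OR of the two bits (the sum
#' line, "did anything arrive"), odd offset `2i + 1` = AND (the carry
#' line, "did both arrive"). In R's 1-based indexing, odd output
#' positions carry OR and even positions AND.
#'
#' For thermometer inputs with `a` and `b` ones, OR contributes
#' `max(a, b)` ones and AND contributes `min(a, b)`, so the output
#' popcount is exactly `a + b`: the layer adds the encoded values in
#' code space. This additivity is what the downstream decoder relies
#' on, and it requires AND (not XOR) on the carry line.
#'
#' @param x1,x2 `binary_code` objects, or plain 0/1 vectors of equal
#'   length.
#' @return Integer 0/1 vector of length `2 * length(x1)`.
#' @examples
#' half_adder(c(1L, 0L), c(1L, 0L)) # 1 1 0 0
#' @export
half_adder <- function(x1, x2) {
  b1 <- if (inherits(x1, "binary_code")) x1$bits else as.integer(x1)
  b2 <- if (inherits(x2, "binary_code")) x2$bits else as.integer(x2)
  if (length(b1) != length(b2)) stop("input codes differ in length")
  out <- integer(2L * length(b1))
  out[c(TRUE, FALSE)] <- as.integer(b1 | b2)
  out[c(FALSE, TRUE)] <- as.integer(b1 & b2)
  out
}

#' Combine two coded signals through the half-adder layer
#'
#' Applies [half_adder()] at each of the `n_samples` lane positions.
#' The decoded value of output sample `i` (its popcount over `k`) is
#' the sum of the two inputs' rescaled sample values, so the output is
#' the coded form of the shifted sum sinusoid.
#'
#' @param a,b `coded_signal` objects with matching sampling and encoder
#'   configurations.
#' @return A `half_adder_output`: fields `codes` (an
#'   `n_samples x 2*m_bits` 0/1 matrix, OR/AND interleaved), `sampling`,
#'   `encoder`, `shift` (the summed affine shifts `(r1 + r2) / 2`),
#'   `clip_count` (summed input diagnostics).
#' @examples
#' a <- encode_signal(sample_sinusoid(polar_vector(3, 0)))
#' b <- encode_signal(sample_sinusoid(polar_vector(4, pi / 2)))
#' h <- combine_signals(a, b)
#' decode_signal(h) # ~ (5, 0.9273)
#' @export
combine_signals <- function(a, b) {
  stopifnot(inherits(a, "coded_signal"), inherits(b, "coded_signal"))
  if (a$sampling$n_samples != b$sampling$n_samples ||
      a$encoder$m_bits != b$encoder$m_bits ||
      a$encoder$k != b$encoder$k) {
    stop("coded signals have mismatched configurations")
  }
  m <- a$encoder$m_bits
  codes <- matrix(0L, nrow = a$sampling$n_samples, ncol = 2L * m)
  codes[, seq(1L, 2L * m, by = 2L)] <- as.integer(a$codes | b$codes)
  codes[, seq(2L, 2L * m, by = 2L)] <- as.integer(a$codes & b$codes)
  structure(list(codes = codes, sampling = a$sampling, encoder = a$encoder,
                 shift = (a$amplitude + b$amplitude) / 2,
                 clip_count = a$clip_count + b$clip_count),
            class = "half_adder_output")
}

#' @export
print.half_adder_output <- function(x, ...) {
  cat(sprintf("<half_adder_output> %d samples x %d bits, shift %.4g\n",
              x$sampling$n_samples, ncol(x$codes), x$shift))
  invisible(x)
}

# Collapse a half-adder output back into a valid thermometer coded
# signal: per sample, keep the popcount and re-lay the ones as a
# prefix over m_bits lanes. Requires popcount <= m_bits, i.e. the
# running sum must fit the encoder ceiling.
rethermometerize <- function(h) {
  stopifnot(inherits(h, "half_adder_output"))
  p <- rowSums(h$codes)
  m <- h$encoder$m_bits
  clip <- h$clip_count + sum(p > m)
  p <- pmin(p, m)
  codes <- matrix(0L, nrow = h$sampling$n_samples, ncol = m)
  codes[] <- as.integer(outer(p, seq_len(m), ">="))
  structure(list(codes = codes, sampling = h$sampling, encoder = h$encoder,
                 amplitude = h$shift, clip_count = as.integer(clip)),
            class = "coded_signal")
}

#' Fold several coded signals through cascaded half-adders
#'
#' Left-fold pairwise combination for the multi-input scaling runs
#' (20 or 30 vectors per trial): each intermediate half-adder output is
#' re-thermometerized (its per-sample popcount re-laid as a prefix of
#' ones) so it is again a valid half-adder input. The encoder ceiling
#' must cover the worst-case running sum — encode the inputs with
#' `range_max >= sum of magnitudes` (see [experiment_config()], which
#' scales the ceiling to `10 * n_inputs`). Overflow beyond the ceiling
#' is clipped and counted, never silent.
#'
#' @param signals List of two or more `coded_signal` objects sharing
#'   one configuration.
#' @return A `coded_signal` whose decoded values are the running sum of
#'   the inputs' rescaled samples, within `n / k` quantization.
#' @export
fold_signals <- function(signals) {
  stopifnot(is.list(signals), length(signals) >= 1L)
  if (length(signals) == 1L) return(signals[[1L]])
  acc <- signals[[1L]]
  for (i in seq(2L, length(signals))) {
    acc <- rethermometerize(combine_signals(acc, signals[[i]]))
  }
  acc
}

#' Network shape of the circuit model
#'
#' Lane counts of the three layers for a given sampling grid: the input
#' layer carries two coded signals (`2 * n_samples` lanes), the hidden
#' (ellipsoid-body) layer and output (protocerebral-bridge) layer one
#' lane per sample. Each lane holds an M-bit code; both lane and bit
#' counts are reported. The reference grid gives 720 / 360 / 360.
#'
#' @param n_samples Sampling points per signal (default 360).
#' @param m_bits Bits per lane (default 200).
#' @return A `network_shape` with fields `n_input`, `n_hidden`,
#'   `n_output` (lane counts) and `bits_input`, `bits_hidden`,
#'   `bits_output`.
#' @examples
#' network_shape()
#' @export
network_shape <- function(n_samples = 360L, m_bits = 200L) {
  n_samples <- as.integer(n_samples)
  m_bits <- as.integer(m_bits)
  stopifnot(n_samples >= 1L, m_bits >= 1L)
  structure(list(n_input = 2L * n_samples, n_hidden = n_samples,
                 n_output = n_samples,
                 bits_input = 2L * n_samples * m_bits,
                 bits_hidden = n_samples * 2L * m_bits,
                 bits_output = n_samples * 2L * m_bits),
            class = "network_shape")
}

#' @export
print.network_shape <- function(x, ...) {
  cat(sprintf("<network_shape> input %d / hidden %d / output %d lanes\n",
              x$n_input, x$n_hidden, x$n_output))
  invisible(x)
}
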