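# Round half away from zero. base::round() rounds half to even, which
# would flip popcounts on exact .5 grid points of k*x.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Range-number (thermometer) encoder configuration
#'
#' The range-number encoder maps a real value `x` in `[0, range_max]` to
#' an `m_bits`-long binary code whose first `round(k * x)` bits are 1
#' and the rest 0 (a thermometer / unary population code). `m_bits =
#' k * range_max` must be integral. The reference configuration is
#' `range_max = 10`, `k = 20`, giving a 200-bit code with resolution
#' `1 / k = 0.05`.
#'
#' @param range_max Positive input ceiling of the encoder.
#' @param k Positive integer scaling factor (bits per unit value).
#' @return An `encoder_config` with fields `range_max`, `k`, `m_bits`.
#' @examples
#' encoder_config()$m_bits # 200
#' @export
encoder_config <- function(range_max = 10, k = 20L) {
  stopifnot(is.numeric(range_max), length(range_max) == 1L,
            is.finite(range_max), range_max > 0,
            is.numeric(k), length(k) == 1L, is.finite(k), k >= 1)
  k <- as.integer(k)
  m <- k * range_max
  if (abs(m - round(m)) > 1e-9) {
    stop("k * range_max must be an integer code length")
  }
  structure(list(range_max = as.numeric(range_max), k = k,
                 m_bits = as.integer(round(m))),
            class = "encoder_config")
}

#' Encode a value as a thermometer code
#'
#' Bit `i` is 1 for `i <= round(k * x)` (round half away from zero),
#' else 0, so the popcount is `round(k * x)`. Values outside
#' `[0, range_max]` by more than a small tolerance are an error here;
#' signal-level encoding clips and counts instead (see
#' [encode_signal()]).
#'
#' @param x Value in `[0, range_max]`.
#' @param cfg An [encoder_config()].
#' @return A `binary_code`: fields `bits` (integer 0/1 vector) and
#'   `config`.
#' @examples
#' sum(rn_encode(2.5)$bits) # 50
#' @export
rn_encode <- function(x, cfg = encoder_config()) {
  stopifnot(inherits(cfg, "encoder_config"),
            is.numeric(x), length(x) == 1L)
  if (!is.finite(x)) stop("'x' must be finite")
  tol <- 1e-9
  if (x < -tol || x > cfg$range_max + tol) {
    stop(sprintf("'x' = %g outside encoder range [0, %g]", x, cfg$range_max))
  }
  p <- .popcount_for(x, cfg)
  structure(list(bits = as.integer(seq_len(cfg$m_bits) <= p), config = cfg),
            class = "binary_code")
}

# clipped popcount(s) for value(s) on the encoder grid
.popcount_for <- function(x, cfg) {
  pmin(pmax(round_half_away(cfg$k * x), 0), cfg$m_bits)
}

#' Decode a binary code to its value
#'
#' Returns `popcount / k`. For encoder output this inverts
#' [rn_encode()] to within the quantization bound `1 / (2k)`. Defined
#' for any 0/1 code (thermometer or not), which is what the half-adder
#' layer produces.
#'
#' @param code A `binary_code`, or a plain 0/1 vector with `cfg` given.
#' @param cfg Encoder configuration when `code` is a plain vector.
#' @return The decoded real value.
#' @export
rn_decode <- function(code, cfg = NULL) {
  if (inherits(code, "binary_code")) {
    cfg <- code$config
    bits <- code$bits
  } else {
    stopifnot(inherits(cfg, "encoder_config"))
    bits <- code
  }
  sum(bits) / cfg$k
}

#' Encode a sampled sinusoid as a coded signal
#'
#' The sinusoid takes values in `[-r, r]` while the encoder domain is
#' `[0, range_max]`, so each sample is affine-rescaled to
#' `v(phi) = (f(phi) + r) / 2`, which lies in `[0, r]`. The shift is
#' transparent downstream: the decoder uses only `max - min` and the
#' peak position, both invariant to it, and under half-adder summation
#' the combined profile's `max - min` equals the sum magnitude exactly.
#'
#' Samples pushed outside `[0, range_max]` (possible once noise is
#' added) are clipped and counted; the count travels with the signal as
#' the `clip_count` field.
#'
#' @param s A `sampled_sinusoid`.
#' @param cfg An [encoder_config()]; the signal amplitude `r` must not
#'   exceed `cfg$range_max`.
#' @param amplitude The shift `r` applied before encoding; defaults to
#'   `max(abs(values))`, which keeps the rescaled samples non-negative
#'   for any clean sinusoid. Pass the nominal magnitude explicitly for
#'   noisy signals so clipping is counted against the true range.
#' @return A `coded_signal`: fields `codes` (an
#'   `n_samples x m_bits` 0/1 integer matrix, one thermometer code per
#'   row), `sampling`, `encoder`, `amplitude`, `clip_count`.
#' @examples
#' cs <- encode_signal(sample_sinusoid(polar_vector(10, 0)))
#' sum(cs$codes[1, ])   # 200: phi = 0 is the peak of (f + r)/2 = 10
#' sum(cs$codes[181, ]) # 0:   phi = 180 degrees is the trough
#' @export
encode_signal <- function(s, cfg = encoder_config(), amplitude = NULL) {
  stopifnot(inherits(s, "sampled_sinusoid"), inherits(cfg, "encoder_config"))
  r <- if (is.null(amplitude)) max(abs(s$values)) else amplitude
  if (r > cfg$range_max + 1e-9) {
    stop(sprintf("signal amplitude %g exceeds encoder range_max %g", r,
                 cfg$range_max))
  }
  v <- (s$values + r) / 2
  clip <- sum(v < -1e-9 | v > cfg$range_max + 1e-9)
  v <- pmin(pmax(v, 0), cfg$range_max)
  p <- .popcount_for(v, cfg)
  codes <- matrix(0L, nrow = s$config$n_samples, ncol = cfg$m_bits)
  codes[] <- as.integer(outer(p, seq_len(cfg$m_bits), ">="))
  structure(list(codes = codes, sampling = s$config, encoder = cfg,
                 amplitude = r, clip_count = as.integer(clip)),
            class = "coded_signal")
}

#' @export
print.coded_signal <- function(x, ...) {
  cat(sprintf(
    "<coded_signal> %d samples x %d bits (k = %d), amplitude %.4g, %d clipped\n",
    x$sampling$n_samples, x$encoder$m_bits, x$encoder$k, x$amplitude,
    x$clip_count))
  invisible(x)
}
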