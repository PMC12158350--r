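#' Read the real-valued activity profile off a half-adder output
#'
#' The output-layer (protocerebral-bridge) view of the hidden layer:
#' per sample, value = popcount / k. For a combination of two encoded
#' signals this reconstructs the shifted sum profile
#' `w(phi) = (f1 + f2 + r1 + r2) / 2` to within `1/k` per sample.
#'
#' @param h A `half_adder_output` (or a `coded_signal`, e.g. from
#'   [fold_signals()]).
#' @return A `sampled_sinusoid` of the decoded values.
#' @export
decode_values <- function(h) {
  stopifnot(inherits(h, "half_adder_output") || inherits(h, "coded_signal"))
  new_sampled_sinusoid(rowSums(h$codes) / h$encoder$k, h$sampling)
}

#' Locate the activity peak of a sampled profile
#'
#' Two modes:
#' * `"argmax"` — the literal bump read-out: the sample with the
#'   highest value (for coded signals, the lane with the most ones).
#'   Ties — a flat quantized plateau around the true peak — are broken
#'   by the circular mean of the tied indices, which recovers the
#'   plateau centre.
#' * `"refined"` (default) — the phase of the first circular harmonic
#'   of the mean-removed profile, `Arg(sum(w_i * exp(1i * phi_i)))`.
#'   For a pure sampled cosine this is exact, giving sub-sample
#'   accuracy; it is also the more noise-robust estimator since it
#'   pools all samples.
#'
#' @param s A `sampled_sinusoid`.
#' @param mode `"refined"` or `"argmax"`.
#' @return List with `peak_index` (0-based sample index of the located
#'   maximum, in `[0, n_samples)`) and `theta_offset` (the peak angle
#'   in radians; equal to `peak_index * delta_theta` in argmax mode,
#'   the harmonic phase in refined mode).
#' @examples
#' locate_peak(sample_sinusoid(polar_vector(2, pi / 2)))$theta_offset
#' @export
locate_peak <- function(s, mode = c("refined", "argmax")) {
  stopifnot(inherits(s, "sampled_sinusoid"))
  mode <- match.arg(mode)
  w <- s$values
  if (max(w) - min(w) <= 0) stop("constant signal has no peak")
  phi <- s$config$phi
  if (mode == "refined") {
    z <- sum((w - mean(w)) * exp(1i * phi))
    theta <- normalize_angle(Arg(z))
    peak_index <- as.integer(round(theta / s$config$delta_theta)) %%
      s$config$n_samples
  } else {
    idx <- which(w >= max(w) - 1e-12)  # quantized plateau
    zz <- sum(exp(1i * phi[idx]))
    theta <- if (Mod(zz) < 1e-9) phi[idx[1L]] else normalize_angle(Arg(zz))
    peak_index <- as.integer(round(theta / s$config$delta_theta)) %%
      s$config$n_samples
  }
  list(peak_index = peak_index, theta_offset = theta)
}

#' Decode a half-adder output to a polar vector
#'
#' The full protocerebral-bridge read-out. The magnitude is
#' `max(w) - min(w)` of the decoded profile: the affine shift applied
#' at encoding contributes equally to max and min, and the underlying
#' sum sinusoid `(f1 + f2) / 2` has amplitude `r_sum / 2`, so the
#' difference is `r_sum` itself. The direction is the peak angle from
#' [locate_peak()]. A constant (degenerate) profile decodes to the
#' zero vector.
#'
#' @param h A `half_adder_output` or folded `coded_signal`.
#' @param peak_mode Passed to [locate_peak()].
#' @return A `decoded_vector`: fields `r`, `theta`, `theta_offset`,
#'   `peak_index`, `clip_count`, plus `harmonic_r` (first-harmonic
#'   amplitude `2|z|/N`, a diagnostic only — the reported `r` always
#'   comes from max - min).
#' @examples
#' a <- encode_signal(sample_sinusoid(polar_vector(3, 0)))
#' b <- encode_signal(sample_sinusoid(polar_vector(4, pi / 2)))
#' decode_signal(combine_signals(a, b))
#' @export
decode_signal <- function(h, peak_mode = c("refined", "argmax")) {
  peak_mode <- match.arg(peak_mode)
  s <- decode_values(h)
  w <- s$values
  r <- max(w) - min(w)
  z <- sum((w - mean(w)) * exp(1i * s$config$phi))
  harmonic_r <- 2 * Mod(z) / s$config$n_samples
  if (r == 0) {
    out <- list(r = 0, theta = 0, theta_offset = 0, peak_index = 0L,
                clip_count = h$clip_count, harmonic_r = harmonic_r)
  } else {
    pk <- locate_peak(s, peak_mode)
    out <- list(r = r, theta = pk$theta_offset,
                theta_offset = pk$theta_offset, peak_index = pk$peak_index,
                clip_count = h$clip_count, harmonic_r = harmonic_r)
  }
  structure(out, class = "decoded_vector")
}

#' @export
print.decoded_vector <- function(x, ...) {
  cat(sprintf(
    "<decoded_vector> r = %.6g, theta = %.6g rad (%.4g deg), peak %d%s\n",
    x$r, x$theta, x$theta * 180 / pi, x$peak_index,
    if (x$clip_count > 0) sprintf(", %d clipped", x$clip_count) else ""))
  invisible(x)
}
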