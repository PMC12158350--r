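#' Sampling grid for the phasor representation
#'
#' The circuit represents a vector `(r, theta)` as the sinusoid
#' `f(phi) = r * sin(phi - theta + pi/2) = r * cos(phi - theta)`,
#' sampled at `n_samples` equally spaced angles `phi_i = 2*pi*i / N`,
#' `i = 0, ..., N-1`. The default `N = 360` (1 degree spacing) matches
#' the modelled ellipsoid-body lane count.
#'
#' Even `n_samples` is required by default so that the on-grid minimum
#' equals minus the maximum exactly; odd counts are allowed with
#' `allow_odd = TRUE` and carry an amplitude bias of at most
#' `r * (1 - cos(delta_theta / 2))`.
#'
#' @param n_samples Number of sampling points, at least 4.
#' @param allow_odd Permit an odd sample count (see Details).
#' @return A `sampling_config` with fields `n_samples`, `delta_theta`
#'   (`= 2*pi / n_samples`) and `phi` (the sampling angles).
#' @examples
#' sampling_config(360)$delta_theta # pi/180
#' @export
sampling_config <- function(n_samples = 360L, allow_odd = FALSE) {
  n_samples <- as.integer(n_samples)
  stopifnot(length(n_samples) == 1L, !is.na(n_samples))
  if (n_samples < 4L) stop("'n_samples' must be at least 4")
  if (n_samples %% 2L == 1L && !allow_odd) {
    stop("'n_samples' must be even (set allow_odd = TRUE to override)")
  }
  structure(list(n_samples = n_samples,
                 delta_theta = 2 * pi / n_samples,
                 phi = 2 * pi * (seq_len(n_samples) - 1L) / n_samples),
            class = "sampling_config")
}

new_sampled_sinusoid <- function(values, config) {
  stopifnot(length(values) == config$n_samples)
  structure(list(values = as.numeric(values), config = config),
            class = "sampled_sinusoid")
}

#' Sample the sinusoid (phasor) representation of a vector
#'
#' Evaluates `f(phi_i) = r * cos(phi_i - theta)` on the sampling grid.
#' The peak value `r` occurs at `phi = theta` (to sample resolution), so
#' the phase carries the direction and the amplitude the magnitude.
#'
#' @param v A [polar_vector()].
#' @param cfg A [sampling_config()].
#' @return A `sampled_sinusoid` (fields `values`, `config`).
#' @examples
#' s <- sample_sinusoid(polar_vector(2, pi / 2), sampling_config(360))
#' which.max(s$values) # sample 91, i.e. phi = 90 degrees
#' @export
sample_sinusoid <- function(v, cfg = sampling_config()) {
  stopifnot(inherits(v, "polar_vector"), inherits(cfg, "sampling_config"))
  new_sampled_sinusoid(v$r * cos(cfg$phi - v$theta), cfg)
}

#' Pointwise sum of two sampled sinusoids
#'
#' The phasor property: the sample-wise sum of the sinusoids of two
#' vectors is the sinusoid of their vector sum. Configurations must
#' match.
#'
#' @param a,b `sampled_sinusoid` objects on the same grid.
#' @return A `sampled_sinusoid`.
#' @export
sinusoid_sum <- function(a, b) {
  stopifnot(inherits(a, "sampled_sinusoid"), inherits(b, "sampled_sinusoid"))
  if (a$config$n_samples != b$config$n_samples) {
    stop("sampling configurations differ")
  }
  new_sampled_sinusoid(a$values + b$values, a$config)
}

#' Recover a vector from a sampled sinusoid
#'
#' Inverse of [sample_sinusoid()] up to quantization: the amplitude is
#' `(max - min) / 2` and the phase is taken at the located peak (see
#' [locate_peak()] for the two peak modes). A constant signal decodes to
#' the zero vector.
#'
#' @param s A `sampled_sinusoid`.
#' @param peak_mode `"refined"` (first circular harmonic, sub-sample
#'   accuracy; the default) or `"argmax"` (integer-sample peak with a
#'   circular-mean tie-break).
#' @return A [polar_vector()].
#' @examples
#' fit_sinusoid(sample_sinusoid(polar_vector(2, pi / 2)))
#' @export
fit_sinusoid <- function(s, peak_mode = c("refined", "argmax")) {
  stopifnot(inherits(s, "sampled_sinusoid"))
  peak_mode <- match.arg(peak_mode)
  r <- (max(s$values) - min(s$values)) / 2
  if (r == 0) return(polar_vector(0, 0))
  pk <- locate_peak(s, peak_mode)
  polar_vector(r, pk$theta_offset)
}
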