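#' Rotate an egocentric travel vector into the allocentric frame
#'
#' The allocentric travelling direction is the egocentric travelling
#' direction rotated by the heading: `T_allo = T_ego + H` (mod 2*pi).
#' The magnitude is unchanged.
#'
#' Internally all angles are standard counter-clockwise radians; the
#' clockwise-positive degree convention used in head-centred diagrams
#' is converted at the CLI / I/O boundary only.
#'
#' @param v_ego [polar_vector()] in the egocentric frame (angle
#'   relative to the head axis, head = 0).
#' @param heading Allocentric heading angle H in radians.
#' @return The allocentric [polar_vector()].
#' @examples
#' ego_to_allo(polar_vector(1, 30 * pi / 180), 45 * pi / 180) # 75 deg
#' @export
ego_to_allo <- function(v_ego, heading) {
  stopifnot(inherits(v_ego, "polar_vector"))
  polar_vector(v_ego$r, normalize_angle(v_ego$theta + heading))
}

#' Four reference axes of the projection path
#'
#' The axes at +45, -45, +135 and -135 degrees relative to the head
#' direction, in radians.
#'
#' @return Numeric vector of the four axis angles.
#' @export
reference_axes <- function() {
  c(pi / 4, -pi / 4, 3 * pi / 4, -3 * pi / 4)
}

#' Ego-to-allo transform via four-axis projection
#'
#' The biological route: the egocentric vector is projected onto the
#' four reference axes (`components[j] = r * cos(t_ego - axes[j])`),
#' each axis is rotated by the heading H, the component-weighted unit
#' vectors are recombined, and the result is halved. The halving is
#' needed because the four axes form two orthogonal pairs, so the raw
#' recombination doubles the magnitude:
#' `sum_j cos(T - a_j) * unit(a_j + H) = 2 r * unit(T + H)` (the
#' second-harmonic terms `sum_j exp(2i a_j)` cancel over the axis set).
#' After renormalization the result equals [ego_to_allo()] exactly in
#' the continuous domain.
#'
#' @inheritParams ego_to_allo
#' @param normalize Apply the factor-1/2 renormalization (default
#'   `TRUE`; `FALSE` exposes the raw doubled recombination for
#'   inspection).
#' @return The allocentric [polar_vector()].
#' @examples
#' four_axis_transform(polar_vector(4, 10 * pi / 180), 100 * pi / 180)
#' @export
four_axis_transform <- function(v_ego, heading, normalize = TRUE) {
  stopifnot(inherits(v_ego, "polar_vector"))
  axes <- reference_axes()
  comp <- v_ego$r * cos(v_ego$theta - axes)
  rotated <- axes + heading
  x <- sum(comp * cos(rotated))
  y <- sum(comp * sin(rotated))
  if (normalize) {
    x <- x / 2
    y <- y / 2
  }
  to_polar(x, y)
}

#' Coded vector addition through the full circuit
#'
#' Runs the complete pipeline — sample each vector as a sinusoid,
#' thermometer-encode, combine through the half-adder layer, decode at
#' the output layer — and returns the decoded vector sum. This is the
#' operation the evaluation harness exercises: frame transformation by
#' vector addition in code space.
#'
#' @param v1,v2 [polar_vector()] operands; their magnitudes must each
#'   fit within `encoder$range_max`.
#' @param sampling A [sampling_config()].
#' @param encoder An [encoder_config()].
#' @param peak_mode Peak-location mode, see [locate_peak()].
#' @return A `decoded_vector` (see [decode_signal()]).
#' @examples
#' coded_vector_sum(polar_vector(3, 0), polar_vector(4, pi / 2))
#' @export
coded_vector_sum <- function(v1, v2, sampling = sampling_config(),
                             encoder = encoder_config(),
                             peak_mode = c("refined", "argmax")) {
  stopifnot(inherits(v1, "polar_vector"), inherits(v2, "polar_vector"))
  peak_mode <- match.arg(peak_mode)
  a <- encode_signal(sample_sinusoid(v1, sampling), encoder, amplitude = v1$r)
  b <- encode_signal(sample_sinusoid(v2, sampling), encoder, amplitude = v2$r)
  decode_signal(combine_signals(a, b), peak_mode)
}

#' Ego-to-allo transformation through the coded circuit
#'
#' The navigation use case of [coded_vector_sum()]: the egocentric
#' travel vector and a heading vector are pushed through the coded
#' pipeline and their decoded sum is returned. With the heading
#' supplied as a unit-magnitude rotation reference this realises the
#' frame shift in code space; with two generic vectors it is plain
#' coded addition, which is how the error statistics are measured.
#'
#' @param v_ego Egocentric travel [polar_vector()].
#' @param heading_vector A [polar_vector()] to be summed with `v_ego`
#'   in code space, or a bare heading angle in radians, in which case
#'   the frame rotation `T_allo = T_ego + H` is applied to `v_ego`
#'   first and the rotated vector is passed through the circuit with a
#'   zero companion (so the read-out still carries circuit
#'   quantization).
#' @inheritParams coded_vector_sum
#' @return A `decoded_vector`.
#' @export
coded_ego_to_allo <- function(v_ego, heading_vector,
                              sampling = sampling_config(),
                              encoder = encoder_config(),
                              peak_mode = c("refined", "argmax")) {
  if (!inherits(heading_vector, "polar_vector")) {
    stopifnot(is.numeric(heading_vector), length(heading_vector) == 1L,
              is.finite(heading_vector))
    v_ego <- ego_to_allo(v_ego, heading_vector)
    heading_vector <- polar_vector(0, 0)
  }
  coded_vector_sum(v_ego, heading_vector, sampling, encoder, peak_mode)
}
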