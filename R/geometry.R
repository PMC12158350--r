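#' Construct a polar 2D vector
#'
#' A vector on the plane given by magnitude and direction. Angles are
#' radians, normalized to `[0, 2*pi)`; magnitudes must be non-negative.
#' This is the exact, closed-form representation against which the coded
#' circuit pipeline is validated.
#'
#' @param r Non-negative magnitude (the experiments draw r from `[0, 10]`).
#' @param theta Angle in radians; any finite value, stored normalized.
#' @return An object of class `polar_vector` with fields `r` and `theta`.
#' @examples
#' polar_vector(5, atan2(4, 3))
#' @export
polar_vector <- function(r, theta) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (r < 0) stop("magnitude 'r' must be non-negative")
  structure(list(r = as.numeric(r), theta = normalize_angle(theta)),
            class = "polar_vector")
}

#' @export
print.polar_vector <- function(x, ...) {
  cat(sprintf("<polar_vector> r = %.6g, theta = %.6g rad (%.4g deg)\n",
              x$r, x$theta, x$theta * 180 / pi))
  invisible(x)
}

#' Normalize an angle into [0, 2*pi)
#'
#' Angles below zero have full turns added; angles at or above `2*pi`
#' have full turns removed. The result is congruent to the input mod
#' `2*pi`.
#'
#' @param a Angle(s) in radians; must be finite.
#' @return Angle(s) in `[0, 2*pi)`.
#' @examples
#' normalize_angle(-pi / 2) # 3*pi/2
#' @export
normalize_angle <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("angles must be finite numerics")
  }
  a %% (2 * pi)
}

#' Convert polar to Cartesian coordinates
#'
#' @param v A [polar_vector()].
#' @return A list with components `x` and `y` (class `cartesian_vector`).
#' @examples
#' to_cartesian(polar_vector(5, atan2(4, 3))) # x = 3, y = 4
#' @export
to_cartesian <- function(v) {
  stopifnot(inherits(v, "polar_vector"))
  structure(list(x = v$r * cos(v$theta), y = v$r * sin(v$theta)),
            class = "cartesian_vector")
}

#' Convert Cartesian to polar coordinates
#'
#' The zero vector maps to `(r = 0, theta = 0)` by convention, making
#' downstream comparisons deterministic.
#'
#' @param x Either a `cartesian_vector` or the x component.
#' @param y The y component when `x` is numeric.
#' @return A [polar_vector()].
#' @export
to_polar <- function(x, y = NULL) {
  if (inherits(x, "cartesian_vector")) {
    y <- x$y
    x <- x$x
  }
  stopifnot(is.numeric(x), is.numeric(y))
  r <- sqrt(x^2 + y^2)
  theta <- if (r == 0) 0 else normalize_angle(atan2(y, x))
  polar_vector(r, theta)
}

#' Exact vector sum in polar form
#'
#' Adds two plane vectors through their Cartesian components and returns
#' the polar result. Serves as the closed-form oracle for the coded
#' pipeline: `r_sum = sqrt(r1^2 + 2 r1 r2 cos(theta1 - theta2) + r2^2)`
#' and `theta_sum = atan2` of the summed components, normalized.
#'
#' @param v1,v2 [polar_vector()] operands.
#' @return A [polar_vector()]; a zero-magnitude sum reports `theta = 0`.
#' @examples
#' vector_sum(polar_vector(3, 0), polar_vector(4, pi / 2))
#' @export
vector_sum <- function(v1, v2) {
  stopifnot(inherits(v1, "polar_vector"), inherits(v2, "polar_vector"))
  x <- v1$r * cos(v1$theta) + v2$r * cos(v2$theta)
  y <- v1$r * sin(v1$theta) + v2$r * sin(v2$theta)
  to_polar(x, y)
}

#' Circular (wrapped) angular distance
#'
#' Distance between two directions on the circle:
#' `min(|d|, 2*pi - |d|)` with `d` the normalized difference. Always in
#' `[0, pi]`. Set `wrap = FALSE` for the plain absolute difference of
#' normalized angles (can reach just under `2*pi`; useful only to expose
#' the boundary artifact at 0/360 degrees).
#'
#' @param a,b Angles in radians.
#' @param wrap Wrap circularly (default `TRUE`).
#' @return Non-negative distance in radians.
#' @examples
#' angular_error(0.01, 2 * pi - 0.01) # 0.02
#' @export
angular_error <- function(a, b, wrap = TRUE) {
  d <- abs(normalize_angle(a) - normalize_angle(b))
  if (wrap) pmin(d, 2 * pi - d) else d
}
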