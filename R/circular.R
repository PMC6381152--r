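#' Wrap angles to the signed circular range \[-180, 180)
#'
#' Canonical representation of a signed circular difference in degrees. The
#' lower bound is closed: 180 maps to -180, so every angle has a single
#' representative.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector in \[-180, 180), congruent to `angle` mod 360.
#' @examples
#' wrap_signed(c(0, 350, 540))
#' @export
wrap_signed <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    abort("`angle` must be a finite numeric vector.")
  }
  ((angle + 180) %% 360) - 180
}

#' Wrap angles to the canonical circle \[0, 360)
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector in \[0, 360).
#' @export
wrap_circle <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    abort("`angle` must be a finite numeric vector.")
  }
  angle %% 360
}

#' Signed circular distance between two angles
#'
#' Computes `a - b` on the circle, wrapped to \[-180, 180). With the package's
#' clockwise-negative convention, a response 90 degrees clockwise of the target
#' has `circ_dist(response, target) == -90`.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed differences in degrees, in \[-180, 180).
#' @examples
#' circ_dist(10, 350)  # 20
#' circ_dist(0, 90)    # -90
#' @export
circ_dist <- function(a, b) {
  wrap_signed(a - b)
}

#' Absolute circular error between target and response
#'
#' The absolute difference between the target location and the reproduced
#' location on the circle, in \[0, 180\] degrees; larger values mean less
#' accurate responses.
#'
#' @param target,response Numeric vectors of angles in degrees (recycled).
#' @return Absolute errors in degrees, in \[0, 180\].
#' @examples
#' abs_error(350, 10)  # 20
#' @export
abs_error <- function(target, response) {
  abs(circ_dist(response, target))
}

#' Circular mean of a set of angles
#'
#' Direction of the vector resultant, in \[0, 360). Undefined when the
#' resultant length is (numerically) zero, e.g. for an antipodal pair.
#'
#' @param angles Non-empty numeric vector of angles in degrees.
#' @param tol Minimum mean resultant length below which the mean is declared
#'   undefined.
#' @return The circular mean in degrees, in \[0, 360).
#' @examples
#' circ_mean(c(10, 350))  # 0
#' @export
circ_mean <- function(angles, tol = 1e-8) {
  if (length(angles) == 0) abort("`angles` must be non-empty.")
  if (!is.numeric(angles) || any(!is.finite(angles))) {
    abort("`angles` must be finite.")
  }
  rad <- angles * pi / 180
  s <- mean(sin(rad))
  c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < tol) {
    abort("Circular mean undefined: resultant length is (numerically) zero.")
  }
  wrap_circle(atan2(s, c) * 180 / pi)
}

#' Von Mises density on the circle, per degree
#'
#' Density of the von Mises (circular normal) distribution with mean direction
#' `mu` and concentration `kappa`, expressed per degree so that it integrates
#' to 1 over any 360-degree interval. At `kappa = 0` it reduces to the uniform
#' density 1/360.
#'
#' @param x Numeric vector of angles in degrees.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration parameter, `0 <= kappa < 700` (the upper guard
#'   avoids Bessel overflow).
#' @return Densities per degree.
#' @examples
#' dvonmises(0, 0, 0)   # 1/360
#' dvonmises(0, 0, 15)
#' @export
dvonmises <- function(x, mu, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa)) {
    abort("`kappa` must be a single finite number.")
  }
  if (kappa < 0) abort("`kappa` must be non-negative.")
  if (kappa >= 700) abort("`kappa` exceeds the overflow guard (700).")
  err <- wrap_signed(x - mu) * pi / 180
  # log I0 via the exponentially scaled Bessel function; stable for large kappa
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  exp(kappa * cos(err) - log(2 * pi) - log_i0) * pi / 180
}
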