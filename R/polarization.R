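#' Jones matrix of a waveplate
#'
#' Retarder with its fast axis at `theta` degrees from horizontal and
#' retardance `delta` radians (pi for a half-wave plate, pi/2 for a
#' quarter-wave plate), up to a global phase.
#'
#' @param theta Fast-axis angle in degrees (taken mod 360).
#' @param delta Retardance in radians.
#' @return Complex 2x2 matrix acting on (Ex, Ey) Jones vectors.
#' @export
jones_waveplate <- function(theta, delta) {
  th <- (theta %% 360) * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  D <- diag(c(exp(-1i * delta / 2), exp(1i * delta / 2)))
  R %*% D %*% t(R) * exp(0i)
}

#' Excitation polarization state set by the waveplate pair
#'
#' The excitation beam is horizontally polarized, passes the quarter-wave
#' plate first and the half-wave plate second (the order on the excitation
#' path), and the emerging fully polarized state is reduced to Stokes-like
#' descriptors: the linear fraction, the linear orientation, and the
#' circular fraction (with handedness).
#'
#' @param hwp_angle Half-wave plate fast-axis angle (degrees), or `NULL`
#'   if the element is removed.
#' @param qwp_angle Quarter-wave plate fast-axis angle (degrees), or
#'   `NULL` if removed.
#' @return An object of class `polarization_state` with fields
#'   `linear_fraction`, `orientation` (degrees), `circular_fraction`,
#'   `handedness` (+1/-1/0) and the complex `jones` vector.
#' @examples
#' excitation_state(0, 0)       # horizontal linear
#' excitation_state(NULL, 45)   # pure circular
#' excitation_state(160, 80)    # the elliptical working point
#' @export
excitation_state <- function(hwp_angle, qwp_angle) {
  stopifnot(is.null(hwp_angle) || is.finite(hwp_angle),
            is.null(qwp_angle) || is.finite(qwp_angle))
  E <- c(1 + 0i, 0i)
  if (!is.null(qwp_angle)) E <- jones_waveplate(qwp_angle, pi / 2) %*% E
  if (!is.null(hwp_angle)) E <- jones_waveplate(hwp_angle, pi) %*% E
  E <- as.vector(E)
  s0 <- sum(Mod(E)^2)
  s1 <- Mod(E[1])^2 - Mod(E[2])^2
  s2 <- 2 * Re(E[1] * Conj(E[2]))
  s3 <- -2 * Im(E[1] * Conj(E[2]))
  structure(list(
    linear_fraction = sqrt(s1^2 + s2^2) / s0,
    orientation = 0.5 * atan2(s2, s1) * 180 / pi,
    circular_fraction = abs(s3) / s0,
    handedness = sign(round(s3 / s0, 12)),
    jones = E
  ), class = "polarization_state")
}

#' @export
print.polarization_state <- function(x, ...) {
  cat("<polarization_state>\n")
  cat(sprintf("  linear fraction %.4f at %.2f deg; circular fraction %.4f (%s)\n",
              x$linear_fraction, x$orientation, x$circular_fraction,
              if (x$handedness > 0) "left" else if (x$handedness < 0) "right" else "-"))
  invisible(x)
}

# Effective anisotropy multiplier of an excitation state: 1 for pure linear
# excitation, -1/2 for pure circular (one-photon photoselection), and the
# linear-fraction mixture in between.
anisotropy_multiplier <- function(state) {
  p <- state$linear_fraction
  p * 1 + (1 - p) * (-0.5)
}

#' Steady-state detection weight of a species behind an analyzer
#'
#' Fraction of a species' emission passed to the detector for a given
#' excitation polarization state, from photoselection theory: with
#' effective steady-state anisotropy r (scaled by the excitation state's
#' anisotropy multiplier: 1 for linear, -1/2 for circular excitation),
#' the parallel analyzer passes \eqn{(1 + 2r)/3} and the perpendicular
#' analyzer \eqn{(1 - r)/3} of the total emission, so that
#' `w_par + 2 * w_perp = 1`. Analyzer `"none"` passes everything.
#'
#' @param species A [fluor_species].
#' @param state A `polarization_state` from [excitation_state()].
#' @param analyzer `"parallel"`, `"perpendicular"` or `"none"`.
#' @param r_max Admissible anisotropy bound (rejects nonphysical r).
#' @return Scalar weight in `[0, 1]`.
#' @export
detection_weight <- function(species, state,
                             analyzer = c("parallel", "perpendicular", "none"),
                             r_max = 0.4) {
  analyzer <- match.arg(analyzer)
  if (analyzer == "none") return(1)
  r <- steady_state_anisotropy(species)
  if (r < -0.5 || r > r_max)
    stop(sprintf("steady-state anisotropy %g outside [-0.5, %g]", r, r_max))
  r_eff <- anisotropy_multiplier(state) * r
  if (analyzer == "parallel") (1 + 2 * r_eff) / 3 else (1 - r_eff) / 3
}
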