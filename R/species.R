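#' Define a fluorophore species
#'
#' A species bundles everything the forward model needs to emit photons:
#' a multi-exponential excited-state decay, a Gaussian emission spectrum
#' (single mode; only the peak is ever decoded downstream), and rotational
#' anisotropy parameters for polarization-resolved detection.
#'
#' @param name Character label.
#' @param lifetimes Numeric vector of decay times (ns), all `> 0`.
#' @param amplitudes Pre-exponential weights, same length as `lifetimes`,
#'   non-negative with positive sum.
#' @param emission_peak Emission spectral peak (nm).
#' @param emission_width Gaussian sigma of the emission spectrum (nm);
#'   `0` means a spectrally pure (delta) emitter.
#' @param r0 Initial (fundamental) anisotropy, dimensionless.
#' @param r_inf Residual anisotropy at long times (hindered rotation).
#' @param theta_rot Rotational correlation time (ns).
#' @param r_max Upper physical bound on anisotropy used for validation
#'   (0.4 for one-photon photoselection; up to 0.57 under two-photon
#'   excitation).
#'
#' @return An object of class `fluor_species`.
#' @examples
#' antho <- fluor_species("anthocyanin-like", lifetimes = c(0.6, 1.8),
#'                        amplitudes = c(2, 1), emission_peak = 640,
#'                        emission_width = 12, r0 = 0.35, theta_rot = 2)
#' @export
fluor_species <- function(name, lifetimes, amplitudes, emission_peak,
                          emission_width = 0, r0 = 0.4, r_inf = 0,
                          theta_rot = 1, r_max = 0.4) {
  stopifnot(is.character(name), length(name) == 1L)
  lifetimes <- as.numeric(lifetimes)
  amplitudes <- as.numeric(amplitudes)
  if (length(lifetimes) < 1L || length(lifetimes) != length(amplitudes))
    stop("'lifetimes' and 'amplitudes' must have equal length >= 1")
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    stop("all lifetimes must be finite and > 0")
  if (any(amplitudes < 0) || sum(amplitudes) <= 0)
    stop("amplitudes must be non-negative with positive sum")
  if (!is.finite(emission_peak) || emission_width < 0)
    stop("emission_peak must be finite and emission_width >= 0")
  if (!(r_inf >= -0.5 && r_inf <= r0 && r0 <= r_max))
    stop(sprintf("anisotropy bounds violated: need -0.5 <= r_inf <= r0 <= %g", r_max))
  if (theta_rot <= 0) stop("theta_rot must be > 0")
  structure(list(
    name = name, lifetimes = lifetimes, amplitudes = amplitudes,
    emission_peak = emission_peak, emission_width = emission_width,
    r0 = r0, r_inf = r_inf, theta_rot = theta_rot, r_max = r_max
  ), class = "fluor_species")
}

#' @export
print.fluor_species <- function(x, ...) {
  cat("<fluor_species>", x$name, "\n")
  cat("  lifetimes (ns):", paste(signif(x$lifetimes, 4), collapse = ", "),
      " amplitudes:", paste(signif(x$amplitudes, 4), collapse = ", "), "\n")
  cat(sprintf("  emission: %g nm (sigma %g nm)\n", x$emission_peak, x$emission_width))
  cat(sprintf("  anisotropy: r0 %g, r_inf %g, theta %g ns\n",
              x$r0, x$r_inf, x$theta_rot))
  invisible(x)
}

#' Steady-state anisotropy of a species
#'
#' Intensity-weighted time average of
#' \eqn{r(t) = r_0 e^{-t/\theta} + r_\infty} over the multi-exponential
#' intensity decay, in closed form:
#' \deqn{r_{ss} = \frac{\sum_i a_i (r_0 \tau_i\theta/(\tau_i+\theta) +
#'   r_\infty \tau_i)}{\sum_i a_i \tau_i}.}
#'
#' @param species A [fluor_species].
#' @return Dimensionless steady-state anisotropy.
#' @export
steady_state_anisotropy <- function(species) {
  stopifnot(inherits(species, "fluor_species"))
  a <- species$amplitudes; tau <- species$lifetimes
  th <- species$theta_rot
  num <- sum(a * (species$r0 * tau * th / (tau + th) + species$r_inf * tau))
  num / sum(a * tau)
}

#' Intensity decay of a species sampled on a time grid
#'
#' @param species A [fluor_species].
#' @param t Numeric vector of times (ns).
#' @param normalize Scale so the samples sum to 1.
#' @return Numeric vector, \eqn{\sum_i a_i e^{-t/\tau_i}}.
#' @keywords internal
species_decay <- function(species, t, normalize = FALSE) {
  d <- rowSums(vapply(seq_along(species$lifetimes), function(i)
    species$amplitudes[i] * exp(-t / species$lifetimes[i]),
    numeric(length(t))))
  if (normalize) d <- d / sum(d)
  d
}

#' Anisotropy decay r(t) of a species
#'
#' @param species A [fluor_species].
#' @param t Times since excitation (ns).
#' @return \eqn{r_0 e^{-t/\theta} + r_\infty}.
#' @keywords internal
species_rt <- function(species, t) {
  species$r0 * exp(-t / species$theta_rot) + species$r_inf
}
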