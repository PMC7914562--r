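#' Instrument configuration for the fiber-HDIM forward model
#'
#' Collects the timing, dispersion, polarization and detection settings of
#' the simulated microscope. Defaults follow a standard multiphoton TCSPC
#' setup: 256 time channels over a 12.5 ns window (80 MHz-class
#' Ti:Sapphire source), a Gaussian instrument response of 150 ps FWHM
#' centred at 10% of the window, and the fiber dispersion calibration of
#' 20 ps of delay per nm of emission wavelength (10 nm per 200 ps).
#'
#' @param n_bins Number of TCSPC time channels (>= 2).
#' @param window Full timing window (ns).
#' @param irf_center Centre of the Gaussian instrument response (ns);
#'   default `0.1 * window`.
#' @param irf_fwhm IRF full width at half maximum (ps).
#' @param dispersion_coeff Fiber chromatic delay per wavelength (ps/nm);
#'   `0` disables spectral encoding.
#' @param ref_wavelength Wavelength mapped to zero extra delay (nm).
#' @param bandpass_center,bandpass_width Ideal top-hat emission bandpass
#'   (nm; full width). Set `bandpass_width = NULL` (or `Inf`) for no filter.
#' @param hwp_angle,qwp_angle Excitation half-/quarter-waveplate fast-axis
#'   angles (degrees). Either may be `NULL` to remove the element.
#' @param analyzer Emission analyzer: `"none"`, `"parallel"` or
#'   `"perpendicular"` (relative to the linear excitation orientation).
#' @param g_factor Detection efficiency ratio eta_par / eta_perp used both
#'   when simulating the perpendicular channel and when computing r.
#' @param photons_per_pixel_scale Expected photon budget per pixel at
#'   relative brightness 1.
#' @param seed Integer seed consumed by stochastic renders.
#' @param two_photon Widen the admissible anisotropy bound to 0.57
#'   (two-photon photoselection); the excitation mixing algebra itself is
#'   kept one-photon.
#' @param dark_rate Constant background counts per bin added to the
#'   expected signal before Poisson sampling.
#'
#' @return An object of class `instrument_config`.
#' @examples
#' cfg <- instrument_config()
#' cfg$dispersion_coeff   # 20 ps/nm
#' @export
instrument_config <- function(n_bins = 256L, window = 12.5,
                              irf_center = NULL, irf_fwhm = 150,
                              dispersion_coeff = 20, ref_wavelength = 630,
                              bandpass_center = 630, bandpass_width = NULL,
                              hwp_angle = 0, qwp_angle = 0,
                              analyzer = c("none", "parallel", "perpendicular"),
                              g_factor = 1, photons_per_pixel_scale = 100,
                              seed = 1L, two_photon = FALSE, dark_rate = 0) {
  analyzer <- match.arg(analyzer)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (!is.finite(window) || window <= 0) stop("window must be > 0")
  if (dispersion_coeff < 0) stop("dispersion_coeff must be >= 0")
  if (g_factor <= 0) stop("g_factor must be > 0")
  if (is.null(irf_center)) irf_center <- 0.1 * window
  if (!is.null(bandpass_width) && !is.finite(bandpass_width)) bandpass_width <- NULL
  if (!is.null(bandpass_width) && bandpass_width <= 0)
    stop("bandpass_width must be > 0 (or NULL for no filter)")
  if (photons_per_pixel_scale < 0) stop("photons_per_pixel_scale must be >= 0")
  structure(list(
    n_bins = n_bins, window = window, irf_center = irf_center,
    irf_fwhm = irf_fwhm, dispersion_coeff = dispersion_coeff,
    ref_wavelength = ref_wavelength, bandpass_center = bandpass_center,
    bandpass_width = bandpass_width, hwp_angle = hwp_angle,
    qwp_angle = qwp_angle, analyzer = analyzer, g_factor = g_factor,
    photons_per_pixel_scale = photons_per_pixel_scale,
    seed = as.integer(seed), two_photon = isTRUE(two_photon),
    dark_rate = dark_rate
  ), class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("<instrument_config>\n")
  cat(sprintf("  timing: %d bins over %g ns (%.3f ps/bin)\n",
              x$n_bins, x$window, 1000 * x$window / x$n_bins))
  cat(sprintf("  IRF: Gaussian, center %g ns, FWHM %g ps\n",
              x$irf_center, x$irf_fwhm))
  cat(sprintf("  dispersion: %g ps/nm, reference %g nm\n",
              x$dispersion_coeff, x$ref_wavelength))
  if (is.null(x$bandpass_width)) cat("  bandpass: none\n")
  else cat(sprintf("  bandpass: %g/%g nm\n", x$bandpass_center, x$bandpass_width))
  cat(sprintf("  excitation: HWP %s deg, QWP %s deg; analyzer %s; G %g\n",
              if (is.null(x$hwp_angle)) "-" else x$hwp_angle,
              if (is.null(x$qwp_angle)) "-" else x$qwp_angle,
              x$analyzer, x$g_factor))
  invisible(x)
}

# Bin width in ns.
bin_dt <- function(config) config$window / config$n_bins

#' Time-bin centers of a configuration
#'
#' Bins are half-open `[t, t + dt)` with bin 0 starting at t = 0; values
#' returned are the midpoints, in ns.
#' @param config An [instrument_config].
#' @return Numeric vector of length `n_bins`.
#' @export
bin_centers <- function(config) {
  (seq_len(config$n_bins) - 0.5) * bin_dt(config)
}

# Admissible anisotropy bound given the excitation mode flag.
config_r_max <- function(config) if (config$two_photon) 0.57 else 0.4

# Bandpass interval (nm) or NULL.
bandpass_limits <- function(config) {
  if (is.null(config$bandpass_width)) return(NULL)
  config$bandpass_center + c(-0.5, 0.5) * config$bandpass_width
}

#' Serialize / restore an instrument configuration as JSON
#'
#' Round-trips losslessly; used by the TIFF sidecar writer and the CLI.
#' @param config An [instrument_config].
#' @param txt JSON text produced by `config_to_json()`.
#' @return `config_to_json()` a JSON string; `config_from_json()` an
#'   [instrument_config].
#' @export
config_to_json <- function(config) {
  stopifnot(inherits(config, "instrument_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname config_to_json
#' @export
config_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  do.call(instrument_config, x[setdiff(names(x), character(0))])
}

#' Gaussian instrument response sampled on the bin grid
#'
#' Normalized to unit sum so that convolution preserves counts.
#' @param config An [instrument_config].
#' @return Numeric vector of length `n_bins`.
#' @export
gaussian_irf <- function(config) {
  sigma <- config$irf_fwhm / 1000 / (2 * sqrt(2 * log(2)))  # ns
  tc <- bin_centers(config)
  irf <- exp(-0.5 * ((tc - config$irf_center) / sigma)^2)
  irf / sum(irf)
}
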