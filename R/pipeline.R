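#' Zero-shift reference histogram for shift decoding / phasor calibration
#'
#' Synthesizes the IRF-reconvolved mono-exponential decay of a given
#' lifetime at the reference wavelength (no dispersion shift) on the
#' config's bin grid — the reference against which fiber time shifts are
#' decoded and phasors calibrated.
#'
#' @param config An [instrument_config].
#' @param tau Reference lifetime (ns).
#' @return Numeric histogram of unit total.
#' @export
reference_histogram <- function(config, tau = 2) {
  t <- bin_centers(config)
  d <- exp(-t / tau)
  h <- circular_convolve(d / sum(d), gaussian_irf(config))
  h / sum(h)
}

#' Per-cell parameters from a sequential multiparametric acquisition
#'
#' Emulates the sequential validation pipeline: the same phantom is
#' imaged four times — plain lifetime (no fiber), parallel and
#' perpendicular anisotropy channels (no fiber), and the fiber spectral
#' arm — with the photon budget split equally across the four
#' acquisitions. Each ROI is reduced to the seven per-cell parameters
#' used for PCA contrast: fractional intensity of the short lifetime
#' species (`f1_pct`), fractional rotational amplitude (`a1_rot`), total
#' intensity, amplitude-weighted mean lifetime (`t_m`), decoded spectral
#' peak (`peak_wavelength`), static anisotropy (`r_static`) and mean
#' rotational time (`theta_mean`).
#'
#' @param phantom A [scene_phantom].
#' @param config Base [instrument_config]; the fiber arm uses its
#'   dispersion/bandpass settings, the other arms disable them.
#' @param mask Label mask (defaults to the phantom's own labels).
#' @param count_floor Minimum ROI counts for fitting.
#' @return A `CellParameterTable`-style data.frame, one row per ROI.
#' @export
hdim_sequential_parameters <- function(phantom, config, mask = NULL,
                                       count_floor = 100) {
  if (is.null(mask)) mask <- phantom$label_image
  quarter <- function(cfg, seed_off, analyzer = "none", fiber = FALSE) {
    cfg$photons_per_pixel_scale <- cfg$photons_per_pixel_scale / 4
    cfg$seed <- cfg$seed + seed_off
    cfg$analyzer <- analyzer
    if (!fiber) { cfg$dispersion_coeff <- 0; cfg$bandpass_width <- NULL }
    cfg
  }
  st_T <- render_stack(phantom, quarter(config, 11L))
  st_par <- render_stack(phantom, quarter(config, 12L, "parallel"))
  st_perp <- render_stack(phantom, quarter(config, 13L, "perpendicular"))
  st_S <- render_stack(phantom, quarter(config, 14L, config$analyzer,
                                        fiber = TRUE))
  hT <- roi_histograms(st_T, mask)
  hpar <- roi_histograms(st_par, mask)
  hperp <- roi_histograms(st_perp, mask)
  hS <- roi_histograms(st_S, mask)
  ref_S <- colSums(hS)
  ids <- as.integer(rownames(hT))
  rows <- lapply(seq_along(ids), function(i) {
    if (sum(hT[i, ]) < count_floor) return(NULL)
    ft <- suppressWarnings(fit_multiexp(hT[i, ], 2, config,
                                        count_floor = count_floor))
    sa <- static_anisotropy(sum(hpar[i, ]), sum(hperp[i, ]), config$g_factor)
    fa <- try(fit_associated_anisotropy(hpar[i, ], hperp[i, ],
                                        ft$lifetimes, config), silent = TRUE)
    sh <- estimate_time_shift(hS[i, ], ref_S, config)
    data.frame(
      roi = ids[i], f1_pct = ft$f1_pct,
      a1_rot = if (inherits(fa, "aniso_fit")) fa$a1_rot else NA_real_,
      intensity = sum(hT[i, ]), t_m = ft$t_m,
      peak_wavelength = shift_to_wavelength(sh, config),
      r_static = sa$r_static,
      theta_mean = if (inherits(fa, "aniso_fit")) fa$theta_mean else NA_real_)
  })
  do.call(rbind, rows)
}

#' Single-shot fiber-HDIM per-cell contrast
#'
#' The direct analysis of the polarization-filtered, spectrally convolved
#' decay stack: per-cell summed histograms are (1) transformed to
#' calibrated phasor coordinates, (2) fit with a free-shift
#' bi-exponential to give the mean lifetime, and (3) cross-correlated
#' against the image-mean histogram to decode the spectral peak. The
#' per-cell (g, s) cloud is clustered by k-means with silhouette
#' selection and the lambda-tau map is assembled.
#'
#' @param stack A fiber-arm `decay_stack`.
#' @param mask Label mask (defaults to the stack's ground-truth labels).
#' @param k_range Candidate cluster counts.
#' @param tau_ref Calibration reference lifetime (ns).
#' @param count_floor Minimum ROI counts.
#' @param seed Clustering seed (defaults to the stack config's seed).
#' @return List with `table` (per-cell parameters incl. `g`, `s`),
#'   `phasors`, `lambda_tau`, `clustering` and `silhouette` (mean
#'   silhouette per k).
#' @export
hdim_fiber_contrast <- function(stack, mask = NULL, k_range = 2,
                                tau_ref = 2, count_floor = 100,
                                seed = NULL) {
  config <- stack$config
  if (is.null(mask)) {
    if (is.null(stack$truth)) stop("no mask given and stack has no ground truth")
    mask <- stack$truth$label_image
  }
  if (is.null(seed)) seed <- config$seed
  hr <- roi_histograms(stack, mask)
  keep <- rowSums(hr) >= count_floor
  hr <- hr[keep, , drop = FALSE]
  if (nrow(hr) < 3) stop("fewer than 3 ROIs above the count floor")
  cal <- phasor_calibration(reference_histogram(config, tau_ref), tau_ref,
                            config)
  ph <- phasor_transform(hr, 1, config, cal)
  ref <- colSums(hr)
  # collapse-to-mono warnings are routine for cells dominated by one species
  fits <- lapply(seq_len(nrow(hr)), function(i)
    suppressWarnings(fit_multiexp(hr[i, ], 2, config, free_shift = TRUE,
                                  count_floor = count_floor)))
  tab <- data.frame(
    roi = as.integer(rownames(hr)),
    g = ph$g, s = ph$s,
    t_m = vapply(fits, `[[`, numeric(1), "t_m"),
    it_m = vapply(fits, `[[`, numeric(1), "it_m"),
    f1_pct = vapply(fits, `[[`, numeric(1), "f1_pct"),
    intensity = rowSums(hr),
    peak_wavelength = vapply(seq_len(nrow(hr)), function(i)
      shift_to_wavelength(estimate_time_shift(hr[i, ], ref, config), config),
      numeric(1)))
  lt <- lambda_tau(tab)
  cl <- cluster_separation(cbind(g = tab$g, s = tab$s), k_range, seed = seed)
  list(table = tab, phasors = ph, lambda_tau = lt, clustering = cl,
       silhouette = cl$silhouette)
}
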