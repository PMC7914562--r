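#' Scene phantom: label image plus per-ROI fluorophore mixtures
#'
#' The phantom stands in for a segmented leaf: an integer label image
#' (ROI id 0 is background), a fluorophore mixture per ROI, and a
#' relative photon rate per ROI.
#'
#' @param label_image Integer matrix (X x Y) of ROI ids; 0 = background.
#' @param cell_mixtures Named list, one entry per ROI id (names are the
#'   ids as character); each entry is a list of `list(species =
#'   <fluor_species>, fraction = <number>)` whose fractions sum to 1.
#' @param brightness Named numeric of relative photon rates per ROI;
#'   missing ROIs default to 1, background ("0") defaults to 0.
#' @return An object of class `scene_phantom`.
#' @export
scene_phantom <- function(label_image, cell_mixtures, brightness = NULL) {
  label_image <- as.matrix(label_image)
  storage.mode(label_image) <- "integer"
  ids <- sort(setdiff(unique(as.vector(label_image)), 0L))
  for (id in ids) {
    key <- as.character(id)
    if (is.null(cell_mixtures[[key]]))
      stop("ROI id ", id, " present in label_image but missing from cell_mixtures")
    fr <- vapply(cell_mixtures[[key]], `[[`, numeric(1), "fraction")
    if (abs(sum(fr) - 1) > 1e-8)
      stop("fractions for ROI ", id, " must sum to 1")
    ok <- vapply(cell_mixtures[[key]],
                 function(e) inherits(e$species, "fluor_species"), logical(1))
    if (!all(ok)) stop("every mixture entry needs a fluor_species")
  }
  if (is.null(brightness)) brightness <- stats::setNames(rep(1, length(ids)),
                                                         as.character(ids))
  structure(list(label_image = label_image, cell_mixtures = cell_mixtures,
                 brightness = brightness), class = "scene_phantom")
}

#' @export
print.scene_phantom <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$label_image)), 0L)
  cat(sprintf("<scene_phantom> %d x %d pixels, %d ROIs\n",
              nrow(x$label_image), ncol(x$label_image), length(ids)))
  invisible(x)
}

phantom_brightness <- function(phantom, id) {
  b <- phantom$brightness[[as.character(id)]]
  if (is.null(b) || is.na(b)) { if (id == 0L) 0 else 1 } else b
}

# Time-resolved analyzer weight per bin for one species, including the
# excitation-state anisotropy multiplier and the detection G factor
# (the simulated perpendicular channel reports counts/g so that the
# standard G-corrected formula recovers r).
analyzer_weight_t <- function(species, config, t) {
  if (config$analyzer == "none") return(rep(1, length(t)))
  state <- excitation_state(config$hwp_angle, config$qwp_angle)
  r_eff <- anisotropy_multiplier(state) * species_rt(species, t)
  if (config$analyzer == "parallel") (1 + 2 * r_eff) / 3
  else (1 - r_eff) / 3 / config$g_factor
}

#' Expected (pre-Poisson) decay profile of a mixture
#'
#' Composes the full forward model for one pixel at unit photon budget:
#' for each species the normalized multi-exponential decay is weighted by
#' the time-resolved analyzer transmission, dispersed through the fiber
#' (emission spectrum mapped to delay, bandpass applied) and convolved
#' with the Gaussian IRF; species are combined by their mixture fractions.
#'
#' @param mixture List of `list(species, fraction)` entries.
#' @param config An [instrument_config].
#' @return Numeric vector of length `n_bins`; its sum is the detected
#'   fraction of the nominal photon budget (<= 1; < 1 when the analyzer
#'   or the bandpass rejects photons).
#' @export
expected_pixel_profile <- function(mixture, config) {
  t <- bin_centers(config)
  irf <- gaussian_irf(config)
  out <- numeric(config$n_bins)
  for (entry in mixture) {
    sp <- entry$species
    d <- species_decay(sp, t, normalize = TRUE)
    d <- d * analyzer_weight_t(sp, config, t)
    disp <- disperse_decay(d, sp$emission_peak, sp$emission_width, config)
    out <- out + entry$fraction * circular_convolve(disp$profile, irf)
  }
  out
}

#' Render one pixel's TCSPC histogram
#'
#' @param mixture List of `list(species, fraction)`; fractions sum to 1.
#' @param n_photons Expected (nominal) photon count for the pixel.
#' @param config An [instrument_config].
#' @param noise Draw Poisson counts (`TRUE`) or return the expected
#'   profile (`FALSE`).
#' @return Numeric vector of length `n_bins` (integer counts when
#'   `noise = TRUE`). Uses the current RNG state; seed with `set.seed()`
#'   for reproducibility.
#' @export
render_pixel <- function(mixture, n_photons, config, noise = TRUE) {
  if (n_photons < 0) stop("n_photons must be >= 0")
  fr <- vapply(mixture, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("mixture fractions must sum to 1")
  mu <- n_photons * expected_pixel_profile(mixture, config) + config$dark_rate
  if (!noise) return(mu)
  stats::rpois(length(mu), mu)
}

#' Render a full decay stack from a phantom
#'
#' Per-ROI expected profiles are computed once and Poisson-sampled per
#' pixel, seeded from `config$seed`, so identical (phantom, config, seed)
#' give bit-identical stacks.
#'
#' @param phantom A [scene_phantom].
#' @param config An [instrument_config].
#' @param noise Poisson noise flag.
#' @return A `decay_stack`: list with `counts` (X x Y x T array), `config`
#'   and `truth` (the phantom).
#' @export
render_stack <- function(phantom, config, noise = TRUE) {
  stopifnot(inherits(phantom, "scene_phantom"),
            inherits(config, "instrument_config"))
  lab <- phantom$label_image
  nx <- nrow(lab); ny <- ncol(lab); nb <- config$n_bins
  counts <- array(0, dim = c(nx, ny, nb))
  ids <- sort(unique(as.vector(lab)))
  profiles <- list()
  for (id in ids) {
    if (id == 0L && is.null(phantom$cell_mixtures[["0"]])) {
      profiles[["0"]] <- rep(0, nb)
      next
    }
    mix <- phantom$cell_mixtures[[as.character(id)]]
    if (is.null(mix))
      stop("ROI id ", id, " missing from cell_mixtures")
    profiles[[as.character(id)]] <-
      expected_pixel_profile(mix, config) *
      phantom_brightness(phantom, id) * config$photons_per_pixel_scale
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  flat <- matrix(0, nx * ny, nb)
  labv <- as.vector(lab)
  for (id in ids) {
    idx <- which(labv == id)
    mu <- profiles[[as.character(id)]] + config$dark_rate
    if (all(mu == 0)) next
    m <- if (noise)
      matrix(stats::rpois(length(idx) * nb, rep(mu, each = length(idx))),
             length(idx), nb)
    else matrix(rep(mu, each = length(idx)), length(idx), nb)
    flat[idx, ] <- m
  }
  counts <- array(flat, dim = c(nx, ny, nb))
  structure(list(counts = counts, config = config, truth = phantom),
            class = "decay_stack")
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_stack> %d x %d pixels, %d time bins, %.3g total counts\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Scan waveplate angles for inter-ROI anisotropy contrast
#'
#' Emulates the instrument's polarization optimization: for every
#' (HWP, QWP) angle pair, parallel and perpendicular stacks are rendered
#' at a low photon budget and an inter-ROI contrast statistic (default:
#' range of ROI-mean static anisotropy) is evaluated. Ties in the argmax
#' are broken toward the smallest angles.
#'
#' @param phantom A [scene_phantom] with at least two ROIs.
#' @param config An [instrument_config]; its `photons_per_pixel_scale`
#'   sets the scan budget.
#' @param hwp_grid,qwp_grid Numeric angle grids (degrees), non-empty.
#' @param contrast_fn Function of a numeric vector of per-ROI mean static
#'   anisotropies returning a scalar contrast; default `diff(range(.))`.
#' @param noise Poisson noise in the scan renders.
#' @return List with `contrast` (matrix, HWP x QWP), `best_hwp`,
#'   `best_qwp`, and the angle grids.
#' @export
polarization_scan <- function(phantom, config, hwp_grid, qwp_grid,
                              contrast_fn = NULL, noise = TRUE) {
  if (length(hwp_grid) < 1 || length(qwp_grid) < 1)
    stop("angle grids must be non-empty")
  ids <- sort(setdiff(unique(as.vector(phantom$label_image)), 0L))
  if (length(ids) < 2) stop("contrast needs at least two ROIs")
  if (is.null(contrast_fn)) contrast_fn <- function(r) diff(range(r))
  hwp_grid <- sort(hwp_grid); qwp_grid <- sort(qwp_grid)
  cm <- matrix(NA_real_, length(hwp_grid), length(qwp_grid),
               dimnames = list(hwp_grid, qwp_grid))
  mask <- phantom$label_image
  for (i in seq_along(hwp_grid)) for (j in seq_along(qwp_grid)) {
    cfg_par <- config; cfg_par$hwp_angle <- hwp_grid[i]
    cfg_par$qwp_angle <- qwp_grid[j]
    cfg_par$seed <- config$seed + (i - 1L) * length(qwp_grid) + (j - 1L)
    cfg_perp <- cfg_par
    cfg_par$analyzer <- "parallel"; cfg_perp$analyzer <- "perpendicular"
    sp <- render_stack(phantom, cfg_par, noise = noise)
    ss <- render_stack(phantom, cfg_perp, noise = noise)
    npx <- prod(dim(sp$counts)[1:2])
    tot_par <- rowSums(matrix(sp$counts, npx))
    tot_perp <- rowSums(matrix(ss$counts, npx))
    rs <- vapply(ids, function(id) {
      sel <- which(as.vector(mask) == id)
      static_anisotropy(sum(tot_par[sel]), sum(tot_perp[sel]),
                        config$g_factor)$r_static
    }, numeric(1))
    cm[i, j] <- contrast_fn(rs)
  }
  best <- which(cm >= max(cm) - 1e-12, arr.ind = TRUE)
  best <- best[order(hwp_grid[best[, 1]], qwp_grid[best[, 2]]), , drop = FALSE][1, ]
  list(contrast = cm, best_hwp = hwp_grid[best[1]], best_qwp = qwp_grid[best[2]],
       hwp_grid = hwp_grid, qwp_grid = qwp_grid)
}
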