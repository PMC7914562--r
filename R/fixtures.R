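#' Jittered-grid cell label image
#'
#' Voronoi-style epidermal-cell mosaic: seeds on a jittered regular grid,
#' pixels assigned to the nearest seed, with a thin background ridge
#' along cell boundaries (id 0), mimicking segmented leaf epidermis.
#'
#' @param nx,ny Image size in pixels.
#' @param n_side Cells per side (total `n_side^2` ROIs).
#' @param gap Half-width of the background boundary ridge, in the
#'   distance-difference metric (0 disables walls).
#' @return Integer matrix of ROI ids (row = x).
#' @export
make_cell_labels <- function(nx, ny, n_side = 5, gap = 1.2) {
  cw <- nx / n_side; ch <- ny / n_side
  sx <- rep((seq_len(n_side) - 0.5) * cw, n_side) +
    stats::runif(n_side^2, -cw / 4, cw / 4)
  sy <- rep((seq_len(n_side) - 0.5) * ch, each = n_side) +
    stats::runif(n_side^2, -ch / 4, ch / 4)
  lab <- matrix(0L, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    d2 <- (x - 0.5 - sx)^2 + (y - 0.5 - sy)^2
    o <- order(d2)[1:2]
    if (sqrt(d2[o[2]]) - sqrt(d2[o[1]]) > gap) lab[x, y] <- o[1]
  }
  lab
}

clipnorm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Deterministic simulation fixtures
#'
#' Small, fully seeded phantom + configuration + rendered stack bundles
#' emulating the study conditions:
#' \describe{
#'   \item{`uniform`}{One ROI covering the image, a single
#'     mono-exponential species; baseline for calibration tests.}
#'   \item{`two_population_leaf`}{A 64 x 64 leaf mosaic of 25 cells in
#'     two populations: an anthocyanin-rich one dominated by a short-
#'     lifetime, red-shifted species (bi-exponential 0.6/1.8 ns, peak
#'     645 nm) and a poor one dominated by longer-lived, bluer
#'     autofluorescence (1.5/3.2 ns, peak 618 nm), both inside the
#'     630/69 nm band. Per-cell variability: mixture fraction, overall
#'     brightness and anisotropy jitter uncorrelated with population.
#'     Rendered with the fiber arm (dispersion on, bandpass on,
#'     effective parallel analyzer, HWP 160 / QWP 80).}
#'   \item{`polarization_scan_demo`}{Two ROIs of equal lifetime but very
#'     different rotational mobility, for exercising the waveplate scan.}
#'   \item{`bandpass_demo`}{Paired stacks (filter on / off, identical
#'     photon-rate settings) of cells sharing a bright band-edge
#'     emitter plus a per-cell variable in-band species: without the
#'     filter the common emitter dominates every cell's decoded shift;
#'     the filter suppresses it and widens the per-cell shift
#'     distribution.}
#' }
#'
#' @param name Scenario name.
#' @param seed Integer seed controlling the phantom and the render.
#' @param size Image side in pixels (default: scenario-specific).
#' @return List with `phantom`, `config` and `stack`; `bandpass_demo`
#'   instead returns `config_on`/`config_off` and `stack_on`/`stack_off`.
#' @export
make_fixture <- function(name = c("uniform", "two_population_leaf",
                                  "polarization_scan_demo", "bandpass_demo"),
                         seed = 1, size = NULL) {
  name <- match.arg(name)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  switch(name,
    uniform = {
      if (is.null(size)) size <- 32
      sp <- fluor_species("uniform-dye", 2.0, 1, emission_peak = 630,
                          emission_width = 8, r0 = 0.3, theta_rot = 1.5)
      lab <- matrix(1L, size, size)
      ph <- scene_phantom(lab, list("1" = list(list(species = sp, fraction = 1))))
      cfg <- instrument_config(photons_per_pixel_scale = 200,
                               seed = seed + 1L)
      list(phantom = ph, config = cfg, stack = render_stack(ph, cfg))
    },
    two_population_leaf = {
      if (is.null(size)) size <- 64
      lab <- make_cell_labels(size, size, n_side = 5)
      ids <- sort(setdiff(unique(as.vector(lab)), 0L))
      rich <- sample(ids, length(ids) %/% 2)
      mixtures <- list(); bright <- stats::setNames(numeric(0), character(0))
      for (id in ids) {
        r0_cell <- clipnorm(1, 0.33, 0.03, 0.05, 0.4)
        antho <- fluor_species("anthocyanin-like", c(0.6, 1.8), c(2, 1),
                               emission_peak = 645, emission_width = 10,
                               r0 = r0_cell, r_inf = 0.02, theta_rot = 2.0)
        other <- fluor_species("autofluorescence", c(1.5, 3.2), c(1, 1.2),
                               emission_peak = 618, emission_width = 10,
                               r0 = r0_cell, r_inf = 0.02, theta_rot = 2.0)
        f <- if (id %in% rich) clipnorm(1, 0.85, 0.06, 0.02, 0.98)
             else clipnorm(1, 0.15, 0.06, 0.02, 0.98)
        mixtures[[as.character(id)]] <-
          list(list(species = antho, fraction = f),
               list(species = other, fraction = 1 - f))
        bright[as.character(id)] <- stats::rlnorm(1, 0, 0.25)
      }
      ph <- scene_phantom(lab, mixtures, bright)
      cfg <- instrument_config(bandpass_width = 69, hwp_angle = 160,
                               qwp_angle = 80, analyzer = "parallel",
                               photons_per_pixel_scale = 500,
                               seed = seed + 1L)
      attr(ph, "rich_ids") <- sort(rich)
      list(phantom = ph, config = cfg, stack = render_stack(ph, cfg))
    },
    polarization_scan_demo = {
      if (is.null(size)) size <- 24
      lab <- matrix(0L, size, size)
      lab[, seq_len(size %/% 2 - 1)] <- 1L
      lab[, (size %/% 2 + 2):size] <- 2L
      mobile <- fluor_species("mobile-dye", 2.0, 1, emission_peak = 630,
                              r0 = 0.08, theta_rot = 0.3)
      rigid <- fluor_species("rigid-dye", 2.0, 1, emission_peak = 630,
                             r0 = 0.38, r_inf = 0.05, theta_rot = 1.5)
      ph <- scene_phantom(lab, list(
        "1" = list(list(species = mobile, fraction = 1)),
        "2" = list(list(species = rigid, fraction = 1))))
      cfg <- instrument_config(dispersion_coeff = 0,
                               photons_per_pixel_scale = 300,
                               seed = seed + 1L)
      list(phantom = ph, config = cfg, stack = render_stack(ph, cfg))
    },
    bandpass_demo = {
      if (is.null(size)) size <- 48
      lab <- make_cell_labels(size, size, n_side = 4)
      ids <- sort(setdiff(unique(as.vector(lab)), 0L))
      common <- fluor_species("band-edge-dominant", 2.2, 1,
                              emission_peak = 672, emission_width = 8,
                              r0 = 0.3, theta_rot = 1.5)
      mixtures <- list()
      for (id in ids) {
        varsp <- fluor_species("in-band-variable", 1.0, 1,
                               emission_peak = stats::runif(1, 600, 660),
                               emission_width = 8, r0 = 0.3, theta_rot = 1.5)
        mixtures[[as.character(id)]] <-
          list(list(species = common, fraction = 0.75),
               list(species = varsp, fraction = 0.25))
      }
      ph <- scene_phantom(lab, mixtures)
      cfg_off <- instrument_config(bandpass_width = NULL,
                                   photons_per_pixel_scale = 250,
                                   seed = seed + 1L)
      cfg_on <- cfg_off; cfg_on$bandpass_width <- 69
      list(phantom = ph, config_on = cfg_on, config_off = cfg_off,
           stack_on = render_stack(ph, cfg_on),
           stack_off = render_stack(ph, cfg_off))
    })
}
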