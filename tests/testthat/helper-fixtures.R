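# Shared builders for small test objects.

tiny_config <- function(...) instrument_config(...)

mono_species <- function(tau = 2, peak = 630, width = 0, ...)
  fluor_species(paste0("mono-", tau), tau, 1, emission_peak = peak,
                emission_width = width, ...)

mono_mixture <- function(...) list(list(species = mono_species(...), fraction = 1))

# Noiseless IRF-reconvolved histogram of a pure mixture at given photons.
noiseless_hist <- function(mixture, photons, config)
  render_pixel(mixture, photons, config, noise = FALSE)

# Two-ROI side-by-side phantom.
two_roi_phantom <- function(size, species_a, species_b, brightness = NULL) {
  lab <- matrix(0L, size, size)
  half <- size %/% 2
  lab[, seq_len(half)] <- 1L
  lab[, (half + 1):size] <- 2L
  scene_phantom(lab, list(
    "1" = list(list(species = species_a, fraction = 1)),
    "2" = list(list(species = species_b, fraction = 1))), brightness)
}
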