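Package: fiberhdim
Title: Fiber-Based Hyperdimensional Fluorescence Contrast Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fiber-dispersed, polarization-filtered
    time-correlated single-photon-counting (TCSPC) fluorescence lifetime images.
    A forward optical model encodes emission spectrum (via chromatic fiber
    dispersion onto the decay-time axis), excitation polarization (via
    half-/quarter-waveplate Jones calculus and dipole photoselection) and
    fluorescence lifetime of fluorophore mixtures into single per-pixel decay
    histograms with Poisson shot noise. Decoding tools recover spectral peak
    shifts by sub-bin cross-correlation, fit multi-exponential decays by
    instrument-response reconvolution, compute static and associated
    time-resolved anisotropy, and map per-cell hyperdimensional contrast with
    phasor transforms, lambda-tau maps, (sparse) principal components and
    k-means/silhouette cluster separation. Aimed at separating short-lifetime,
    red-shifted vacuolar pigments (anthocyanins) from other plant
    autofluorescence at single-cell resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    tiff,
    minpack.lm,
    cluster
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
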