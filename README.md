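# fiberhdim

Simulation and analysis of **fiber-dispersed hyperdimensional contrast
imaging**: a fluorescence-lifetime (TCSPC) scheme in which a long
multimode collection fiber converts each photon's emission wavelength
into an extra arrival delay (here 20 ps/nm, i.e. 200 ps per 10 nm) and
the excitation waveplates fix a polarization contrast axis, so that a
*single* per-pixel decay histogram simultaneously encodes lifetime,
emission spectrum and anisotropy. The package is aimed at microscopists
and image analysts who want to study, calibrate or decode this class of
measurement — its motivating application is separating anthocyanin-rich
from anthocyanin-poor plant epidermal cells by their short (0.5–3 ns),
red-shifted vacuolar pigment fluorescence.

## What is inside

**Forward model.** Per pixel, the expected histogram is

μ(t) = N Σₛ fₛ · IRF ⊗ [ ∫ Sₛ(λ) dₛ(t − c(λ − λ_ref)) wₛ(t) dλ ],

with multi-exponential decays dₛ(t) = Σᵢ aᵢ e^(−t/τᵢ), Gaussian emission
spectra Sₛ mapped onto the time axis by the fiber dispersion c, an ideal
630/69 nm-style bandpass, analyzer weights wₛ(t) = (1 ± 2 r_eff(t))/3
driven by r(t) = r₀e^(−t/θ) + r∞ and the Jones-calculus excitation state
of the HWP/QWP pair, a Gaussian IRF, and Poisson shot noise
(`fluor_species()`, `instrument_config()`, `scene_phantom()`,
`render_stack()`, `polarization_scan()`).

**Decoding.** IRF-reconvolution multi-exponential fitting with Poisson
weights (`fit_multiexp()`, a classed `decay_fit` with
`print`/`coef`/`fitted`/`residuals`/`plot` methods), sub-bin
cross-correlation shift decoding and the shift-to-wavelength calibration
(`estimate_time_shift()`, `shift_to_wavelength()`), static and
associated time-resolved anisotropy (`static_anisotropy()`,
`fit_associated_anisotropy()`), and pixel/ROI maps
(`parameter_image()`, `paint_cells()`).

**Contrast.** Calibrated phasor transforms on the universal semicircle
(`phasor_transform()`, `phasor_calibration()`), lambda–tau maps
(`lambda_tau()`), standardized (sparse) PCA (`standardize_table()`,
`pca_contrast()`) and k-means with silhouette model selection
(`cluster_separation()`); `hdim_fiber_contrast()` and
`hdim_sequential_parameters()` run the two competing per-cell pipelines
end to end.

**I/O.** Multi-page TIFF + JSON sidecar stacks (`write_stack()`,
`read_stack()`), read-only Becker&Hickl SDT support with a synthetic
fixture writer (`read_sdt()`, `write_sdt_fixture()`), label masks, run
manifests, and a CLI (`inst/cli/fiberhdim.R`) with the verbs `simulate`,
`polscan`, `fit`, `aniso`, `contrast`, `fixtures`.

## Worked example

```r
library(fiberhdim)

# a 64 x 64 leaf phantom: 25 cells, two populations, fiber arm on
fx <- make_fixture("two_population_leaf", seed = 1)
fx$stack
#> <decay_stack> 64 x 64 pixels, 256 time bins, 8.27e+05 total counts

fc <- hdim_fiber_contrast(fx$stack, k_range = 2)
head(fc$table[, c("roi", "g", "s", "t_m", "peak_wavelength")], 4)
#>   roi     g     s   t_m peak_wavelength
#> 1   1 0.552 0.408 1.886         623.070
#> 2   2 0.657 0.468 1.342         632.954
#> 3   3 0.527 0.408 2.043         620.251
#> 4   4 0.512 0.404 2.159         619.983
fc$silhouette
#>     2
#> 0.908
```

Each row is one cell: `(g, s)` are its calibrated phasor coordinates,
`t_m` the amplitude-weighted mean lifetime from a free-shift
bi-exponential reconvolution fit, and `peak_wavelength` the emission
peak decoded from the fiber time shift. Anthocyanin-rich cells sit at
short `t_m` and red-shifted peaks (e.g. cell 2), and k-means on the
phasor cloud separates the two populations with mean silhouette 0.91 —
well above the 0.5 threshold for substantial cluster structure.

The dispersion encoding itself is visible on a single decay: a 3 ns
emitter peaking 10 nm above the reference wavelength fits back with its
shift decoded,

```r
cfg <- instrument_config(seed = 17)   # 20 ps/nm, 256 bins over 12.5 ns
set.seed(17)
h <- render_pixel(list(list(species = fluor_species("antho", 3, 1, 640),
                            fraction = 1)), 1e6, cfg)
f <- fit_multiexp(h, 1, cfg, free_shift = TRUE)
round(c(tau_ns = unname(f$lifetimes), shift_ps = f$shift), 3)
#>   tau_ns shift_ps
#>    2.994  199.308
shift_to_wavelength(f$shift, cfg)
#> [1] 639.965
```

i.e. the 10 nm peak offset is recovered as a ~200 ps delay and converted
back to 640 nm by the fiber calibration.

## Documentation

The methods vignette (`vignettes/fiber-hdim-methods.Rmd`) describes the
model and its assumptions, the timing/phasor conventions, what the
synthetic phantoms do and do not emulate, and the numerical design
choices; every exported function has reference documentation.
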