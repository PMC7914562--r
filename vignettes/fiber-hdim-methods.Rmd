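---
title: "Fiber-dispersed hyperdimensional contrast imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-dispersed hyperdimensional contrast imaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement this package models

A time-correlated single-photon-counting (TCSPC) microscope records, per
pixel, a histogram of photon arrival times relative to the laser pulse.
Fiber-dispersed hyperdimensional contrast imaging folds two further
fluorescence dimensions into that same one-dimensional histogram:

* **Spectrum.** The emission is collected through a long multimode fiber
  whose chromatic dispersion delays photons in proportion to their
  wavelength. With the calibration used here — 20 ps of delay per nm,
  i.e. 200 ps per 10 nm — a fluorophore's emission peak becomes a rigid
  time shift of its decay, and its spectral lineshape becomes a smearing
  kernel along the time axis.
* **Polarization.** The excitation polarization is set by a quarter-wave
  plate followed by a half-wave plate, and the detection path has an
  effective analyzer. Photoselection then weights each species' decay by
  its time-dependent anisotropy, so rotational mobility modulates the
  recorded curve.

A single detector therefore records, per pixel, a polarization-filtered,
spectrally convolved intensity decay. The package implements both the
forward model (so the scheme can be studied quantitatively on synthetic
phantoms with known ground truth) and the decoding chain used on real
data: reconvolution lifetime fitting, sub-bin spectral-shift decoding,
static and associated time-resolved anisotropy, and the per-cell contrast
representations (phasor plots, lambda-tau maps, PCA, k-means with
silhouette scoring).

## Forward model

For a species with pre-exponential amplitudes $a_i$ and lifetimes
$\tau_i$, emission Gaussian $S(\lambda)$ (peak $\lambda_p$, width
$\sigma$), and anisotropy decay $r(t) = r_0 e^{-t/\theta} + r_\infty$,
the expected histogram of a pixel is assembled as

$$
\mu(t) \;=\; N \sum_{\text{species } s} f_s \,
\mathrm{IRF} \otimes \Big[ \int S_s(\lambda)\,
  d_s\big(t - c(\lambda - \lambda_{\mathrm{ref}})\big)\, w_s(t)\,
  d\lambda \Big],
$$

where $d_s(t) = \sum_i a_i e^{-t/\tau_i}$ (unit-normalized), $c$ is the
dispersion coefficient, $w_s(t)$ the analyzer transmission
($(1 + 2 r_{\mathrm{eff}}(t))/3$ parallel, $(1 - r_{\mathrm{eff}}(t))/3/G$
perpendicular, 1 for no analyzer), and counts are drawn as independent
Poisson variates. The excitation state enters through
$r_{\mathrm{eff}}(t) = m\, r(t)$ with $m = p - (1-p)/2$, $p$ the linear
fraction of the excitation computed by Jones calculus: pure linear
excitation gives $m = 1$, pure circular the classic one-photon $-1/2$,
elliptical states interpolate linearly. The bandpass filter is an ideal
top-hat that truncates and rescales $S(\lambda)$, so filtered renders
lose exactly the out-of-band spectral fraction.

Assumptions worth keeping in mind:

* Emission spectra are single Gaussians; only the peak is ever decoded
  (the width is reported as "unresolved" by design, since a single
  dispersed decay cannot separate width from lineshape without further
  modelling).
* Photoselection is one-photon. Under the `two_photon` flag the
  admissible anisotropy bound is widened from 0.4 to 0.57, but the
  angular algebra is kept one-photon because no cos⁴ mixing rule is
  assumed; this is a deliberate simplification.
* Noise is Poisson only — no afterpulsing or dead time; a constant dark
  rate per bin is available via `dark_rate`.

## Timing conventions and numerical choices

**Window and bins.** Default 256 channels over 12.5 ns (~48.8 ps/bin),
the natural window of an 80 MHz-class Ti:Sapphire oscillator. Bins are
half-open $[t, t + \Delta t)$ starting at $t = 0$; computations use bin
centres.

**Periodic (circular) time axis.** Dispersion shifts and the IRF
convolution act circularly on the window: photons delayed past the end
re-enter at the start, exactly as delayed fluorescence wraps into the
next excitation period of a high-repetition-rate source. This choice is
what makes photon conservation of the dispersion operator exact (tested
to 1e-6 relative and holding to machine precision), and it makes the IRF
an exactly multiplicative factor in phasor space, so a single-reference
phasor calibration removes it without residual.

**IRF.** Gaussian, default 150 ps FWHM centred at 10% of the window,
sampled on the bin grid and normalized to unit sum.

**Fractional shifts.** Sub-bin time shifts use linear interpolation on
the circular grid, which conserves the histogram total exactly.

**Shift decoding.** The spectral shift estimator maximizes the circular
normalized cross-correlation, Fourier-upsampled 16x and refined by
parabolic interpolation; accuracy on smooth decays is a few tenths of a
ps (the 10 nm calibration round trip decodes 200 ps to within ~0.2 ps).
The zero-shift reference is synthesized from the configuration
(IRF-reconvolved mono-exponential at the reference wavelength); for real
data a reference ROI's mean histogram serves instead. Pixel-level maps
default to the image-mean histogram as reference, which centres the
decoded wavelength scale on the image average.

**Reconvolution fitting.** Weighted Levenberg–Marquardt least squares
(via `minpack.lm`) of the circularly IRF-convolved multi-exponential
with Poisson weights $1/\max(y, 1)$, matching the chi-square-reporting
style of commercial TCSPC fitters; a Poisson-deviance MLE objective is
available behind a flag. Start values come from a tail log-slope
estimate. Results are canonicalized ($\tau_1 \le \tau_2$, non-negative
amplitudes); two-component fits that collapse (lifetimes within 1% or
one component's intensity fraction below $10^{-4}$) are refit as
mono-exponential with a warning, and non-convergence sets a flag rather
than throwing. Derived scalars follow the standard definitions:
fractional intensity $f_1 = a_1\tau_1 / \sum a_i \tau_i$ (an intensity
fraction, distinct from the amplitude fraction, which is reported
separately), amplitude-weighted $\tau_m$ and intensity-weighted
$i\tau_m$.

**Phasors.** First-harmonic by default with $\omega = 2\pi/\mathrm{window}$
and bin-centre times. Calibration maps a measured mono-exponential
reference onto its theoretical point $1/(1 - i\omega\tau)$; calibrated
mono-exponentials then sit on the universal semicircle to better than
$10^{-3}$ across 0.5–3 ns. One discretization fact is documented rather
than hidden: in the zero-lifetime limit a delta decay carries the
half-bin phase $\omega \Delta t / 2 \approx 0.012$ rad of the bin-centre
convention, so the (1, 0) corner is approached only to within half a
bin.

**Anisotropy.** $r(t)$ is formed bin-wise with the G factor and a count
floor (low-count bins become NaN and are excluded); the associated model
fixes the two population lifetimes from the intensity fit, fits
per-species $r_{0i}, \theta_i$ plus a shared $r_\infty$, and starts the
fit domain at the 90%-rise bin of the IRF since no anisotropy
deconvolution is attempted. Times in the rotational model are measured
from the IRF centre. No upper bound is placed on $\theta$: rotational
times far above the fluorescence lifetimes are legitimate and occur for
large or bound fluorophores. The G factor defaults to 1 (no calibration
is assumed); `calibrate_g_factor()` implements tail matching against a
reference dye. Both the conventional difference-over-total anisotropy
and the depolarized-fraction ratio are computed and exported, because
instrument conventions differ on which of the two is painted as "r";
they are related by $r = 1 - 3d$ and the package does not silently pick
one.

**Clustering.** k-means with 10 restarts and a fixed seed; model order
is chosen by mean Euclidean silhouette, with ties broken by lower
inertia and then smaller k. Mean silhouette above 0.5 is read, as is
conventional, as substantial cluster structure.

## The synthetic phantoms: what they emulate, and what they do not

`make_fixture()` ships four deterministic scenarios. The central one,
`two_population_leaf`, emulates a cotyledon epidermis imaged through the
fiber arm: a 64 x 64 jittered-Voronoi mosaic of 25 cells, half
anthocyanin-rich (dominated by a short-lifetime bi-exponential species,
0.6/1.8 ns, red-shifted peak at 645 nm) and half anthocyanin-poor
(longer-lived 1.5/3.2 ns autofluorescence peaking at 618 nm), both
emission peaks inside a 630/69 nm band; the anthocyanin short components
sit inside the 0.5–3.0 ns reference range used for this pigment.
Biological variability is emulated by per-cell mixture fractions
(s.d. 0.06 around 0.85/0.15), log-normal brightness (s.d. 0.25), and
per-cell anisotropy jitter uncorrelated with population — the latter two
deliberately make intensity and the rotational parameters noisy,
population-uninformative axes, as they are in the real tissue. The
photon budget (nominal 500 per pixel) is set so every cell detects at
least $10^4$ photons after analyzer and bandpass losses.

`bandpass_demo` reproduces the mechanism by which a restrictive emission
filter *widens* the per-cell spectral-shift distribution: every cell
shares a bright band-edge emitter (peak 672 nm) that dominates
unfiltered decoding and pins all cells near one shift, plus a weaker
per-cell variable in-band species; the 630/69 filter suppresses the
dominant emitter so the per-cell variation becomes visible. The package
asserts only the monotone widening, not a specific widening factor,
because the factor depends entirely on the sample's spectral
composition.

What the phantoms do **not** emulate: chlorophyll photophysics and
re-absorption, spatial texture within cells, segmentation errors (label
masks are taken as given — segmentation itself is out of scope), fiber
modal dispersion beyond the linear calibration, detector afterpulsing
and dead time, and real filter edge profiles. Passing tests on these
phantoms therefore validate the *decoding chain and its contrasts*, not
the biology of any particular leaf.

## Design choices where the design was open

* **Waveplate order and input state.** The simulator fixes a horizontal
  input polarization passing the QWP first, then the HWP. Real
  instruments differ in element order and in residual polarization of
  the delivery optics, and measured peak-contrast angles are known to
  drift for exactly that reason; no specific ellipse (e.g. the one
  produced by HWP 160 / QWP 80 here) should be treated as ground truth
  for another instrument. The polarization scan utility exists precisely
  so the best contrast axis is *found*, not assumed.
* **Sequential-versus-single-shot comparison.** The sequential
  seven-parameter pipeline splits the photon budget equally across its
  four acquisitions (lifetime, two polarization channels, fiber arm),
  which is what "matched photon budget" means here; the single-shot
  fiber arm spends the whole budget on one stack. This is the fair-odds
  framing in which the phasor contrast is compared against sequential
  PCA contrast.
* **Per-cell granularity.** All contrast tables reduce each ROI to the
  mean over its valid (non-NaN) pixels; unsegmentable or under-count
  regions drop out of all statistics rather than entering as zeros.
* **On-disk formats.** The canonical format is multi-page TIFF plus a
  JSON sidecar (plain-text inspectable, lossless); counts above 65535
  are stored as scaled 32-bit float pages with the scale in the sidecar,
  exact for counts below $2^{24}$. The vendor SDT format is read-only,
  against the publicly documented header layout; the reader fails loudly
  on anything it does not recognize, and the bundled fixture writer
  produces only clearly labelled synthetic files for tests.

## Problem sizes

The test-suite and acceptance computations run at desk scale by choice:
64 x 64 pixels x 256 bins for the leaf phantom (25 cells, >= 1e4 photons
each), 48 x 48 for the bandpass pair, single-histogram fits at 1e6
photons, and dense-grid fitting oracles restricted to small lifetime
boxes. These sizes keep every check reproducible in seconds on a single
CPU while leaving the per-cell statistics (fit errors ~1–3%) in the same
regime as full-frame acquisitions.

## Known limitations

* The dispersion model is strictly linear in wavelength; real fibers
  show mild curvature over wide spectral ranges.
* Free-shift bi-exponential fitting at low counts can trade shift
  against the fast component; the per-cell tables mitigate this by
  fitting ROI-summed histograms.
* The associated anisotropy fit inherits the no-deconvolution
  approximation; rotational times comparable to the IRF width (< ~0.3
  ns) are recovered with visible bias.
* Sparse PCA uses a soft-thresholded power iteration with an L1 budget;
  it is a pragmatic sparse rotation, not a tuned feature selector, and
  with strongly correlated informative columns it may concentrate
  loading on one representative of a correlated pair.
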