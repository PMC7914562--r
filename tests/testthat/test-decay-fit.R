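test_that("kernel binning sums the clipped neighbourhood", {
  cfg <- tiny_config(n_bins = 16, photons_per_pixel_scale = 30, seed = 2L)
  ph <- two_roi_phantom(8, mono_species(1, 630), mono_species(2.5, 630))
  st <- render_stack(ph, cfg)
  expect_equal(binned_histogram(st, 3, 4, 1), st$counts[3, 4, ])
  # interior 5x5 kernel vs explicit double loop
  oracle <- rep(0, 16)
  for (i in 2:6) for (j in 2:6) oracle <- oracle + st$counts[i, j, ]
  expect_equal(binned_histogram(st, 4, 4, 5), oracle)
  # corner clips to the 9 in-bounds pixels
  oracle <- rep(0, 16)
  for (i in 1:3) for (j in 1:3) oracle <- oracle + st$counts[i, j, ]
  expect_equal(binned_histogram(st, 1, 1, 5), oracle)
  expect_error(binned_histogram(st, 0, 1, 5), "outside")
  expect_error(binned_histogram(st, 1, 1, 4), "odd")
})

test_that("noiseless mono-exponential fits recover the lifetime to 1e-6", {
  cfg <- tiny_config()
  h <- 5e4 * expected_pixel_profile(mono_mixture(tau = 2), cfg)
  f <- fit_multiexp(h, 1, cfg)
  expect_true(f$converged)
  expect_equal(f$lifetimes, 2, tolerance = 1e-6)
  expect_equal(f$t_m, 2, tolerance = 1e-6)
  expect_lt(f$chi_sq_red, 1e-10)
})

test_that("noiseless bi-exponential fits recover all four parameters", {
  cfg <- tiny_config()
  sp <- fluor_species("bi", c(0.8, 2.5), c(2, 1), 630)
  h <- 1e5 * expected_pixel_profile(list(list(species = sp, fraction = 1)), cfg)
  f <- fit_multiexp(h, 2, cfg)
  expect_true(f$converged)
  expect_equal(f$lifetimes, c(0.8, 2.5), tolerance = 1e-3)
  expect_equal(f$amplitudes[1] / f$amplitudes[2], 2, tolerance = 1e-3)
  # independent grid + linear-amplitude oracle: the fit must do at least
  # as well as the best point of a dense lifetime grid
  grid <- expand.grid(t1 = seq(0.5, 1.1, by = 0.05),
                      t2 = seq(2.0, 3.0, by = 0.05))
  w <- 1 / pmax(h, 1)
  gridsse <- apply(grid, 1, function(g) {
    b1 <- 1e5 * expected_pixel_profile(list(list(
      species = fluor_species("g1", g[["t1"]], 1, 630), fraction = 1)), cfg)
    b2 <- 1e5 * expected_pixel_profile(list(list(
      species = fluor_species("g2", g[["t2"]], 1, 630), fraction = 1)), cfg)
    co <- coef(lm(h ~ 0 + b1 + b2, weights = w))
    sum(w * (h - co[1] * b1 - co[2] * b2)^2)
  })
  expect_lte(sum(w * (h - fitted(f))^2), min(gridsse) + 1e-9)
})

test_that("a Poisson-sampled 3 ns decay at 1e6 photons fits back within 2%", {
  cfg <- tiny_config(seed = 9L)
  set.seed(9)
  h <- render_pixel(mono_mixture(tau = 3), 1e6, cfg)
  f <- fit_multiexp(h, 1, cfg)
  expect_true(f$converged)
  expect_equal(f$lifetimes, 3, tolerance = 0.02)
  expect_lt(abs(f$chi_sq_red - 1), 0.3)
})

test_that("fit results are canonical on every return path", {
  cfg <- tiny_config(seed = 21L)
  set.seed(21)
  sp <- fluor_species("bi", c(0.7, 2.2), c(1.5, 1), 630)
  for (i in 1:5) {
    h <- render_pixel(list(list(species = sp, fraction = 1)), 3e4, cfg)
    f <- suppressWarnings(fit_multiexp(h, 2, cfg))
    expect_lte(f$lifetimes[1], f$lifetimes[length(f$lifetimes)])
    expect_true(all(f$amplitudes >= 0))
    expect_gte(f$f1_pct, 0); expect_lte(f$f1_pct, 100)
    expect_gte(f$t_m, f$lifetimes[1] - 1e-9)
    expect_lte(f$t_m, f$lifetimes[length(f$lifetimes)] + 1e-9)
    expect_gte(f$it_m, f$t_m - 1e-9)
  }
  # degenerate two-component input collapses to mono with a warning
  hm <- 5e4 * expected_pixel_profile(mono_mixture(tau = 2), cfg)
  expect_warning(fm <- fit_multiexp(hm, 2, cfg), "degenerate|mono")
  expect_equal(fm$n_components, 1)
  expect_error(fit_multiexp(rep(0, cfg$n_bins), 1, cfg), "count floor")
})

test_that("sub-bin time-shift estimation is accurate and antisymmetric", {
  cfg <- tiny_config()
  h <- 1e5 * expected_pixel_profile(mono_mixture(tau = 2), cfg)
  expect_lt(abs(estimate_time_shift(h, h, cfg)), 0.5)            # ps
  dt_ps <- cfg$window / cfg$n_bins * 1000
  h4 <- fractional_shift(h, 4)
  expect_equal(estimate_time_shift(h4, h, cfg), 4 * dt_ps, tolerance = 1e-6)
  hf <- fractional_shift(h, 0.37)
  est <- estimate_time_shift(hf, h, cfg)
  expect_lt(abs(est - 0.37 * dt_ps), 0.1 * dt_ps)
  expect_equal(estimate_time_shift(h, hf, cfg), -est, tolerance = 0.02 * dt_ps)
  expect_error(estimate_time_shift(rep(0, cfg$n_bins), h, cfg), "all-zero")
})

test_that("time shifts convert to wavelengths by the fiber calibration", {
  cfg <- tiny_config(ref_wavelength = 600)
  expect_equal(shift_to_wavelength(200, cfg), 610)
  expect_equal(shift_to_wavelength(0, cfg), 600)
  expect_equal(shift_to_wavelength(500, cfg), 625)
  cfg0 <- tiny_config(dispersion_coeff = 0)
  expect_error(shift_to_wavelength(100, cfg0), "dispersion_coeff")
})

test_that("parameter images behave on uniform and two-ROI phantoms", {
  # "sum" of an empty stack is all zeros
  cfg <- tiny_config(n_bins = 32, photons_per_pixel_scale = 0, seed = 4L)
  ph <- scene_phantom(matrix(1L, 6, 6), list("1" = mono_mixture()))
  st0 <- render_stack(ph, cfg)
  expect_true(all(parameter_image(st0, "sum") == 0))

  # uniform phantom: fitted mean lifetime constant within CV < 5%
  cfg <- tiny_config(photons_per_pixel_scale = 4000, seed = 6L)
  ph <- scene_phantom(matrix(1L, 8, 8), list("1" = mono_mixture(tau = 2)))
  st <- render_stack(ph, cfg)
  img <- parameter_image(st, "t_m", kernel = 5, n_components = 1)
  expect_lt(sd(img) / mean(img), 0.05)

  # two-ROI phantom: decoded per-ROI peak wavelengths differ by the truth
  cfg2 <- tiny_config(photons_per_pixel_scale = 800, seed = 8L)
  ph2 <- two_roi_phantom(10, mono_species(2, 624), mono_species(2, 639))
  st2 <- render_stack(ph2, cfg2)
  img2 <- parameter_image(st2, "peak_wavelength", kernel = 5, count_floor = 100)
  pc <- paint_cells(ph2$label_image, img2)
  expect_equal(diff(pc$table$value), 15, tolerance = 1)
  expect_error(parameter_image(st2, "bogus"), "unknown parameter")
})

test_that("the Poisson-deviance MLE objective recovers lifetimes too", {
  cfg <- tiny_config(seed = 31L)
  set.seed(31)
  h <- render_pixel(mono_mixture(tau = 2.2), 2e5, cfg)
  f <- fit_multiexp(h, 1, cfg, mle = TRUE)
  expect_true(f$converged)
  expect_equal(f$lifetimes, 2.2, tolerance = 0.02)
})
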