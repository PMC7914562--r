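test_that("static anisotropy follows the closed forms", {
  expect_equal(static_anisotropy(1, 1, 1)$r_static, 0)
  expect_equal(static_anisotropy(1, 1, 1)$depol_ratio, 1 / 3)
  expect_equal(static_anisotropy(2, 1, 1)$r_static, 0.25)
  lim <- static_anisotropy(5, 0, 1)
  expect_equal(lim$r_static, 1)
  expect_equal(lim$depol_ratio, 0)
  # the two exported definitions are linked by r = 1 - 3 * depol_ratio
  x <- static_anisotropy(3.2, 1.1, 1.07)
  expect_equal(x$r_static, 1 - 3 * x$depol_ratio, tolerance = 1e-12)
  expect_error(static_anisotropy(0, 0, 1), "positive")
})

test_that("r(t) is zero for matched channels, NaN below the floor, grid-checked", {
  ip <- c(100, 80, 60, 3); iq <- c(100, 80, 60, 3)
  r <- anisotropy_decay(ip, iq, 1, count_floor = 10)
  expect_equal(r[1:3], rep(0, 3))
  expect_true(is.nan(r[4]))
  expect_error(anisotropy_decay(1:4, 1:5), "same bin grid")
})

test_that("r(t) is exactly invariant under I_perp * k with g / k", {
  set.seed(1)
  ip <- rpois(64, 500); iq <- rpois(64, 300)
  k <- 2.7
  expect_equal(anisotropy_decay(ip, iq, 0.9),
               anisotropy_decay(ip, iq * k, 0.9 / k), tolerance = 1e-12)
})

test_that("rendered single-species r(t) matches the generating closed form", {
  cfg <- tiny_config(dispersion_coeff = 0)
  sp <- fluor_species("rt", 2.5, 1, 630, r0 = 0.35, r_inf = 0.05, theta_rot = 2)
  mix <- list(list(species = sp, fraction = 1))
  cpar <- cfg; cpar$analyzer <- "parallel"
  cperp <- cfg; cperp$analyzer <- "perpendicular"
  ipar <- render_pixel(mix, 5e5, cpar, noise = FALSE)
  iperp <- render_pixel(mix, 5e5, cperp, noise = FALSE)
  r <- anisotropy_decay(ipar, iperp, cfg$g_factor, count_floor = 1e-6)
  te <- bin_centers(cfg) - cfg$irf_center
  sel <- te > 0.3 & te < 8          # clear of the IRF and of wraparound
  expect_lt(max(abs(r[sel] - (0.35 * exp(-te[sel] / 2) + 0.05))), 0.01)
})

test_that("the associated model nests the single-species fit exactly", {
  cfg <- tiny_config()
  te <- bin_centers(cfg) - cfg$irf_center
  I <- ifelse(te > 0, exp(-te / 2.5), 0) * 1e6
  rt <- 0.3 * exp(-te / 1.8) + 0.04
  ipar <- I * (1 + 2 * rt) / 3
  iperp <- I * (1 - rt) / 3
  fa <- fit_associated_anisotropy(ipar, iperp, 2.5, cfg, count_floor = 1)
  expect_true(fa$converged)
  expect_equal(fa$r0_fit, 0.3, tolerance = 1e-4)
  expect_equal(fa$theta_fit, 1.8, tolerance = 1e-4)
  expect_equal(fa$r_inf_fit, 0.04, tolerance = 1e-4)
})

test_that("two-species associated parameters are recovered from a noiseless curve", {
  cfg <- tiny_config()
  te <- bin_centers(cfg) - cfg$irf_center
  tau <- c(0.8, 2.5); theta <- c(0.4, 3); r0 <- c(0.35, 0.25); rinf <- 0.05
  a1 <- 0.6
  pop <- cbind(a1 * exp(-te / tau[1]), (1 - a1) * exp(-te / tau[2]))
  rt <- (pop[, 1] * (r0[1] * exp(-te / theta[1]) + rinf) +
         pop[, 2] * (r0[2] * exp(-te / theta[2]) + rinf)) / rowSums(pop)
  I <- ifelse(te > 0, rowSums(pop), 0) * 2e6
  ipar <- I * (1 + 2 * rt) / 3
  iperp <- I * (1 - rt) / 3
  fa <- fit_associated_anisotropy(ipar, iperp, tau, cfg, count_floor = 1)
  expect_true(fa$converged)
  expect_equal(fa$a1_rot, a1, tolerance = 1e-2)
  expect_equal(fa$r0_fit, r0, tolerance = 1e-2)
  expect_equal(fa$theta_fit, theta, tolerance = 3e-2)
  # long-time asymptote equals the shared residual anisotropy
  expect_equal(fa$r_inf_fit, rinf, tolerance = 1e-3)
  expect_equal(fa$theta_mean, a1 * theta[1] + (1 - a1) * theta[2],
               tolerance = 0.05)
})

test_that("forward-model round trip recovers anisotropy parameters within 5%", {
  cfg <- tiny_config(dispersion_coeff = 0, seed = 13L)
  sp <- fluor_species("rt", 2.5, 1, 630, r0 = 0.35, r_inf = 0.05, theta_rot = 2)
  mix <- list(list(species = sp, fraction = 1))
  cpar <- cfg; cpar$analyzer <- "parallel"
  cperp <- cfg; cperp$analyzer <- "perpendicular"
  set.seed(13)
  ipar <- render_pixel(mix, 5e5, cpar)
  iperp <- render_pixel(mix, 5e5, cperp)
  fa <- fit_associated_anisotropy(ipar, iperp, 2.5, cfg)
  expect_true(fa$converged)
  expect_equal(fa$r0_fit, 0.35, tolerance = 0.05)
  expect_equal(fa$theta_fit, 2, tolerance = 0.05)
  expect_equal(fa$r_inf_fit, 0.05, tolerance = 0.05)
})

test_that("the G factor can be calibrated from a reference tail", {
  cfg <- tiny_config(dispersion_coeff = 0, g_factor = 1.6)
  sp <- fluor_species("ref", 3, 1, 630, r0 = 0.3, r_inf = 0, theta_rot = 0.15)
  mix <- list(list(species = sp, fraction = 1))
  cpar <- cfg; cpar$analyzer <- "parallel"
  cperp <- cfg; cperp$analyzer <- "perpendicular"
  ipar <- render_pixel(mix, 1e6, cpar, noise = FALSE)
  iperp <- render_pixel(mix, 1e6, cperp, noise = FALSE)
  expect_equal(calibrate_g_factor(ipar, iperp, r_inf_ref = 0), 1.6,
               tolerance = 0.02)
})
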