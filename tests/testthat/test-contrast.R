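test_that("paint_cells averages ROI pixels and drops empty ROIs", {
  mask <- matrix(c(1, 1, 2, 2, 0, 3), 2, 3)
  img <- matrix(c(4, 6, 1, 3, 9, NaN), 2, 3)
  out <- paint_cells(mask, img)
  # explicit per-ROI loop oracle
  expect_equal(out$table$roi, c(1, 2))
  expect_equal(out$table$value, c(mean(c(4, 6)), mean(c(1, 3))))
  expect_true(all(is.nan(out$painted[mask == 0])))
  expect_equal(out$painted[mask == 1], rep(5, 2))
  # constant single-ROI image
  one <- paint_cells(matrix(1L, 3, 3), matrix(7, 3, 3))
  expect_equal(one$table$value, 7)
  expect_true(all(one$painted == 7))
  expect_error(paint_cells(matrix(1L, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("phasor transform hits closed-form and fine-grid oracle values", {
  cfg <- tiny_config()
  cal <- phasor_calibration(reference_histogram(cfg, 2), 2, cfg)
  # zero-lifetime limit: a delta decay keeps unit modulation and sits at
  # (1, 0) up to the half-bin phase of the bin-centre time convention
  delta <- c(1, rep(0, cfg$n_bins - 1))
  zd <- with(phasor_transform(delta, 1, cfg),
             complex(real = g, imaginary = s))
  omega <- 2 * pi / cfg$window
  dt <- cfg$window / cfg$n_bins
  expect_equal(Mod(zd), 1, tolerance = 1e-12)
  expect_lte(abs(Arg(zd)), omega * dt / 2 + 1e-9)
  # the calibrated measured zero-lifetime emitter (the IRF itself) shows the
  # same half-bin-bounded proximity to (1, 0)
  zi <- with(phasor_transform(gaussian_irf(cfg), 1, cfg, cal),
             complex(real = g, imaginary = s))
  expect_equal(Mod(zi), 1, tolerance = 1e-4)
  expect_lte(abs(Arg(zi)), omega * dt / 2 + 1e-4)
  # calibrated mono-exponential with omega * tau = 1 lands at (0.5, 0.5)
  tau1 <- cfg$window / (2 * pi)
  p1 <- phasor_transform(reference_histogram(cfg, tau1), 1, cfg, cal)
  expect_equal(p1$g, 0.5, tolerance = 1e-3)
  expect_equal(p1$s, 0.5, tolerance = 1e-3)
  # uncalibrated discrete transform vs 1e4-point quadrature oracle
  tc <- bin_centers(cfg)
  h <- exp(-tc / 2)
  z <- phasor_transform(h, 1, cfg)
  tf <- (seq_len(10000) - 0.5) * cfg$window / 10000
  hf <- exp(-tf / 2)
  w <- 2 * pi / cfg$window
  zf <- sum(hf * exp(1i * w * tf)) / sum(hf)
  expect_lt(abs(complex(real = z$g, imaginary = z$s) - zf), 1e-4)
  expect_error(phasor_transform(rep(0, cfg$n_bins), 1, cfg), "zero-count")
})

test_that("calibrated mono-exponentials sit on the universal semicircle, phase ordered", {
  cfg <- tiny_config()
  cal <- phasor_calibration(reference_histogram(cfg, 2), 2, cfg)
  taus <- c(0.5, 1, 2, 3)
  hs <- t(vapply(taus, function(tau) reference_histogram(cfg, tau),
                 numeric(cfg$n_bins)))
  ph <- phasor_transform(hs, 1, cfg, cal)
  resid <- abs(sqrt((ph$g - 0.5)^2 + ph$s^2) - 0.5)
  expect_lt(max(resid), 1e-3)
  phase <- atan2(ph$s, ph$g)
  expect_true(all(diff(phase) > 0))
})

test_that("a pure time shift rotates the phasor by exactly n*omega*delta", {
  cfg <- tiny_config()
  h <- reference_histogram(cfg, 1.3)
  z0 <- with(phasor_transform(h, 1, cfg), complex(real = g, imaginary = s))
  dt <- cfg$window / cfg$n_bins
  for (k in c(1, 4, 11)) {                       # integer shifts: exact
    zk <- with(phasor_transform(fractional_shift(h, k), 1, cfg),
               complex(real = g, imaginary = s))
    expect_equal(Arg(zk / z0), 2 * pi / cfg$window * k * dt, tolerance = 1e-12)
  }
  zf <- with(phasor_transform(fractional_shift(h, 2.4), 1, cfg),
             complex(real = g, imaginary = s))
  expect_equal(Arg(zf / z0), 2 * pi / cfg$window * 2.4 * dt, tolerance = 1e-4)
})

test_that("lambda-tau populations land in disjoint regions with correct occupancy", {
  set.seed(11)
  tab <- data.frame(roi = 1:6,
                    peak_wavelength = c(640, 642, 641, 618, 616, 617),
                    t_m = c(1.0, 1.1, 0.9, 2.4, 2.5, 2.6))
  edges <- list(lambda = c(610, 630, 650), tau = c(0.5, 1.75, 3))
  lt <- lambda_tau(tab, bins = edges)
  expect_equal(lt$counts[2, 1], 3)     # red-shifted short-lifetime block
  expect_equal(lt$counts[1, 2], 3)     # bluer long-lifetime block
  expect_equal(sum(lt$counts), 6)
  perm <- lambda_tau(tab[sample(6), ], bins = edges)
  expect_equal(perm$counts, lt$counts)
  single <- lambda_tau(tab[1, c("roi", "peak_wavelength", "t_m")], bins = 4)
  expect_equal(sum(single$counts > 0), 1)
  expect_error(lambda_tau(data.frame(a = 1:3)), "needs a")
})

test_that("standardization yields exact z-scores and is idempotent", {
  tab <- data.frame(roi = 1:3, v = c(1, 2, 3))
  z <- standardize_table(tab, "v")
  expect_equal(z$v, c(-1, 0, 1))
  expect_equal(standardize_table(z, "v")$v, z$v, tolerance = 1e-12)
  set.seed(2)
  big <- data.frame(a = rnorm(40, 5, 3), b = runif(40))
  zb <- standardize_table(big)
  expect_equal(unname(colMeans(zb)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zb, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_warning(zc <- standardize_table(data.frame(k = rep(4, 5))), "constant")
  expect_equal(zc$k, rep(0, 5))
})

test_that("PCA contrast explains rank structure and recovers planted subspaces", {
  # two perfectly correlated columns: PC1 carries everything
  tab <- data.frame(x = c(-1.2, 0.3, 0.9, -0.4, 0.4),
                    y = 2 * c(-1.2, 0.3, 0.9, -0.4, 0.4))
  pc <- pca_contrast(tab, 2)
  expect_equal(pc$explained_variance_ratio[1], 1, tolerance = 1e-12)
  # isotropic noise: no dominant axis (p = 4, n = 1000)
  set.seed(3)
  noise <- as.data.frame(matrix(rnorm(4000), 1000, 4))
  pn <- pca_contrast(standardize_table(noise), 4)
  expect_true(all(pn$explained_variance_ratio > 0.15 &
                  pn$explained_variance_ratio < 0.35))
  expect_true(all(diff(pn$explained_variance_ratio) <= 1e-12))
  # planted rank-2 structure + small noise: subspace within 5 degrees
  set.seed(4)
  B <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  S <- matrix(rnorm(200 * 2, sd = c(3, 2)), 200, 2, byrow = TRUE)
  X <- S %*% t(B) + matrix(rnorm(1200, sd = 0.05), 200, 6)
  pp <- pca_contrast(as.data.frame(X), 2)
  ang <- acos(pmin(svd(crossprod(B, pp$loadings))$d, 1)) * 180 / pi
  expect_lt(max(ang), 5)
  # sign convention: largest-magnitude loading entry positive
  expect_true(all(apply(pp$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_contrast(tab, 3), "more components")
})

test_that("sparse PCA shrinks loadings while keeping the dominant axis", {
  set.seed(5)
  n <- 120
  lead <- rnorm(n, sd = 3)
  tab <- data.frame(a = lead + rnorm(n, sd = 0.1),
                    b = lead + rnorm(n, sd = 0.1),
                    c = rnorm(n), d = rnorm(n), e = rnorm(n))
  z <- standardize_table(tab)
  sp <- pca_contrast(z, 2, sparse = TRUE, sumabsv = 1.2)
  expect_true(sum(abs(sp$loadings[, 1]) < 1e-6) >= 2)  # noise columns zeroed
  expect_gte(max(abs(sp$loadings[c("a", "b"), 1])), 0.5)
  expect_true(all(diff(sp$explained_variance_ratio) <= 1e-9))
})

test_that("k-means silhouette selection separates blobs and rejects blur", {
  set.seed(6)
  blobs <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
                 matrix(rnorm(60, 3, 0.05), 30, 2))
  cl <- cluster_separation(blobs, 2:4, seed = 7)
  expect_equal(cl$best_k, 2)
  expect_gt(cl$silhouette["2"], 0.9)
  one <- matrix(rnorm(160), 80, 2)
  cl1 <- cluster_separation(one, 2:4, seed = 7)
  expect_true(all(cl1$silhouette < 0.5))
  # permutation invariance up to relabelling
  perm <- sample(nrow(blobs))
  clp <- cluster_separation(blobs[perm, ], 2, seed = 7)
  agree <- table(cl$labels[perm], clp$labels)
  expect_equal(sum(apply(agree, 1, max)), nrow(blobs))
  expect_error(cluster_separation(blobs, 1:3, seed = 1), "k >= 2")
  expect_error(cluster_separation(blobs[1:3, ], 2:5, seed = 1), "at least")
})
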