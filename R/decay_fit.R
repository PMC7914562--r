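#' Kernel-binned histogram at a pixel
#'
#' Sums the histograms of the `kernel x kernel` neighbourhood centred on
#' `(x, y)`, truncated at the image borders — the usual spatial binning
#' applied before pixel-wise decay fitting (default 5 x 5).
#'
#' @param stack A `decay_stack`.
#' @param x,y Pixel indices (1-based).
#' @param kernel Odd neighbourhood size.
#' @return Numeric vector of length `n_bins`.
#' @export
binned_histogram <- function(stack, x, y, kernel = 5) {
  d <- dim(stack$counts)
  if (kernel %% 2 != 1 || kernel < 1) stop("kernel must be odd and >= 1")
  if (x < 1 || x > d[1] || y < 1 || y > d[2]) stop("pixel outside image")
  h <- (kernel - 1) / 2
  xs <- max(1, x - h):min(d[1], x + h)
  ys <- max(1, y - h):min(d[2], y + h)
  apply(stack$counts[xs, ys, , drop = FALSE], 3, sum)
}

# Model: circularly IRF-reconvolved multi-exponential plus flat offset,
# with an optional onset shift (ps) applied as a periodic fractional-bin
# displacement — the same operator the forward model uses.
decay_model_curve <- function(amplitudes, lifetimes, offset, shift_ps, config) {
  t <- bin_centers(config)
  d <- numeric(config$n_bins)
  for (i in seq_along(lifetimes)) d <- d + amplitudes[i] * exp(-t / lifetimes[i])
  if (shift_ps != 0)
    d <- fractional_shift(d, shift_ps / (bin_dt(config) * 1000))
  circular_convolve(d, gaussian_irf(config)) + offset
}

# Crude tail-slope lifetime estimate used to seed the optimizer.
tail_tau_estimate <- function(hist, config) {
  t <- bin_centers(config)
  pk <- which.max(hist)
  i0 <- min(pk + 3L, length(hist) - 4L)
  sel <- seq(i0, length(hist))
  y <- hist[sel]
  keep <- y > max(1, stats::quantile(y, 0.05))
  if (sum(keep) < 5) return(config$window / 5)
  fit <- stats::lm(log(y[keep]) ~ t[sel][keep])
  sl <- stats::coef(fit)[2]
  if (!is.finite(sl) || sl >= -1e-6) config$window / 5 else min(-1 / sl, config$window * 2)
}

#' Fit an IRF-reconvolved multi-exponential decay
#'
#' Weighted Levenberg–Marquardt least squares of
#' `IRF %*% (offset + sum_i a_i exp(-(t - shift)/tau_i))` against a TCSPC
#' histogram, with Poisson weights `1/max(counts, 1)`. A Poisson-deviance
#' maximum-likelihood objective is available via `mle = TRUE`. The result
#' is canonicalized (`t1 <= t2`) and carries the standard derived scalars:
#' fractional intensity of the short component
#' `f1_pct = 100 a1 t1 / (a1 t1 + a2 t2)`, amplitude-weighted mean
#' lifetime `t_m = sum(a tau)/sum(a)` and intensity-weighted mean lifetime
#' `it_m = sum(a tau^2)/sum(a tau)`.
#'
#' Non-convergence is reported through the `converged` flag, not an
#' error; a two-component fit collapsing to equal lifetimes (within 1%)
#' or to a vanishing component (intensity fraction below 1e-4) is refit
#' as mono-exponential with a warning.
#'
#' @param hist Numeric count histogram on the config's bin grid.
#' @param n_components 1 or 2 exponential components.
#' @param config An [instrument_config] (timing + IRF).
#' @param free_shift Also fit a time displacement of the decay onset (ps),
#'   e.g. a fiber dispersion shift.
#' @param count_floor Minimum total counts required to attempt a fit.
#' @param mle Use Poisson-deviance MLE instead of weighted least squares.
#' @return An object of class `decay_fit`.
#' @examples
#' cfg <- instrument_config()
#' sp <- fluor_species("mono", 2, 1, 630)
#' h <- render_pixel(list(list(species = sp, fraction = 1)), 1e5, cfg)
#' fit_multiexp(h, n_components = 1, config = cfg)
#' @export
fit_multiexp <- function(hist, n_components = 2, config,
                         free_shift = FALSE, count_floor = 100, mle = FALSE) {
  stopifnot(length(hist) == config$n_bins, n_components %in% 1:2)
  total <- sum(hist)
  if (total < count_floor)
    stop("total counts ", total, " below count floor ", count_floor)
  nc <- as.integer(n_components)

  tau2 <- tail_tau_estimate(hist, config)
  tau_start <- if (nc == 1) tau2 else c(tau2 / 3, tau2 * 1.2)
  off_start <- max(0, min(hist))
  # linear amplitude seed: scale unit-amplitude model to the data total
  unit <- decay_model_curve(rep(1, nc), tau_start, 0, 0, config)
  a_start <- rep(max(total - off_start * length(hist), 1) / sum(unit), nc) /
    if (nc == 2) 2 else 1

  par0 <- c(a_start, tau_start, off_start, if (free_shift) 0)
  lower <- c(rep(0, nc), rep(1e-3, nc), 0,
             if (free_shift) -config$window * 500)
  upper <- c(rep(Inf, nc), rep(config$window * 4, nc), max(hist) + 1,
             if (free_shift) config$window * 500)
  unpack <- function(p) list(a = p[1:nc], tau = p[(nc + 1):(2 * nc)],
                             off = p[2 * nc + 1],
                             sh = if (free_shift) p[2 * nc + 2] else 0)
  w <- 1 / pmax(hist, 1)
  resid_fn <- if (!mle) {
    function(p) { q <- unpack(p)
      sqrt(w) * (hist - decay_model_curve(q$a, q$tau, q$off, q$sh, config)) }
  } else {
    # square-rooted per-bin Poisson deviance keeps the LM framework
    function(p) { q <- unpack(p)
      mu <- pmax(decay_model_curve(q$a, q$tau, q$off, q$sh, config), 1e-12)
      dev <- 2 * (mu - hist + ifelse(hist > 0, hist * log(hist / mu), 0))
      sign(hist - mu) * sqrt(pmax(dev, 0)) }
  }
  fit <- try(minpack.lm::nls.lm(par0, lower, upper, resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
             silent = TRUE)
  converged <- !inherits(fit, "try-error") && fit$info %in% 1:4
  p <- if (inherits(fit, "try-error")) par0 else fit$par
  q <- unpack(p)

  degenerate <- nc == 2 && converged &&
    (abs(diff(q$tau)) / max(q$tau) < 0.01 ||
       min(q$a * q$tau) / sum(q$a * q$tau) < 1e-4)
  if (degenerate) {
    warning("two-component fit degenerate (t1 ~ t2 or a vanishing component); ",
            "collapsing to mono-exponential")
    out <- fit_multiexp(hist, 1, config, free_shift, count_floor, mle)
    out$collapsed <- TRUE
    return(out)
  }

  ord <- order(q$tau)
  tau <- q$tau[ord]; a <- q$a[ord]
  at <- a * tau
  fitted_curve <- decay_model_curve(a, tau, q$off, q$sh, config)
  dof <- max(config$n_bins - length(p), 1)
  structure(list(
    lifetimes = tau, amplitudes = a, offset = q$off, shift = q$sh,
    f1_pct = if (sum(at) > 0) 100 * at[1] / sum(at) else NA_real_,
    t_m = sum(at) / sum(a), it_m = sum(a * tau^2) / sum(at),
    chi_sq_red = sum(w * (hist - fitted_curve)^2) / dof,
    sum = total, n_components = nc, converged = converged,
    collapsed = FALSE, mle = mle, free_shift = free_shift,
    fitted = fitted_curve, data = hist, config = config
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d-exponential%s%s\n", x$n_components,
              if (x$free_shift) " + shift" else "",
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  t%d = %.4g ns   a%d = %.4g\n", i, x$lifetimes[i], i,
                x$amplitudes[i]))
  cat(sprintf("  t_m = %.4g ns, it_m = %.4g ns, f1 = %.1f%%\n",
              x$t_m, x$it_m, x$f1_pct))
  cat(sprintf("  offset = %.3g, shift = %.3g ps, chi2_red = %.3g, sum = %.4g\n",
              x$offset, x$shift, x$chi_sq_red, x$sum))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.decay_fit <- function(object, ...) {
  nc <- object$n_components
  stats::setNames(
    c(object$amplitudes, object$lifetimes, object$offset, object$shift),
    c(paste0("a", seq_len(nc)), paste0("t", seq_len(nc)), "offset", "shift"))
}

#' @export
fitted.decay_fit <- function(object, ...) object$fitted

#' @export
residuals.decay_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$data - object$fitted
  if (type == "weighted") r / sqrt(pmax(object$data, 1)) else r
}

#' @export
plot.decay_fit <- function(x, ...) {
  t <- bin_centers(x$config)
  graphics::plot(t, x$data, type = "s", log = "y", xlab = "time (ns)",
                 ylab = "counts", col = "grey40",
                 main = sprintf("%d-exp fit, t_m = %.3g ns", x$n_components, x$t_m),
                 ...)
  graphics::lines(t, pmax(x$fitted, .Machine$double.xmin), col = "red3", lwd = 2)
  invisible(x)
}

#' Sub-bin time shift between two histograms
#'
#' Lag maximizing the circular normalized cross-correlation, refined to
#' sub-bin precision by Fourier upsampling of the correlation followed by
#' parabolic interpolation around its peak. Antisymmetric:
#' `shift(a, b) = -shift(b, a)` within one interpolation step.
#'
#' @param hist Histogram whose delay is sought.
#' @param reference Zero-shift reference histogram on the same bin grid
#'   (e.g. the IRF-reconvolved decay at the reference wavelength, or a
#'   reference ROI's mean histogram).
#' @param config An [instrument_config] (for the bin width).
#' @param upsample Fourier upsampling factor for the correlation grid.
#' @return Shift in ps (positive = `hist` delayed w.r.t. `reference`).
#' @export
estimate_time_shift <- function(hist, reference, config, upsample = 16) {
  n <- length(hist)
  stopifnot(n == length(reference), n == config$n_bins)
  if (sum(hist) == 0 || sum(reference) == 0)
    stop("cannot estimate a shift from an all-zero histogram")
  h <- hist / sqrt(sum(hist^2)); r <- reference / sqrt(sum(reference^2))
  cc <- stats::fft(h) * Conj(stats::fft(r))
  m <- n * upsample
  pad <- complex(m)
  half <- n %/% 2
  pad[1:half] <- cc[1:half]
  pad[(m - half + 1):m] <- cc[(n - half + 1):n]
  c2 <- Re(stats::fft(pad, inverse = TRUE))
  i <- which.max(c2)
  ii <- c((i - 2) %% m + 1, i, i %% m + 1)
  y <- c2[ii]
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y[1] - y[3]) / denom
  lag <- (i - 1 + delta)
  if (lag > m / 2) lag <- lag - m
  lag / upsample * bin_dt(config) * 1000
}

#' Convert a decoded time shift to an emission wavelength
#'
#' Inverts the fiber dispersion calibration:
#' `wavelength = ref_wavelength + shift / dispersion_coeff`
#' (200 ps at 20 ps/nm = +10 nm).
#'
#' @param shift_ps Time shift (ps).
#' @param config An [instrument_config] with `dispersion_coeff > 0`.
#' @return Wavelength in nm.
#' @export
shift_to_wavelength <- function(shift_ps, config) {
  if (config$dispersion_coeff <= 0)
    stop("dispersion_coeff must be > 0 to decode wavelengths")
  config$ref_wavelength + shift_ps / config$dispersion_coeff
}

#' Per-ROI summed histograms
#'
#' @param stack A `decay_stack`.
#' @param mask Integer label matrix matching the stack's image size;
#'   ROI id 0 (background) is skipped.
#' @return Matrix with one row per ROI (rownames = ids) of summed
#'   histograms; attribute `"n_pixels"` carries the ROI sizes.
#' @export
roi_histograms <- function(stack, mask) {
  d <- dim(stack$counts)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == d[1:2])) stop("mask shape does not match stack")
  ids <- sort(setdiff(unique(as.vector(mask)), 0L))
  flat <- matrix(stack$counts, d[1] * d[2], d[3])
  out <- t(vapply(ids, function(id)
    colSums(flat[as.vector(mask) == id, , drop = FALSE]), numeric(d[3])))
  rownames(out) <- ids
  attr(out, "n_pixels") <- vapply(ids, function(id) sum(mask == id), numeric(1))
  out
}

#' Pixel-wise scalar parameter image
#'
#' Applies kernel-binned decay fitting or shift decoding at every pixel
#' and returns a scalar map. Pixels whose binned histogram falls below
#' the count floor are NaN and are excluded from all downstream means.
#'
#' @param stack A `decay_stack`.
#' @param parameter One of `"t_m"`, `"it_m"`, `"t1"`, `"t2"`, `"f1_pct"`,
#'   `"shift"`, `"peak_wavelength"`, `"sum"`, `"offset"`, `"chi_sq_red"`.
#' @param kernel Odd binning kernel passed to [binned_histogram()].
#' @param config Defaults to the stack's own configuration.
#' @param n_components Components for fit-derived parameters.
#' @param count_floor Minimum binned counts; below it the pixel is NaN.
#' @param reference Zero-shift reference histogram for `"shift"` /
#'   `"peak_wavelength"`; defaults to the image-mean histogram, so decoded
#'   wavelengths are relative to the image average sitting at
#'   `ref_wavelength`.
#' @return Numeric matrix (X x Y).
#' @export
parameter_image <- function(stack, parameter, kernel = 5,
                            config = stack$config, n_components = 2,
                            count_floor = 100, reference = NULL) {
  pars <- c("t_m", "it_m", "t1", "t2", "f1_pct", "shift", "peak_wavelength",
            "sum", "offset", "chi_sq_red")
  if (!parameter %in% pars)
    stop("unknown parameter '", parameter, "'")
  d <- dim(stack$counts)
  out <- matrix(NaN, d[1], d[2])
  if (parameter == "sum") {
    return(apply(stack$counts, c(1, 2), sum))
  }
  needs_fit <- parameter %in% c("t_m", "it_m", "t1", "t2", "f1_pct",
                                "offset", "chi_sq_red")
  if (!needs_fit && is.null(reference))
    reference <- apply(stack$counts, 3, sum)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    h <- binned_histogram(stack, x, y, kernel)
    if (sum(h) < count_floor) next
    out[x, y] <- if (needs_fit) {
      f <- fit_multiexp(h, n_components, config, count_floor = count_floor)
      switch(parameter,
             t_m = f$t_m, it_m = f$it_m, t1 = f$lifetimes[1],
             t2 = f$lifetimes[min(2, length(f$lifetimes))],
             f1_pct = f$f1_pct, offset = f$offset, chi_sq_red = f$chi_sq_red)
    } else {
      s <- estimate_time_shift(h, reference, config)
      if (parameter == "shift") s else shift_to_wavelength(s, config)
    }
  }
  out
}
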