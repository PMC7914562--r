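#' Paint per-ROI means of a parameter image
#'
#' Computes the mean of each ROI's non-NaN pixels and fills the ROI with
#' it. Background (id 0) stays NaN; ROIs with no valid pixel are omitted
#' from the table (unsegmented/under-count regions drop out of all
#' downstream statistics).
#'
#' @param label_mask Integer ROI matrix (0 = background).
#' @param parameter_image Numeric matrix of the same shape (NaN = invalid).
#' @return List with `table` (data.frame `roi`, `value`) and `painted`
#'   (matrix with each ROI filled by its mean).
#' @export
paint_cells <- function(label_mask, parameter_image) {
  label_mask <- as.matrix(label_mask)
  parameter_image <- as.matrix(parameter_image)
  if (!all(dim(label_mask) == dim(parameter_image)))
    stop("mask and image shapes differ")
  ids <- sort(setdiff(unique(as.vector(label_mask)), 0L))
  painted <- matrix(NaN, nrow(label_mask), ncol(label_mask))
  vals <- numeric(0); keep <- integer(0)
  for (id in ids) {
    v <- parameter_image[label_mask == id]
    v <- v[is.finite(v)]
    if (length(v) == 0) next
    m <- mean(v)
    painted[label_mask == id] <- m
    keep <- c(keep, id); vals <- c(vals, m)
  }
  list(table = data.frame(roi = keep, value = vals), painted = painted)
}

# Theoretical phasor of a mono-exponential lifetime at harmonic n:
# z = 1 / (1 - i n w tau), i.e. g = 1/(1+(nwt)^2), s = nwt/(1+(nwt)^2).
phasor_theory <- function(tau, omega, harmonic = 1) {
  1 / (1 - 1i * harmonic * omega * tau)
}

#' Phasor calibration from a mono-exponential reference
#'
#' Computes the phase/modulation correction that maps a measured
#' reference histogram of known lifetime onto its theoretical point on
#' the universal semicircle; the same complex factor is then applied to
#' all data, removing the instrument response (under the periodic
#' convolution model the IRF is an exactly multiplicative factor).
#'
#' @param reference Measured histogram of the reference.
#' @param tau_ref Known mono-exponential lifetime of the reference (ns).
#' @param config An [instrument_config].
#' @param harmonic Phasor harmonic.
#' @return List with the complex `factor` and its `phase` / `modulation`.
#' @export
phasor_calibration <- function(reference, tau_ref, config, harmonic = 1) {
  omega <- 2 * pi / config$window
  zr <- phasor_raw(reference, harmonic, config)
  zt <- phasor_theory(tau_ref, omega, harmonic)
  f <- zt / zr
  list(factor = f, phase = Arg(f), modulation = Mod(f),
       tau_ref = tau_ref, harmonic = harmonic)
}

# Uncalibrated complex phasor of one histogram (bin centers).
phasor_raw <- function(hist, harmonic, config) {
  tot <- sum(hist)
  if (tot <= 0) stop("cannot transform a zero-count histogram")
  tc <- bin_centers(config)
  omega <- 2 * pi / config$window
  sum(hist * exp(1i * harmonic * omega * tc)) / tot
}

#' Phasor transform of decay histograms
#'
#' Fit-free Fourier projection
#' \deqn{g = \sum_k I_k \cos(n\omega t_k)/\sum_k I_k,\qquad
#'       s = \sum_k I_k \sin(n\omega t_k)/\sum_k I_k}
#' with \eqn{\omega = 2\pi/\mathrm{window}} and bin-centre times. Both the
#' fitted lifetime and any fiber dispersion shift move the phasor: a pure
#' time shift `delta` rotates it by exactly `n * omega * delta` (Fourier
#' shift theorem), which is what makes the transform sensitive to the
#' spectrally coded delay.
#'
#' @param hist A histogram vector, or a matrix of histograms (one row per
#'   ROI/pixel).
#' @param harmonic Harmonic number n (default 1).
#' @param config An [instrument_config].
#' @param calibration Optional result of [phasor_calibration()].
#' @return A data.frame of class `phasor_set` with columns `g`, `s` (and
#'   rownames carried over), attributes `harmonic`, `omega`,
#'   `calibrated`.
#' @export
phasor_transform <- function(hist, harmonic = 1, config, calibration = NULL) {
  m <- if (is.matrix(hist)) hist else matrix(hist, nrow = 1)
  z <- apply(m, 1, phasor_raw, harmonic = harmonic, config = config)
  if (!is.null(calibration)) z <- z * calibration$factor
  out <- data.frame(g = Re(z), s = Im(z))
  rownames(out) <- rownames(m)
  structure(out, harmonic = harmonic, omega = 2 * pi / config$window,
            calibrated = !is.null(calibration),
            class = c("phasor_set", "data.frame"))
}

#' @export
plot.phasor_set <- function(x, ...) {
  th <- seq(0, pi, length.out = 200)
  graphics::plot(0.5 + 0.5 * cos(th), 0.5 * sin(th), type = "l", lty = 2,
                 col = "grey50", xlab = "g", ylab = "s", asp = 1,
                 xlim = c(0, 1), ylim = c(0, 0.6),
                 main = "phasor plot")
  graphics::points(x$g, x$s, ...)
  invisible(x)
}

#' Build a lambda-tau map
#'
#' 2D histogram of decoded spectral peak (wavelength or raw time shift)
#' against mean lifetime, the contrast space in which anthocyanin-rich
#' and -poor cells separate; also keeps the per-ROI scatter coordinates.
#'
#' @param table Data frame with a `peak_wavelength` (or `peak_shift`)
#'   column and a lifetime column (`t_m` preferred, else `it_m`).
#' @param bins Number of bins per axis, or a list
#'   `list(lambda = edges, tau = edges)` of explicit break points.
#' @return Object of class `lambda_tau_map`: `counts` matrix,
#'   `lambda_edges`, `tau_edges`, and `scatter` (the input coordinates).
#' @export
lambda_tau <- function(table, bins = 16) {
  lam_col <- intersect(c("peak_wavelength", "peak_shift"), names(table))[1]
  tau_col <- intersect(c("t_m", "it_m"), names(table))[1]
  if (is.na(lam_col) || is.na(tau_col))
    stop("table needs a peak_wavelength/peak_shift and a t_m/it_m column")
  lam <- table[[lam_col]]; tau <- table[[tau_col]]
  ok <- is.finite(lam) & is.finite(tau)
  lam <- lam[ok]; tau <- tau[ok]
  if (is.list(bins)) {
    le <- bins$lambda; te <- bins$tau
  } else {
    pad <- function(v) { r <- range(v); if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      seq(r[1] - 1e-9 * max(1, abs(r[1])), r[2] + 1e-9 * max(1, abs(r[2])),
          length.out = bins + 1) }
    le <- pad(lam); te <- pad(tau)
  }
  ci <- cut(lam, le, include.lowest = TRUE)
  cj <- cut(tau, te, include.lowest = TRUE)
  counts <- table(ci, cj)
  structure(list(counts = unclass(counts), lambda_edges = le, tau_edges = te,
                 scatter = data.frame(lambda = lam, tau = tau,
                                      roi = if ("roi" %in% names(table))
                                        table$roi[ok] else seq_along(lam)),
                 lambda_axis = lam_col, tau_axis = tau_col),
            class = "lambda_tau_map")
}

#' @export
print.lambda_tau_map <- function(x, ...) {
  cat(sprintf("<lambda_tau_map> %d points, %d x %d bins (%s vs %s)\n",
              nrow(x$scatter), length(x$lambda_edges) - 1,
              length(x$tau_edges) - 1, x$lambda_axis, x$tau_axis))
  invisible(x)
}

#' @export
plot.lambda_tau_map <- function(x, ...) {
  graphics::plot(x$scatter$lambda, x$scatter$tau,
                 xlab = x$lambda_axis, ylab = paste(x$tau_axis, "(ns)"),
                 main = "lambda-tau map", ...)
  invisible(x)
}

#' Z-score columns of a parameter table
#'
#' Each selected column is centred to mean 0 and scaled to sample SD 1;
#' constant columns become all zeros with a warning.
#'
#' @param table A data.frame.
#' @param columns Columns to standardize (default: all numeric except
#'   `roi`).
#' @return The table with those columns standardized.
#' @export
standardize_table <- function(table, columns = NULL) {
  if (nrow(table) < 2) stop("need at least two rows to standardize")
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       "roi")
  for (cn in columns) {
    v <- table[[cn]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("column '", cn, "' is constant; standardized to zeros")
      table[[cn]] <- rep(0, length(v))
    } else table[[cn]] <- (v - mean(v)) / s
  }
  table
}

# Rank-1 L1-penalized power iteration (soft-thresholded), deflated per
# component — a lightweight sparse-PCA in the penalized matrix
# decomposition style.
sparse_pc <- function(X, n_components, sumabsv) {
  p <- ncol(X)
  V <- matrix(0, p, n_components)
  U <- matrix(0, nrow(X), n_components)
  dvals <- numeric(n_components)
  soft <- function(x, c) sign(x) * pmax(abs(x) - c, 0)
  l1proj <- function(v) {
    # binary search the threshold so that ||v||_1 <= sumabsv with ||v||_2 = 1
    vn <- v / sqrt(sum(v^2))
    if (sum(abs(vn)) <= sumabsv) return(vn)
    lo <- 0; hi <- max(abs(v))
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      w <- soft(v, mid)
      if (sum(w^2) == 0) { hi <- mid; next }
      w <- w / sqrt(sum(w^2))
      if (sum(abs(w)) > sumabsv) lo <- mid else hi <- mid
    }
    w <- soft(v, hi); w / sqrt(sum(w^2))
  }
  R <- X
  for (k in seq_len(n_components)) {
    v <- svd(R, nu = 0, nv = 1)$v[, 1]
    for (it in 1:200) {
      u <- R %*% v; u <- u / max(sqrt(sum(u^2)), 1e-12)
      v_new <- l1proj(drop(crossprod(R, u)))
      if (sum((v_new - v)^2) < 1e-12) { v <- v_new; break }
      v <- v_new
    }
    d <- drop(crossprod(u, R %*% v))
    U[, k] <- u; V[, k] <- v; dvals[k] <- d
    R <- R - d * tcrossprod(u, v)
  }
  list(scores = sweep(U, 2, dvals, `*`), loadings = V, d = dvals)
}

#' Principal-component contrast of a cell parameter table
#'
#' Ordinary PCA (via `prcomp`) of an already standardized table, or an
#' L1-penalized sparse variant. Loadings follow the sign convention that
#' each vector's largest-magnitude entry is positive; explained-variance
#' ratios are non-increasing.
#'
#' @param table Standardized data.frame (see [standardize_table()]).
#' @param n_components Number of components (default 2).
#' @param sparse Use the sparse (soft-thresholded) variant.
#' @param sumabsv Sparsity budget: bound on the L1 norm of each unit-L2
#'   loading vector (between 1 and sqrt(p); smaller = sparser).
#' @param columns Columns to use (default all numeric except `roi`).
#' @return List of class `hdim_pca`: `scores` (rows = ROIs), `loadings`,
#'   `explained_variance_ratio`.
#' @export
pca_contrast <- function(table, n_components = 2, sparse = FALSE,
                         sumabsv = NULL, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       "roi")
  X <- as.matrix(table[, columns, drop = FALSE])
  if (n_components > ncol(X))
    stop("more components than columns")
  if (nrow(X) < n_components) stop("need at least as many rows as components")
  total_var <- sum(apply(X, 2, stats::var))
  if (!sparse) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(n_components), drop = FALSE]
    loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    evr <- evr[seq_len(n_components)]
  } else {
    if (is.null(sumabsv)) sumabsv <- sqrt(ncol(X)) * 0.7
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sp <- sparse_pc(Xc, n_components, sumabsv)
    scores <- sp$scores
    loadings <- sp$loadings
    evr <- apply(scores, 2, stats::var) / total_var
    dimnames(loadings) <- list(columns, paste0("PC", seq_len(n_components)))
    colnames(scores) <- paste0("PC", seq_len(n_components))
  }
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- if ("roi" %in% names(table)) table$roi else rownames(table)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr, sparse = sparse),
            class = "hdim_pca")
}

#' @export
print.hdim_pca <- function(x, ...) {
  cat(sprintf("<hdim_pca>%s %d components, explained variance ratio: %s\n",
              if (x$sparse) " sparse," else "", ncol(x$scores),
              paste(signif(x$explained_variance_ratio, 3), collapse = ", ")))
  invisible(x)
}

#' k-means cluster separation with silhouette selection
#'
#' Runs k-means (k-means++-style multiple restarts via `nstart`) for each
#' k in `k_range`, scores each clustering by its mean Euclidean
#' silhouette, and returns the k maximizing it (ties broken by lower
#' within-cluster inertia, then smaller k). Deterministic given `seed`.
#'
#' @param points Numeric matrix or data.frame of coordinates (per-ROI
#'   phasor (g, s), PC scores, or lambda-tau positions).
#' @param k_range Candidate cluster counts (all >= 2).
#' @param seed Integer RNG seed.
#' @param nstart Restarts per k.
#' @return List with `best_k`, `labels` (for `best_k`), `silhouette`
#'   (named vector over k), `inertia` (within-cluster sum of squares).
#' @export
cluster_separation <- function(points, k_range = 2:6, seed = 1, nstart = 10) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (any(k_range < 2)) stop("k_range must contain only k >= 2")
  if (nrow(X) < max(k_range) + 1)
    stop("need at least max(k_range) + 1 points")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  d <- stats::dist(X)
  sil <- inertia <- stats::setNames(numeric(length(k_range)), k_range)
  labs <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed)
    km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    inertia[i] <- km$tot.withinss
    labs[[i]] <- km$cluster
  }
  ord <- order(-sil, inertia, k_range)
  best <- ord[1]
  list(best_k = k_range[best], labels = labs[[best]], silhouette = sil,
       inertia = inertia)
}
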