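#' Deformation vector between two conformations
#'
#' The 3N-dimensional difference Delta q = q_b - q_a, optionally after
#' Kabsch superposition of b onto a. This is the simplest description of a
#' conformational change, and the vector along which a morph interpolates.
#'
#' @param a,b [nodeset()] objects with equal N.
#' @param superpose superpose b onto a first (default TRUE).
#' @return an object of class `deformation_vector` with fields `values`
#'   (length 3N, Angstrom), `source`, `target`.
#' @export
deformation_vector <- function(a, b, superpose = TRUE) {
  if (n_nodes(a) != n_nodes(b)) stop("node counts differ")
  bb <- if (superpose) kabsch_superpose(b, a)$nodes else b
  structure(list(values = to_coordinate_vector(bb) - to_coordinate_vector(a),
                 source = a$labels, target = bb$labels),
            class = "deformation_vector")
}

#' Linear morph between two conformations
#'
#' Frame t (t = 0 ... n_frames-1) is a + (t/(n_frames-1)) * Delta q, so the
#' first frame is a and the last is b (after superposition when enabled).
#' Linear interpolation of coarse-grained nodes can of course pass through
#' conformations that are unphysical at atomic resolution; the morph is a
#' visualization of the deformation direction, not a transition path.
#'
#' @param a,b [nodeset()] objects with equal N.
#' @param n_frames number of frames, >= 2.
#' @param superpose superpose b onto a first (default TRUE).
#' @return a [gd_ensemble()] with M = n_frames.
#' @export
morph <- function(a, b, n_frames = 11L, superpose = TRUE) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop("a morph needs at least 2 frames")
  dv <- deformation_vector(a, b, superpose = superpose)
  qa <- to_coordinate_vector(a)
  n <- n_nodes(a)
  coords <- array(NA_real_, c(n_frames, n, 3))
  for (t in seq_len(n_frames)) {
    frac <- (t - 1) / (n_frames - 1)
    coords[t, , ] <- coordinate_matrix(qa + frac * dv$values)
  }
  gd_ensemble(coords, a$labels)
}

#' Positional covariance matrix of a superposed ensemble
#'
#' C = (1/M) sum_m Delta q_m Delta q_m^T with deviations taken about the
#' ensemble mean, over common-core columns only. The ensemble is assumed
#' already superposed (run [iterative_superpose()] first); the 1/M
#' normalization treats C as the average of the deviation outer products
#' (switch to 1/(M-1) with `unbiased = TRUE`).
#'
#' @param ensemble a superposed [gd_ensemble()] with M >= 2.
#' @param unbiased use 1/(M-1) instead of 1/M.
#' @return object of class `covariance_matrix` with fields `matrix`
#'   (3Nc x 3Nc over the Nc core columns), `mean` (a [nodeset()]), `M`.
#' @export
ensemble_covariance <- function(ensemble, unbiased = FALSE) {
  m <- n_members(ensemble)
  if (m < 2) stop("covariance needs M >= 2")
  core <- core_columns(ensemble)
  Q <- t(vapply(seq_len(m), function(i)
    to_coordinate_vector(ensemble$coords[i, core, , drop = TRUE]),
    numeric(3 * sum(core))))
  mu <- colMeans(Q)
  D <- sweep(Q, 2, mu)
  denom <- if (unbiased) m - 1 else m
  C <- crossprod(D) / denom
  structure(list(matrix = C,
                 mean = nodeset(coordinate_matrix(mu),
                                ensemble$labels[core, , drop = FALSE]),
                 M = m), class = "covariance_matrix")
}

#' Principal component analysis of an ensemble covariance
#'
#' Eigendecomposition of the positional covariance: eigenvectors p_k are
#' the principal components (directions of concerted motion away from the
#' mean), eigenvalues sigma_k their variance contributions, sorted
#' descending. At most min(3N, M-1) components are non-zero; when rigid
#' motions were removed by superposition the effective count drops by a
#' further ~6.
#'
#' @param cov a `covariance_matrix` from [ensemble_covariance()].
#' @param n number of components to retain (default: all non-zero).
#' @return a [mode_set()] of kind PCA; `variances` are the sigma_k and the
#'   extra field `variance_fraction` gives sigma_k / sum(sigma).
#' @export
pca_modes <- function(cov, n = NULL) {
  eig <- eigen(cov$matrix, symmetric = TRUE)
  lam <- pmax(eig$values, 0)          # clip tiny negative round-off
  total <- sum(lam)
  tol <- 1e-12 * max(lam, 1e-300)
  nz <- sum(lam > tol)
  if (is.null(n)) n <- nz
  n <- min(as.integer(n), length(lam))
  V <- fix_mode_signs(eig$vectors[, seq_len(n), drop = FALSE])
  out <- mode_set(V, lam[seq_len(n)], lam[seq_len(n)],
                  n_zero = length(lam) - nz, kind = "PCA",
                  labels = cov$mean$labels)
  out$variance_fraction <- if (total > 0) lam[seq_len(n)] / total else rep(0, n)
  out$total_variance <- total
  out$mean <- cov$mean
  out
}

#' Project ensemble members onto principal components
#'
#' Entry (m, j) is the dot product of member m's deviation from the PCA
#' mean with unit mode j, in Angstrom. Dividing by sqrt(N) converts a
#' projection to the RMSD contributed by that component.
#'
#' @param ensemble a superposed [gd_ensemble()] (same core as the modes).
#' @param modes a PCA [mode_set()] carrying its `mean` (from [pca_modes()]),
#'   or any mode set plus an explicit `mean` nodeset.
#' @param k number of components (default: all retained).
#' @param mean override mean structure.
#' @return object of class `projection_set`: fields `coordinates` (M x k),
#'   `modes`, `labels`.
#' @export
project_ensemble <- function(ensemble, modes, k = NULL, mean = NULL) {
  mu <- if (!is.null(mean)) mean else modes$mean
  if (is.null(mu)) stop("modes carry no mean structure; pass mean=")
  if (is.null(k)) k <- ncol(modes$vectors)
  k <- min(k, ncol(modes$vectors))
  core <- core_columns(ensemble)
  if (3 * sum(core) != nrow(modes$vectors))
    stop("mode dimension does not match the ensemble core")
  m <- n_members(ensemble)
  qmu <- to_coordinate_vector(mu)
  P <- matrix(NA_real_, m, k)
  for (i in seq_len(m)) {
    dq <- to_coordinate_vector(ensemble$coords[i, core, , drop = TRUE]) - qmu
    P[i, ] <- as.vector(dq %*% modes$vectors[, seq_len(k), drop = FALSE])
  }
  structure(list(coordinates = P, modes = modes,
                 labels = paste0("m", seq_len(m))),
            class = "projection_set")
}

#' Generate a conformer along mode directions
#'
#' q_new = q_ref + sum_j c_j p_j. With `variance_fraction` scaling the
#' coefficient for mode j is taken as sqrt(f_j * sigma_j): an
#' r.m.s.-amplitude corresponding to a fraction f of the mode's variance
#' (so f = 1/8 displaces by sqrt(sigma/8) along the unit mode).
#'
#' @param reference a [nodeset()] matching the mode dimension.
#' @param modes a [mode_set()].
#' @param coefficients numeric, one per leading mode (length <= retained
#'   modes); Angstrom along unit modes, or variance fractions when
#'   `variance_fraction = TRUE`.
#' @param variance_fraction interpret coefficients as variance fractions
#'   (sign gives the direction).
#' @return a [nodeset()].
#' @export
generate_conformer <- function(reference, modes, coefficients,
                               variance_fraction = FALSE) {
  k <- length(coefficients)
  if (k > ncol(modes$vectors))
    stop("more coefficients than retained modes")
  cj <- coefficients
  if (variance_fraction)
    cj <- sign(cj) * sqrt(abs(cj) * modes$variances[seq_len(k)])
  q <- to_coordinate_vector(reference)
  if (length(q) != nrow(modes$vectors))
    stop("reference dimension does not match the modes")
  qn <- q + as.vector(modes$vectors[, seq_len(k), drop = FALSE] %*% cj)
  nodeset(coordinate_matrix(qn), reference$labels)
}

# Scott's rule bandwidth per dimension for a 2D KDE
scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 6)

#' Conformational landscape density from 2D projections
#'
#' Bins (or kernel-smooths) the first two projection coordinates to
#' estimate the occupancy of the low-dimensional conformational space,
#' and converts it to a relative free-energy surface
#' G = -ln(rho / rho_max) in k_B T units (empty bins = +Inf). A meaningful
#' landscape needs a large, unbiased ensemble; with few members this is
#' only a first sketch of the basins.
#'
#' @param proj a `projection_set` (or M x k matrix); the first two columns
#'   are used. k must be >= 2 unless `allow_1d = TRUE`.
#' @param method `"histogram"` (default) or `"kde"` (Gaussian kernel,
#'   Scott's rule bandwidth; needs M >= 10).
#' @param bins grid resolution per axis (default 25).
#' @param allow_1d permit a single projection column.
#' @return list with `x`, `y` (bin centers), `density` (normalized to sum
#'   (histogram) or integrate (kde) to 1) and `free_energy`.
#' @export
landscape_density <- function(proj, method = c("histogram", "kde"),
                              bins = 25L, allow_1d = FALSE) {
  method <- match.arg(method)
  P <- if (inherits(proj, "projection_set")) proj$coordinates else as.matrix(proj)
  if (ncol(P) < 2) {
    if (!allow_1d) stop("landscape needs k = 2 projection columns (or allow_1d)")
    P <- cbind(P[, 1], 0)
  }
  x <- P[, 1]; y <- P[, 2]
  m <- length(x)
  pad <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    r + c(-1, 1) * 0.05 * diff(r)
  }
  rx <- pad(x); ry <- pad(y)
  if (method == "histogram") {
    bx <- seq(rx[1], rx[2], length.out = bins + 1)
    by <- seq(ry[1], ry[2], length.out = bins + 1)
    ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1), bins)
    iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1), bins)
    dens <- matrix(0, bins, bins)
    for (i in seq_len(m)) dens[ix[i], iy[i]] <- dens[ix[i], iy[i]] + 1
    dens <- dens / m
    cx <- (bx[-1] + bx[-length(bx)]) / 2
    cy <- (by[-1] + by[-length(by)]) / 2
  } else {
    if (m < 10) stop("kde landscape needs M >= 10")
    h <- c(scott_bandwidth(x), scott_bandwidth(y))
    if (any(h <= 0)) stop("degenerate projections: zero bandwidth")
    # kde2d uses h/4 as the Gaussian kernel sd, so pass 4 * (Scott sigma)
    kd <- MASS::kde2d(x, y, h = 4 * h, n = bins, lims = c(rx, ry))
    dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
    dens <- kd$z / (sum(kd$z) * dx * dy)
    cx <- kd$x; cy <- kd$y
  }
  g <- -log(dens / max(dens))
  list(x = cx, y = cy, density = dens, free_energy = g, method = method)
}
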