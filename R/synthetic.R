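#' Cubic-lattice test structure
#'
#' n_side^3 nodes on a cubic lattice with the given spacing: the simplest
#' non-collinear geometry with planted, exactly known distances, used as a
#' stand-in for a folded structure in tests and demonstrations.
#'
#' @param n_side nodes per edge, >= 2.
#' @param spacing lattice constant in Angstrom (default 3.8, the C-alpha
#'   virtual bond length).
#' @return a [nodeset()] with chain "A" and sequential numbering.
#' @export
make_lattice_structure <- function(n_side, spacing = 3.8) {
  n_side <- as.integer(n_side)
  if (n_side < 2) stop("n_side must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  g <- (seq_len(n_side) - 1) * spacing
  coords <- as.matrix(expand.grid(x = g, y = g, z = g))
  nodeset(coords)
}

#' Two-state synthetic ensemble with a planted deformation direction
#'
#' Half the members sit at base + (amplitude/2) * direction, half at
#' base - (amplitude/2) * direction, each perturbed by i.i.d. isotropic
#' Gaussian coordinate noise. The planted direction is the ground-truth
#' first principal component: with zero noise the ensemble covariance is
#' rank 1 with eigenvalue amplitude^2 / 4 (1/M convention).
#'
#' @param base a [nodeset()].
#' @param direction length-3N vector (normalized internally).
#' @param amplitude peak-to-peak displacement along the direction
#'   (Angstrom).
#' @param noise_sigma Gaussian noise scale per coordinate (Angstrom).
#' @param M number of members, >= 2.
#' @param seed RNG seed.
#' @return a [gd_ensemble()] with attribute `truth`: a list holding the
#'   planted unit direction, amplitude, noise and per-member state, so
#'   tests never re-derive the ground truth.
#' @export
make_two_state_ensemble <- function(base, direction, amplitude,
                                    noise_sigma, M, seed) {
  M <- as.integer(M)
  if (M < 2) stop("M must be >= 2")
  n <- n_nodes(base)
  direction <- as.numeric(direction)
  if (length(direction) != 3 * n) stop("direction must be a 3N vector")
  direction <- direction / sqrt(sum(direction^2))
  qb <- to_coordinate_vector(base)
  state <- rep(c(1, -1), length.out = M)
  coords <- array(NA_real_, c(M, n, 3))
  noise <- with_seed(seed,
    matrix(stats::rnorm(M * 3 * n, sd = noise_sigma), M, 3 * n))
  for (i in seq_len(M)) {
    q <- qb + state[i] * (amplitude / 2) * direction + noise[i, ]
    coords[i, , ] <- coordinate_matrix(q)
  }
  ens <- gd_ensemble(coords, base$labels)
  attr(ens, "truth") <- list(direction = direction, amplitude = amplitude,
                             noise_sigma = noise_sigma, state = state,
                             seed = seed)
  ens
}

#' Random internal (non-rigid) deformation direction
#'
#' A seeded random unit 3N vector with the six rigid-body components
#' (translations and infinitesimal rotations of `base`) projected out.
#' This is the natural planted direction for a two-state ensemble: a
#' genuine conformational change carries no net rigid-body motion, and
#' superposition would silently strip any rigid component from a naive
#' random direction, biasing recovery comparisons.
#'
#' @param base a [nodeset()].
#' @param seed RNG seed.
#' @return unit numeric vector of length 3N, orthogonal to the rigid
#'   subspace of `base`.
#' @export
random_internal_direction <- function(base, seed) {
  n <- n_nodes(base)
  v <- with_seed(seed, stats::rnorm(3 * n))
  B <- rigid_basis(base$coords)
  v <- v - B %*% crossprod(B, v)
  as.vector(v / sqrt(sum(v^2)))
}

#' Synthetic blob density map with planted centers
#'
#' Sum of isotropic Gaussians with an explicit sigma, for planted-truth
#' testing of the pseudoatom fitting pipeline. The planted centers and
#' weights are attached as attribute `truth`.
#'
#' @param centers K x 3 matrix of blob centers (Angstrom).
#' @param weights per-blob integrated weights (default 1).
#' @param sigma Gaussian sigma in Angstrom.
#' @param voxel voxel size (Angstrom).
#' @param pad padding beyond the blob bounding box (default 4 sigma).
#' @return a [density_grid()] with attribute `truth`.
#' @export
make_blob_map <- function(centers, weights = NULL, sigma = 2, voxel = 1,
                          pad = 4 * sigma) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1) stop("need at least one center")
  if (is.null(weights)) weights <- rep(1, nrow(centers))
  grid <- gaussian_map(centers, sigma, voxel, pad, weights)
  attr(grid, "truth") <- list(centers = centers, weights = weights,
                              sigma = sigma)
  grid
}

#' Write planted ground truth as a JSON sidecar
#' @param x an object carrying a `truth` attribute.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_truth <- function(x, file) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object carries no planted ground truth")
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
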