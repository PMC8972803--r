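#' 3D density grid
#'
#' A voxel map with per-axis voxel size (Angstrom) and the Cartesian
#' position of the center of voxel (1,1,1) as origin. Values are stored
#' x-fastest, matching MRC column order after axis normalization.
#'
#' @param values nx x ny x nz numeric array.
#' @param voxel length-3 (or scalar) voxel size in Angstrom, > 0.
#' @param origin length-3 position of the first voxel center (Angstrom).
#' @param threshold optional density threshold used by fitting.
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(values, voxel, origin = c(0, 0, 0), threshold = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("density values must be finite")
  voxel <- rep_len(as.numeric(voxel), 3)
  if (any(voxel <= 0)) stop("voxel size must be positive")
  structure(list(values = values, voxel = voxel,
                 origin = as.numeric(origin), threshold = threshold),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s voxels @ %.3g A, origin (%s)\n",
              paste(dim(x$values), collapse = "x"), x$voxel[1],
              paste(sprintf("%.3g", x$origin), collapse = ", ")))
  invisible(x)
}

# Cartesian centers of all voxels, as a (#voxels) x 3 matrix in storage order
voxel_centers <- function(grid, idx = NULL) {
  d <- dim(grid$values)
  if (is.null(idx)) idx <- seq_len(prod(d))
  ai <- arrayInd(idx, d)
  sweep((ai - 1) * rep(grid$voxel, each = nrow(ai)), 2, grid$origin, "+")
}

#' Read an MRC2014 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32), both endiannesses,
#' and arbitrary axis order (mapc/mapr/maps), which is normalized to
#' (x, y, z) storage. Voxel size comes from the cell dimensions over the
#' sampling counts; the origin from the ORIGIN header words.
#'
#' @param path path to an MRC file.
#' @return a [density_grid()].
#' @export
read_density <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_header <- readBin(con, "raw", n = 1024)
  if (length(raw_header) < 1024) stop("MRC format error: truncated header")
  endian <- "little"
  geti <- function(word) readBin(raw_header[(4 * (word - 1) + 1):(4 * word)],
                                 "integer", size = 4, endian = endian)
  getf <- function(word) readBin(raw_header[(4 * (word - 1) + 1):(4 * word)],
                                 "numeric", size = 4, endian = endian)
  machst <- raw_header[213:216]
  if (as.integer(machst[1]) == 0x11) endian <- "big"
  nc <- geti(1); nr <- geti(2); ns <- geti(3)
  mode <- geti(4)
  if (!(mode %in% c(0, 1, 2)))
    stop(sprintf("MRC format error: unsupported MODE %d (need 0, 1 or 2)", mode))
  m <- c(geti(8), geti(9), geti(10))
  cella <- c(getf(11), getf(12), getf(13))
  crs <- c(geti(17), geti(18), geti(19))
  if (!setequal(crs, 1:3))
    stop("MRC format error: invalid MAPC/MAPR/MAPS axis codes")
  nsymbt <- geti(24)
  origin <- c(getf(50), getf(51), getf(52))
  if (any(m <= 0)) stop("MRC format error: non-positive MX/MY/MZ sampling")
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- as.double(nc) * nr * ns
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = endian))
  if (length(vals) < nvox)
    stop("MRC format error: truncated data section")
  arr <- array(vals, dim = c(nc, nr, ns))
  # storage dimension d corresponds to Cartesian axis crs[d]
  arr <- aperm(arr, perm = order(crs))
  density_grid(arr, voxel = cella / m, origin = origin)
}

#' Write a density grid as MRC2014 (mode 2, float32)
#' @param grid a [density_grid()].
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_density <- function(grid, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  d <- dim(grid$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                          # nx ny nz
  wi(2)                          # mode float32
  wi(c(0, 0, 0))                 # nxstart
  wi(d)                          # mx my mz
  wf(d * grid$voxel)             # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1, 2, 3))                 # mapc mapr maps
  v <- grid$values
  wf(c(min(v), max(v), mean(v))) # dmin dmax dmean
  wi(1)                          # ispg
  wi(0)                          # nsymbt
  wi(rep(0, 3))                  # extra 25-27
  wi(20140)                      # nversion (MRC2014)
  wi(rep(0, 21))                 # extra 29-49
  wf(grid$origin)                # origin x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.vector(v)))    # rms
  wi(0)                          # nlabl
  writeBin(raw(800), con)        # labels
  writeBin(as.vector(v), con, size = 4, endian = "little")
  invisible(file)
}

#' Synthesize a density map from a structure
#'
#' Places an isotropic 3D Gaussian on every node with
#' sigma = resolution / (2 sqrt(2 ln 2)) (so FWHM equals the nominal
#' resolution), each normalized to integrate to its weight. Serves as a
#' stand-in for an experimental cryoEM map in tests and demonstrations.
#'
#' @param nodes a [nodeset()].
#' @param resolution nominal resolution (FWHM) in Angstrom, > 0.
#' @param voxel voxel size in Angstrom; must be <= resolution / 2.
#' @param pad padding around the structure's bounding box (Angstrom).
#' @param weights optional per-node weights (default 1).
#' @return a [density_grid()].
#' @export
synth_density <- function(nodes, resolution, voxel = resolution / 3,
                          pad = 2 * resolution, weights = NULL) {
  if (resolution <= 0) stop("resolution must be positive")
  if (voxel > resolution / 2)
    stop("voxel too coarse: need voxel <= resolution / 2 to sample the blobs")
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  gaussian_map(nodes$coords, sigma, voxel, pad, weights)
}

gaussian_map <- function(centers, sigma, voxel, pad, weights = NULL) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (is.null(weights)) weights <- rep(1, k)
  lo <- apply(centers, 2, min) - pad
  hi <- apply(centers, 2, max) + pad
  ax <- lapply(1:3, function(a) seq(lo[a], hi[a], by = voxel))
  d <- vapply(ax, length, integer(1))
  vals <- array(0, dim = d)
  for (b in seq_len(k)) {
    if (weights[b] == 0) next
    g <- lapply(1:3, function(a)
      stats::dnorm(ax[[a]], mean = centers[b, a], sd = sigma))
    vals <- vals + weights[b] * outer(outer(g[[1]], g[[2]]), g[[3]])
  }
  density_grid(vals, voxel = voxel, origin = lo)
}

#' Fitted pseudoatom model
#'
#' K codebook vector positions plus per-pseudoatom weights (the density
#' mass of each codebook's nearest-neighbour Voronoi cell) and fit
#' metadata.
#'
#' @param positions K x 3 matrix (Angstrom).
#' @param weights K non-negative reals.
#' @param meta list of fit metadata.
#' @return an object of class `pseudoatom_model`.
#' @export
pseudoatom_model <- function(positions, weights, meta = list()) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("need at least one pseudoatom")
  structure(list(positions = positions, weights = weights, meta = meta),
            class = "pseudoatom_model")
}

#' @export
print.pseudoatom_model <- function(x, ...) {
  cat(sprintf("<pseudoatom_model> K=%d, total weight %.4g\n",
              nrow(x$positions), sum(x$weights)))
  invisible(x)
}

#' Neural-gas (TRN) pseudoatom fitting of a density map
#'
#' Vector quantization of the above-threshold density into K codebook
#' vectors by the annealed neural-gas rule: at each step a point x is
#' drawn from the voxels with probability proportional to density (with
#' uniform jitter inside the voxel), all codebooks are ranked by distance
#' to x, and each moves by
#' eps(t) * exp(-rank / lambda(t)) * (x - w), with eps and lambda decaying
#' exponentially from their initial to final values over `steps` updates.
#' Weights are assigned afterwards as the density mass of each codebook's
#' nearest-neighbour cell, so they conserve the total above-threshold
#' mass exactly. Fully reproducible given `seed`.
#'
#' @param grid a [density_grid()].
#' @param K number of pseudoatoms, >= 1.
#' @param seed RNG seed (required for reproducibility).
#' @param schedule list with `eps_i`, `eps_f`, `lambda_i`, `lambda_f`,
#'   `steps`; defaults 0.3, 0.005, K/3, 0.01, max(200*K, 2000). The final
#'   rate and step floor follow the original neural-gas literature: the
#'   final position is an annealed average over roughly 2/eps_f samples,
#'   so a coarser eps_f would leave codebooks jittering by a sizeable
#'   fraction of the density spread.
#' @param threshold density threshold (defaults to the grid's, else 0:
#'   all strictly positive density).
#' @param jitter add uniform within-voxel jitter to samples (default TRUE).
#' @return a [pseudoatom_model()]; `meta` records seed, schedule,
#'   threshold and the final mass-weighted quantization error.
#' @export
trn_fit <- function(grid, K, seed, schedule = list(), threshold = NULL,
                    jitter = TRUE) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (is.null(threshold)) threshold <- if (is.null(grid$threshold)) 0 else grid$threshold
  sch <- utils::modifyList(
    list(eps_i = 0.3, eps_f = 0.005, lambda_i = K / 3, lambda_f = 0.01,
         steps = max(200L * K, 2000L)),
    schedule)
  if (sch$steps < 1) stop("schedule needs steps >= 1")
  v <- as.vector(grid$values)
  sel <- which(v > threshold)
  if (!length(sel)) stop("no density above threshold: nothing to fit")
  if (length(sel) < K)
    stop(sprintf("K = %d exceeds the %d voxels above threshold", K, length(sel)))
  centers <- voxel_centers(grid, sel)
  mass <- v[sel]
  prob <- mass / sum(mass)
  W <- with_seed(seed, {
    init <- sample.int(length(sel), K, replace = FALSE, prob = prob)
    W <- centers[init, , drop = FALSE]
    steps <- as.integer(sch$steps)
    draws <- sample.int(length(sel), steps, replace = TRUE, prob = prob)
    jit <- if (jitter)
      matrix(stats::runif(3 * steps, -0.5, 0.5), steps, 3) *
        rep(grid$voxel, each = steps)
    else matrix(0, steps, 3)
    frac <- seq_len(steps) / steps
    eps <- sch$eps_i * (sch$eps_f / sch$eps_i)^frac
    lam <- sch$lambda_i * (sch$lambda_f / sch$lambda_i)^frac
    for (t in seq_len(steps)) {
      x <- centers[draws[t], ] + jit[t, ]
      d2 <- rowSums(sweep(W, 2, x)^2)
      r <- rank(d2, ties.method = "first") - 1
      h <- eps[t] * exp(-r / lam[t])
      W <- W + h * sweep(-W, 2, x, "+")
    }
    W
  })
  # nearest-codebook (Voronoi) assignment of above-threshold voxels
  assign_idx <- nearest_index(centers, W)
  weights <- vapply(seq_len(K), function(k) sum(mass[assign_idx == k]),
                    numeric(1))
  mind2 <- rowSums((centers - W[assign_idx, , drop = FALSE])^2)
  qerr <- sum(mass * mind2) / sum(mass)
  pseudoatom_model(W, weights,
                   meta = list(seed = seed, schedule = sch,
                               threshold = threshold,
                               quantization_error = qerr))
}

# for each row of X, the index of the nearest row of W (ties: lowest index)
nearest_index <- function(X, W) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) - 2 * X %*% t(W) +
    outer(rep(1, nrow(X)), rowSums(W^2))
  max.col(-d2, ties.method = "first")
}

#' Nearest-neighbour mapping between pseudoatoms and atoms
#'
#' Assigns every atom (node) to its nearest pseudoatom by Euclidean
#' distance (ties to the lowest pseudoatom index) and returns the inverse
#' member lists.
#'
#' @param model a [pseudoatom_model()].
#' @param nodes a [nodeset()].
#' @return list with `atom_to_pseudo` (length N integer) and `members`
#'   (length K list of atom index vectors).
#' @export
map_pseudoatoms_to_atoms <- function(model, nodes) {
  if (n_nodes(nodes) < 1) stop("empty node set")
  a2p <- nearest_index(nodes$coords, model$positions)
  members <- lapply(seq_len(nrow(model$positions)),
                    function(k) which(a2p == k))
  list(atom_to_pseudo = a2p, members = members)
}

#' Convert a pseudoatom model to a nodeset
#' @param model a [pseudoatom_model()].
#' @return a [nodeset()] (weights are not carried; see
#'   [write_pseudoatoms()] for the B-factor convention).
#' @export
pseudoatom_nodes <- function(model) {
  k <- nrow(model$positions)
  nodeset(model$positions,
          data.frame(chain = rep("A", k), resno = seq_len(k),
                     resname = rep("PSD", k), insert = rep("", k),
                     stringsAsFactors = FALSE))
}

#' Write pseudoatoms as a PDB file (weights in the B-factor column)
#' @param model a [pseudoatom_model()].
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_pseudoatoms <- function(model, file) {
  write_structure(pseudoatom_nodes(model), file, bfactor = model$weights)
}

#' ANM normal modes of a pseudoatom model
#'
#' Builds an anisotropic network over the codebook positions and returns
#' its normal modes. Because pseudoatoms sit much further apart than
#' residues, the cutoff defaults to 2.0 x the mean nearest-neighbour
#' codebook distance instead of the residue-level 15 A.
#'
#' @param model a [pseudoatom_model()] with K >= 2.
#' @param params optional [enm_parameters()]; default gamma 1 and the
#'   adaptive cutoff above.
#' @param n_modes modes to retain (default: all non-zero).
#' @return a [mode_set()] of kind ANM.
#' @export
pseudoatom_anm <- function(model, params = NULL, n_modes = NULL) {
  if (nrow(model$positions) < 2) stop("pseudoatom ANM needs K >= 2")
  nodes <- pseudoatom_nodes(model)
  if (is.null(params)) {
    D <- pairwise_dist(nodes$coords)
    diag(D) <- Inf
    nn <- mean(apply(D, 1, min))
    params <- enm_parameters(gamma = 1, r_cut = 2 * nn, model = "ANM")
  }
  compute_modes(build_anm_hessian(nodes, params), n_modes)
}
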