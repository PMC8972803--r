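#' Elastic network model parameters
#'
#' A uniform force constant `gamma` (reduced units) and a distance cutoff
#' `r_cut` (Angstrom) define the spring network: every node pair closer
#' than `r_cut` in the reference structure is connected by a harmonic
#' spring of stiffness `gamma`. Defaults follow the standard literature
#' values for residue-level coarse graining: 15 A for the anisotropic
#' network model (ANM), 10 A for the Gaussian network model (GNM),
#' gamma = 1.
#'
#' @param gamma force constant, > 0.
#' @param r_cut cutoff distance in Angstrom, > 0.
#' @param model `"ANM"` or `"GNM"`.
#' @return an `enm_parameters` object.
#' @export
enm_parameters <- function(gamma = 1, r_cut = NULL, model = c("ANM", "GNM")) {
  model <- match.arg(model)
  if (is.null(r_cut)) r_cut <- if (model == "ANM") 15 else 10
  if (gamma <= 0 || r_cut <= 0) stop("gamma and r_cut must be positive")
  structure(list(gamma = gamma, r_cut = r_cut, model = model),
            class = "enm_parameters")
}

pairwise_dist <- function(coords) as.matrix(stats::dist(coords))

#' Build the ANM Hessian
#'
#' The 3N x 3N Hessian of the ANM potential
#' V = (gamma/2) * sum_contacts (r_ij - r_ij^0)^2, evaluated at the
#' reference structure. The 3 x 3 off-diagonal super-element for a
#' contacting pair is -(gamma / (r_ij^0)^2) * x_ij x_ij^T with
#' x_ij = x_j - x_i, zero beyond the cutoff; diagonal super-elements are
#' minus the sum of the off-diagonal blocks in their row, which makes the
#' matrix translation-invariant and positive semi-definite.
#'
#' @param nodes a [nodeset()] with N >= 2 and no coincident nodes.
#' @param params an [enm_parameters()] (ANM defaults if omitted).
#' @return an object of class `hessian_matrix` with fields `matrix`,
#'   `params`, `labels`.
#' @export
build_anm_hessian <- function(nodes, params = enm_parameters(model = "ANM")) {
  X <- nodes$coords
  n <- nrow(X)
  if (n < 2) stop("ANM needs at least 2 nodes")
  D <- pairwise_dist(X)
  if (any(D[upper.tri(D)] < 1e-6))
    stop("coincident nodes (distance < 1e-6 A): singular geometry")
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      r0 <- D[i, j]
      if (r0 > params$r_cut) next
      dx <- X[j, ] - X[i, ]
      blk <- -(params$gamma / r0^2) * tcrossprod(dx)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  comp <- contact_components(D <= params$r_cut)
  if (comp > 1)
    warning(sprintf("contact graph has %d connected components; expect extra zero modes", comp))
  structure(list(matrix = H, params = params, labels = nodes$labels,
                 coords = X), class = "hessian_matrix")
}

#' Build the GNM Kirchhoff (connectivity) matrix
#'
#' N x N graph Laplacian of the contact network: off-diagonal entries
#' -gamma for pairs within the cutoff, zero otherwise; diagonal entries
#' gamma times the contact count.
#'
#' @param nodes a [nodeset()] with N >= 2.
#' @param params an [enm_parameters()] (GNM defaults if omitted).
#' @return an object of class `kirchhoff_matrix`.
#' @export
build_gnm_kirchhoff <- function(nodes, params = enm_parameters(model = "GNM")) {
  X <- nodes$coords
  n <- nrow(X)
  if (n < 2) stop("GNM needs at least 2 nodes")
  D <- pairwise_dist(X)
  A <- (D <= params$r_cut) & upper.tri(D)
  K <- matrix(0, n, n)
  K[A] <- -params$gamma
  K <- K + t(K)
  diag(K) <- -rowSums(K)
  comp <- contact_components(D <= params$r_cut)
  if (comp > 1)
    warning(sprintf("contact graph has %d connected components; expect extra zero modes", comp))
  structure(list(matrix = K, params = params, labels = nodes$labels,
                 coords = X), class = "kirchhoff_matrix")
}

# connected components of the contact graph (BFS on the adjacency)
contact_components <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Normal mode set
#'
#' Container for eigenvectors/eigenvalues from ANM, GNM or PCA with
#' zero-mode bookkeeping. For elastic models the per-mode variance is
#' 1/lambda (reduced units, k_B T / gamma = 1); for PCA it is the
#' eigenvalue sigma_k itself.
#'
#' @param vectors matrix with orthonormal mode columns ((3N or N) x k).
#' @param eigenvalues length-k non-negative eigenvalues.
#' @param variances per-mode variances.
#' @param n_zero number of zero modes removed before retention.
#' @param kind `"ANM"`, `"GNM"` or `"PCA"`.
#' @param labels node label table.
#' @return an object of class `mode_set`.
#' @export
mode_set <- function(vectors, eigenvalues, variances, n_zero, kind, labels = NULL) {
  structure(list(vectors = as.matrix(vectors), eigenvalues = eigenvalues,
                 variances = variances, n_zero = as.integer(n_zero),
                 kind = kind, labels = labels), class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set:%s> %d modes (%d zero modes removed)\n",
              x$kind, ncol(x$vectors), x$n_zero))
  invisible(x)
}

# deterministic eigenvector sign: largest-magnitude component positive
fix_mode_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Compute normal modes of an elastic network matrix
#'
#' Dense symmetric eigendecomposition. Eigenvalues below
#' `1e-6 * max(lambda)` count as zero modes (rigid-body motions): they are
#' removed and counted in `n_zero`. Remaining modes are sorted ascending
#' by eigenvalue, so mode 1 is the softest internal motion (in full-atom
#' numbering it would be "mode 7"). A warning is issued when the zero-mode
#' count differs from the expectation (6 for ANM, 1 for GNM) - collinear
#' or disconnected geometries legitimately do.
#'
#' @param matrix a `hessian_matrix` or `kirchhoff_matrix`.
#' @param n_modes number of non-zero modes to retain, or `NULL` for all.
#' @return a [mode_set()] with variances 1/lambda.
#' @export
compute_modes <- function(matrix, n_modes = NULL) {
  kind <- if (inherits(matrix, "hessian_matrix")) "ANM"
          else if (inherits(matrix, "kirchhoff_matrix")) "GNM"
          else stop("matrix must be a hessian_matrix or kirchhoff_matrix")
  eig <- eigen(matrix$matrix, symmetric = TRUE)
  lam <- rev(eig$values)              # ascending
  V <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  tol <- 1e-6 * max(lam)
  zero <- lam < tol
  n_zero <- sum(zero)
  expected <- if (kind == "ANM") 6L else 1L
  if (n_zero != expected)
    warning(sprintf("%s has %d zero modes (expected %d): degenerate or disconnected geometry",
                    kind, n_zero, expected))
  lam <- lam[!zero]
  V <- V[, !zero, drop = FALSE]
  if (!is.null(n_modes)) {
    n_modes <- as.integer(n_modes)
    if (n_modes > length(lam)) {
      warning(sprintf("requested %d modes but only %d non-zero modes exist; truncating",
                      n_modes, length(lam)))
      n_modes <- length(lam)
    }
    lam <- lam[seq_len(n_modes)]
    V <- V[, seq_len(n_modes), drop = FALSE]
  }
  mode_set(fix_mode_signs(V), lam, 1 / lam, n_zero, kind, matrix$labels)
}

#' Mean-square fluctuations per node
#'
#' ANM: MSF_i = sum_k (1/lambda_k) |p_k at node i|^2 over the three
#' Cartesian components of node i. GNM: MSF_i = 3 * sum_k
#' (1/lambda_k) p_ki^2 (the factor 3 converts the isotropic per-coordinate
#' fluctuation to a per-node value). Reduced units k_B T / gamma = 1.
#'
#' @param modes a [mode_set()] of kind ANM or GNM.
#' @return numeric per-node MSF.
#' @export
msf <- function(modes) {
  if (modes$kind == "PCA")
    stop("unsupported kind: use the ensemble variance for PCA mode sets")
  V2 <- modes$vectors^2
  percomp <- V2 %*% modes$variances
  if (modes$kind == "ANM") {
    n <- nrow(V2) / 3
    as.vector(rowsum(as.vector(percomp), rep(seq_len(n), each = 3)))
  } else {
    3 * as.vector(percomp)
  }
}

#' Root-mean-square fluctuations
#' @param modes a [mode_set()] of kind ANM or GNM.
#' @return sqrt of [msf()].
#' @export
rmsf <- function(modes) sqrt(msf(modes))

#' Covariance matrix from a mode set
#'
#' C = sum_k variance_k p_k p_k^T over retained modes. With all non-zero
#' modes of an elastic model retained this equals the Moore-Penrose
#' pseudo-inverse of the Hessian (or Kirchhoff matrix).
#'
#' @param modes a [mode_set()].
#' @return symmetric positive semi-definite matrix.
#' @export
covariance_from_modes <- function(modes) {
  V <- modes$vectors
  V %*% (modes$variances * t(V))
}

#' ANM potential energy of a deformed conformation
#'
#' V = (gamma/2) * sum over reference contacts (r_ij - r_ij^0)^2, with the
#' contact list fixed by the reference distances against the cutoff.
#' Zero at the reference by construction.
#'
#' @param reference,conformation [nodeset()] objects with equal N.
#' @param params an [enm_parameters()].
#' @return energy in reduced units.
#' @export
anm_potential <- function(reference, conformation,
                          params = enm_parameters(model = "ANM")) {
  Xr <- reference$coords
  Xc <- if (inherits(conformation, "nodeset")) conformation$coords
        else as.matrix(conformation)
  if (!all(dim(Xr) == dim(Xc))) stop("node counts differ")
  D0 <- pairwise_dist(Xr)
  D <- pairwise_dist(Xc)
  sel <- upper.tri(D0) & D0 <= params$r_cut
  (params$gamma / 2) * sum((D[sel] - D0[sel])^2)
}

# Moore-Penrose pseudo-inverse via symmetric eigendecomposition
pinv_sym <- function(M, tol = NULL) {
  eig <- eigen(M, symmetric = TRUE)
  if (is.null(tol)) tol <- 1e-8 * max(abs(eig$values), 1e-300)
  keep <- abs(eig$values) > tol
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  V <- eig$vectors[, keep, drop = FALSE]
  V %*% (t(V) / eig$values[keep])
}

# orthonormal basis of the 6 rigid-body motions (3 translations + 3
# infinitesimal rotations about the centroid) of a coordinate set
rigid_basis <- function(coords) {
  n <- nrow(coords)
  Xc <- sweep(coords, 2, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  ax <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(Xc, 1, function(p) c(ax[a, 2] * p[3] - ax[a, 3] * p[2],
                                        ax[a, 3] * p[1] - ax[a, 1] * p[3],
                                        ax[a, 1] * p[2] - ax[a, 2] * p[1])))
    B[, 3 + a] <- as.vector(t(rot))
  }
  qr.Q(qr(B))
}

#' Vibrational subsystem analysis (VSA) Hessian reduction
#'
#' Integrates out the environment degrees of freedom by the generalized
#' Schur complement H_eff = H_ss - H_se H_ee^+ H_es, where s indexes the
#' subsystem nodes and e the complement. The environment block of a free
#' elastic network can be singular, hence the pseudo-inverse. The reduced
#' matrix is symmetric PSD and inherits the subsystem's six rigid-body
#' zero modes. VSA is the standard remedy for "tip effects": flexible
#' termini or loops are demoted to environment so their noise no longer
#' dominates the soft modes.
#'
#' The subsystem covariance identity holds in the rigid-projected sense:
#' pinv(H_eff) equals P C_ss P, where C_ss is the subsystem block of
#' pinv(H) and P projects out the subsystem's rigid-body motions (the two
#' pseudo-inverses null different rigid spaces, so the unprojected blocks
#' differ for free networks).
#'
#' @param hessian a `hessian_matrix`.
#' @param subsystem integer vector of node indices to keep (non-empty).
#' @return a `hessian_matrix` over the subsystem nodes.
#' @export
vsa_reduce <- function(hessian, subsystem) {
  subsystem <- sort(unique(as.integer(subsystem)))
  n <- nrow(hessian$matrix) / 3
  if (!length(subsystem)) stop("subsystem must be non-empty")
  if (any(subsystem < 1 | subsystem > n)) stop("subsystem index out of range")
  si <- as.vector(vapply(subsystem, function(i) (3 * i - 2):(3 * i), numeric(3)))
  ei <- setdiff(seq_len(3 * n), si)
  H <- hessian$matrix
  Heff <- if (!length(ei)) H else {
    H[si, si] - H[si, ei, drop = FALSE] %*% pinv_sym(H[ei, ei, drop = FALSE]) %*%
      H[ei, si, drop = FALSE]
  }
  Heff <- (Heff + t(Heff)) / 2
  structure(list(matrix = Heff, params = hessian$params,
                 labels = hessian$labels[subsystem, , drop = FALSE],
                 coords = hessian$coords[subsystem, , drop = FALSE]),
            class = "hessian_matrix")
}
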