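#' Root-mean-square deviation between two node sets
#'
#' Plain RMSD over paired nodes, without any superposition:
#' sqrt(mean_n |a_n - b_n|^2).
#'
#' @param a,b [nodeset()] objects (or N x 3 matrices) with equal N.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  ma <- if (inherits(a, "nodeset")) a$coords else as.matrix(a)
  mb <- if (inherits(b, "nodeset")) b$coords else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("node counts differ")
  sqrt(mean(rowSums((ma - mb)^2)))
}

# weighted Kabsch on raw matrices; returns list(R, t, rmsd)
# R maps centred mobile onto centred target; reflection corrected by
# flipping the sign of the smallest singular vector when det < 0
kabsch_core <- function(mobile, target, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative")
  ws <- sum(weights)
  if (ws <= 0) stop("weights must sum to a positive value")
  w <- weights / ws
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d < 0) {
    # proper rotation only: reflect along the least-significant direction
    sv$v[, 3] <- -sv$v[, 3]
  }
  R <- sv$v %*% t(sv$u)
  tr <- unname(ct - as.vector(R %*% cm))
  fitted <- sweep(A %*% t(R), 2, ct, "+")
  list(R = R, t = tr,
       rmsd = sqrt(sum(w * rowSums((fitted - target)^2))),
       fitted = fitted)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' RMSD of `mobile` onto `target`, using the SVD solution with reflection
#' correction so that det(R) = +1 always.
#'
#' @param mobile,target [nodeset()] objects with equal N (N >= 3,
#'   non-collinear for a unique rotation).
#' @param weights optional non-negative per-node weights (sum > 0).
#' @return list with elements `nodes` (transformed mobile), `rotation`
#'   (3 x 3, det +1), `translation` (length 3) and `rmsd` (weighted
#'   least-squares minimum, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mm <- if (inherits(mobile, "nodeset")) mobile$coords else as.matrix(mobile)
  mt <- if (inherits(target, "nodeset")) target$coords else as.matrix(target)
  if (!all(dim(mm) == dim(mt))) stop("node counts differ")
  # collinearity check: rank of centred coordinates
  cc <- sweep(mm, 2, colMeans(mm))
  if (nrow(mm) >= 3 && svd(cc)$d[2] < 1e-8 * max(svd(cc)$d[1], 1))
    warning("all nodes are (nearly) collinear; rotation about the axis is degenerate")
  fit <- kabsch_core(mm, mt, weights)
  labs <- if (inherits(mobile, "nodeset")) mobile$labels else NULL
  list(nodes = nodeset(fit$fitted, labs), rotation = fit$R,
       translation = fit$t, rmsd = fit$rmsd)
}

ensemble_mean_coords <- function(coords, mask) {
  n <- dim(coords)[2]
  out <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    pres <- mask[, j]
    if (any(pres)) out[j, ] <- colMeans(coords[pres, j, , drop = FALSE], dims = 1)
  }
  out
}

#' Iteratively superpose an ensemble onto its converging mean
#'
#' Each iteration superposes every member onto the current mean structure
#' (masked nodes carry zero weight) and recomputes the mean; iteration
#' stops when the RMSD between successive means drops below `tol`. The
#' initial reference is the ensemble's reference member.
#'
#' @param ensemble a [gd_ensemble()] with M >= 2.
#' @param tol convergence tolerance on the mean, Angstrom (default 1e-5).
#' @param max_iter iteration cap (default 50).
#' @return list with `ensemble` (superposed), `mean` (a [nodeset()] over
#'   core columns), `n_iter`, and `converged` (logical; a non-converged
#'   result is returned, not raised).
#' @export
iterative_superpose <- function(ensemble, tol = 1e-5, max_iter = 50L) {
  if (n_members(ensemble) < 2) stop("iterative superposition needs M >= 2")
  if (tol <= 0) stop("tol must be positive")
  coords <- ensemble$coords
  mask <- ensemble$mask
  m <- dim(coords)[1]
  ref <- coords[ensemble$reference, , , drop = TRUE]
  mean_old <- ref
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    for (i in seq_len(m)) {
      pres <- mask[i, ] & !apply(is.na(mean_old), 1, any)
      fit <- kabsch_core(coords[i, pres, , drop = TRUE],
                         mean_old[pres, , drop = FALSE])
      moved <- sweep(coords[i, , , drop = TRUE] %*% t(fit$R), 2, fit$t, "+")
      coords[i, , ] <- moved
    }
    mean_new <- ensemble_mean_coords(coords, mask)
    ok <- !apply(is.na(mean_new) | is.na(mean_old), 1, any)
    delta <- sqrt(mean(rowSums((mean_new[ok, , drop = FALSE] -
                                mean_old[ok, , drop = FALSE])^2)))
    mean_old <- mean_new
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- ensemble
  out$coords <- coords
  core <- core_columns(out)
  list(ensemble = out,
       mean = nodeset(mean_old[core, , drop = FALSE],
                      out$labels[core, , drop = FALSE]),
       n_iter = n_iter, converged = converged)
}

#' Trim ensemble columns (flexible termini and loops)
#'
#' Removes columns consistently from every member, its labels and mask.
#' Used to excise flexible termini/loops whose noise ("tip effects") would
#' otherwise dominate superposition and soft modes.
#'
#' @param ensemble a [gd_ensemble()].
#' @param keep logical vector of columns to keep, or NULL when using
#'   `drop_termini`.
#' @param drop_termini drop this many columns from each end.
#' @return the trimmed [gd_ensemble()]; fewer than 3 surviving columns is
#'   an error (superposition would be undefined).
#' @export
trim_ensemble <- function(ensemble, keep = NULL, drop_termini = NULL) {
  n <- dim(ensemble$coords)[2]
  if (is.null(keep)) {
    if (is.null(drop_termini)) stop("supply keep or drop_termini")
    k <- as.integer(drop_termini)
    keep <- rep(TRUE, n)
    if (k > 0) keep[c(seq_len(min(k, n)), seq.int(max(1, n - k + 1), n))] <- FALSE
  }
  if (length(keep) != n) stop("keep must have one flag per column")
  if (sum(keep) < 3) stop("fewer than 3 columns would survive trimming")
  gd_ensemble(ensemble$coords[, keep, , drop = FALSE],
              ensemble$labels[keep, , drop = FALSE],
              ensemble$mask[, keep, drop = FALSE],
              ensemble$reference)
}

#' Total ensemble variance about the masked mean
#'
#' Sum over members and present nodes of squared deviation from the
#' per-column mean, divided by M. Non-increasing across iterations of
#' [iterative_superpose()].
#'
#' @param ensemble a [gd_ensemble()].
#' @return total variance (Angstrom^2).
#' @export
ensemble_variance <- function(ensemble) {
  mu <- ensemble_mean_coords(ensemble$coords, ensemble$mask)
  tot <- 0
  m <- dim(ensemble$coords)[1]
  for (i in seq_len(m)) {
    pres <- ensemble$mask[i, ]
    d <- ensemble$coords[i, pres, , drop = TRUE] - mu[pres, , drop = FALSE]
    tot <- tot + sum(d^2)
  }
  tot / m
}
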