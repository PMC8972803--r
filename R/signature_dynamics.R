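#' Directional overlap (correlation cosine) between two mode vectors
#'
#' |v . w| / (|v| |w|). The absolute value is taken because eigenvector
#' sign is arbitrary.
#'
#' @param v,w numeric vectors of equal length, non-zero norm.
#' @return overlap in \[0, 1\].
#' @export
mode_overlap <- function(v, w) {
  if (length(v) != length(w)) stop("vectors differ in length")
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("zero vector has no direction")
  min(abs(sum(v * w)) / (nv * nw), 1)
}

#' Pairwise overlap matrix between two mode sets
#'
#' @param A,B [mode_set()] objects on the same node dimension.
#' @param k number of leading modes from each (default: all shared).
#' @return k_A x k_B matrix of [mode_overlap()] values.
#' @export
overlap_matrix <- function(A, B, k = NULL) {
  if (nrow(A$vectors) != nrow(B$vectors))
    stop("mode sets live on different node dimensions")
  ka <- if (is.null(k)) ncol(A$vectors) else min(k, ncol(A$vectors))
  kb <- if (is.null(k)) ncol(B$vectors) else min(k, ncol(B$vectors))
  Va <- A$vectors[, seq_len(ka), drop = FALSE]
  Vb <- B$vectors[, seq_len(kb), drop = FALSE]
  na <- sqrt(colSums(Va^2)); nb <- sqrt(colSums(Vb^2))
  pmin(abs(crossprod(Va, Vb)) / outer(na, nb), 1)
}

#' Greedily match modes between two sets by overlap
#'
#' Repeatedly takes the globally largest overlap among unmatched
#' rows/columns; ties break deterministically to the lowest row index,
#' then lowest column index.
#'
#' @param M an overlap matrix with entries in \[0, 1\].
#' @return data.frame with columns `i` (row mode), `j` (matched column
#'   mode), `overlap`, ordered by matching round.
#' @export
match_modes <- function(M) {
  M <- as.matrix(M)
  nr <- nrow(M); nc <- ncol(M)
  rows <- rep(TRUE, nr); cols <- rep(TRUE, nc)
  out <- data.frame(i = integer(), j = integer(), overlap = numeric())
  for (step in seq_len(min(nr, nc))) {
    sub <- M
    sub[!rows, ] <- -Inf
    sub[, !cols] <- -Inf
    best <- max(sub)
    # ties: lowest i, then lowest j (column-major which() would favour j)
    cand <- which(sub == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    out <- rbind(out, data.frame(i = i, j = j, overlap = M[i, j]))
    rows[i] <- FALSE; cols[j] <- FALSE
  }
  out
}

mode_variances <- function(A, k) {
  v <- A$variances[seq_len(k)]
  if (any(!is.finite(v)) || any(v < 0)) stop("invalid mode variances")
  v
}

#' Covariance overlap between two mode sets (Hess)
#'
#' Normalized similarity of the covariance matrices implied by two mode
#' sets with per-mode variances v (1/lambda for elastic models, sigma for
#' PCA):
#' Omega = 1 - sqrt\{ \[sum_i v_i^A + sum_j v_j^B
#'   - 2 sum_ij sqrt(v_i^A v_j^B) (p_i^A . p_j^B)^2\] /
#'   (sum_i v_i^A + sum_j v_j^B) \}.
#' Omega = 1 for identical dynamics, 0 for disjoint mode spaces; symmetric
#' in A and B and invariant to a common rescaling of all variances.
#'
#' @param A,B [mode_set()] objects on the same node dimension.
#' @param k number of leading modes to compare (default 20, the soft-mode
#'   range where family dynamics are most conserved).
#' @return Omega in \[0, 1\].
#' @export
covariance_overlap <- function(A, B, k = 20L) {
  if (nrow(A$vectors) != nrow(B$vectors))
    stop("mode sets live on different node dimensions")
  ka <- min(k, ncol(A$vectors)); kb <- min(k, ncol(B$vectors))
  va <- mode_variances(A, ka); vb <- mode_variances(B, kb)
  tot <- sum(va) + sum(vb)
  if (tot <= 0) stop("zero total variance")
  G <- crossprod(A$vectors[, seq_len(ka), drop = FALSE],
                 B$vectors[, seq_len(kb), drop = FALSE])
  cross <- sum(outer(sqrt(va), sqrt(vb)) * G^2)
  arg <- (tot - 2 * cross) / tot
  # identical mode sets cancel to rounding error; sqrt would amplify that
  # to ~1e-8, so snap below-noise arguments to zero
  if (arg < 1e-12) arg <- 0
  1 - sqrt(arg)
}

#' Signature fluctuation profile across a family
#'
#' Element-wise mean and population standard deviation of per-node scalar
#' profiles (for example MSFs or mode-shape magnitudes) over family
#' members aligned to a common core.
#'
#' @param members list of numeric vectors of equal length (one per family
#'   member).
#' @return object of class `signature_profile` with fields `mean`, `sd`
#'   (population convention: F = 1 gives all-zero sd), `n_members`.
#' @export
signature_profile <- function(members) {
  if (!length(members)) stop("need at least one member profile")
  len <- vapply(members, length, integer(1))
  if (length(unique(len)) != 1) stop("profiles differ in length")
  X <- do.call(rbind, members)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  structure(list(mean = mu, sd = sdv, n_members = length(members)),
            class = "signature_profile")
}

#' Dynamics distance matrix over family members
#'
#' d(i, j) = 1 - covariance_overlap(i, j, k): zero for identical dynamics,
#' one for disjoint mode spaces.
#'
#' @param members list of [mode_set()] objects on a shared common core.
#' @param k modes per comparison (default 20).
#' @param labels member labels (default m1, m2, ...).
#' @return object of class `dynamics_distance` wrapping a symmetric F x F
#'   matrix with zero diagonal.
#' @export
dynamics_distance_matrix <- function(members, k = 20L, labels = NULL) {
  f <- length(members)
  if (f < 2) stop("need at least two members")
  dims <- vapply(members, function(m) nrow(m$vectors), integer(1))
  if (length(unique(dims)) != 1)
    stop("members live on different cores; align them first")
  if (is.null(labels)) labels <- paste0("m", seq_len(f))
  D <- matrix(0, f, f, dimnames = list(labels, labels))
  for (i in seq_len(f - 1)) for (j in seq.int(i + 1, f)) {
    D[i, j] <- D[j, i] <- 1 - covariance_overlap(members[[i]], members[[j]], k)
  }
  structure(list(matrix = D, labels = labels, k = as.integer(k)),
            class = "dynamics_distance")
}

#' UPGMA tree from a distance matrix
#'
#' Size-weighted arithmetic-average agglomeration producing an ultrametric
#' rooted tree: each merge joins the pair at minimal average distance, at
#' height d/2; ties break by the lexicographically smallest label pair.
#'
#' @param D a `dynamics_distance` or symmetric numeric matrix with zero
#'   diagonal and labels in dimnames.
#' @return object of class `upgma_tree` with fields `newick` (string with
#'   branch lengths), `merges` (data.frame log of joins) and `heights`.
#' @export
upgma_tree <- function(D) {
  M <- if (inherits(D, "dynamics_distance")) D$matrix else as.matrix(D)
  if (!isSymmetric(unname(M), tol = 1e-12)) stop("distance matrix must be symmetric")
  labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(M)))
  f <- nrow(M)
  if (f < 2) stop("need at least two taxa")
  # active cluster state
  newick <- labels
  first <- labels            # lexicographically smallest leaf per cluster
  size <- rep(1L, f)
  height <- rep(0, f)
  act <- seq_len(f)
  merges <- data.frame(a = character(), b = character(), height = numeric())
  while (length(act) > 1) {
    na <- length(act)
    best <- NULL
    for (p in seq_len(na - 1)) for (q in seq.int(p + 1, na)) {
      d <- M[act[p], act[q]]
      key <- sort(c(first[act[p]], first[act[q]]))
      if (is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(p = act[p], q = act[q], d = d, key = key)
      }
    }
    h <- best$d / 2
    i <- best$p; j <- best$q
    bl_i <- h - height[i]; bl_j <- h - height[j]
    # order children by their smallest leaf for a deterministic string
    kids <- if (first[i] <= first[j])
      sprintf("%s:%.10g,%s:%.10g", newick[i], bl_i, newick[j], bl_j)
    else
      sprintf("%s:%.10g,%s:%.10g", newick[j], bl_j, newick[i], bl_i)
    merges <- rbind(merges, data.frame(a = first[i], b = first[j], height = h))
    # UPGMA update: size-weighted average distance to the new cluster
    others <- setdiff(act, c(i, j))
    for (o in others) {
      M[i, o] <- M[o, i] <- (size[i] * M[i, o] + size[j] * M[j, o]) /
        (size[i] + size[j])
    }
    newick[i] <- sprintf("(%s)", kids)
    size[i] <- size[i] + size[j]
    height[i] <- h
    first[i] <- min(first[i], first[j])
    act <- setdiff(act, j)
  }
  structure(list(newick = paste0(newick[act], ";"), merges = merges,
                 heights = merges$height, labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree>", x$newick, "\n")
  invisible(x)
}

#' Write a tree in Newick format
#' @param tree an `upgma_tree`.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, file) {
  writeLines(tree$newick, file)
  invisible(file)
}
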