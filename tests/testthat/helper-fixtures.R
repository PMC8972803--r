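# shared fixture builders; all randomness takes an explicit seed

random_nodeset <- function(n, seed, box = 10) {
  set.seed(seed)
  nodeset(matrix(runif(3 * n, 0, box), ncol = 3))
}

# a small two-residue C-alpha PDB as text lines
two_residue_pdb <- function() {
  c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
}

# 2 residues, 8 atoms total (backbone-ish), for all-atom selection
eight_atom_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.989   2.839   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.693   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.581   0.000  1.00  0.00           O",
    "END")
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

rotation_about_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# orthonormal mode matrix (dim x k) plus positive variances, seeded
random_mode_set <- function(dim, k, seed, kind = "PCA") {
  set.seed(seed)
  V <- qr.Q(qr(matrix(rnorm(dim * k), dim, k)))
  v <- sort(rexp(k), decreasing = TRUE) + 0.1
  mode_set(V, eigenvalues = 1 / v, variances = v, n_zero = 0L, kind = kind)
}

# density-weighted centroid of a grid's above-threshold voxels
grid_centroid <- function(grid, threshold = 0) {
  v <- as.vector(grid$values)
  sel <- which(v > threshold)
  ctr <- globaldyn:::voxel_centers(grid, sel)
  colSums(ctr * v[sel]) / sum(v[sel])
}
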