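#' Coarse-grained node set
#'
#' A `nodeset` holds one coarse-grained node per residue (or per atom): a
#' table of labels and an N x 3 matrix of Cartesian coordinates in Angstrom.
#' It is the elementary structure container used by every model in the
#' package, and flattens to the 3N coordinate vector
#' q = (x1, y1, z1, ..., xN, yN, zN) used by the elastic network and PCA
#' machinery.
#'
#' @param coords numeric N x 3 matrix of coordinates (Angstrom).
#' @param labels optional data.frame with columns `chain`, `resno`, `resname`
#'   and `insert`; defaults to chain "A", sequential numbering.
#' @return an object of class `nodeset`.
#' @export
nodeset <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 1) stop("a nodeset needs at least one node")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(labels)) {
    labels <- data.frame(chain = rep("A", n), resno = seq_len(n),
                         resname = rep("ALA", n), insert = rep("", n),
                         stringsAsFactors = FALSE)
  }
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  for (col in c("chain", "resno", "resname", "insert")) {
    if (is.null(labels[[col]]))
      labels[[col]] <- switch(col, chain = "A", resno = seq_len(n),
                              resname = "ALA", insert = "")
  }
  labels$insert[is.na(labels$insert)] <- ""
  if (nrow(labels) != n) stop("labels and coords disagree on N")
  key <- node_keys(labels)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, insertion code) labels")
  dimnames(coords) <- NULL
  structure(list(coords = coords, labels = labels), class = "nodeset")
}

node_keys <- function(labels) {
  key <- paste(labels$chain, labels$resno, labels$insert, sep = ":")
  # atom-resolution node sets (all-atom selection) disambiguate by atom name
  if (!is.null(labels$atom)) key <- paste(key, labels$atom, sep = ":")
  key
}

#' @export
print.nodeset <- function(x, ...) {
  cat(sprintf("<nodeset> %d nodes, %d chain(s)\n",
              nrow(x$coords), length(unique(x$labels$chain))))
  invisible(x)
}

#' Number of nodes
#' @param x a nodeset or ensemble.
#' @return integer node count.
#' @export
n_nodes <- function(x) {
  if (inherits(x, "nodeset")) nrow(x$coords)
  else if (inherits(x, "gd_ensemble")) dim(x$coords)[2]
  else stop("unsupported type")
}

#' Flatten a nodeset to its 3N coordinate vector
#'
#' Interleaved per node: (x1, y1, z1, x2, y2, z2, ...). The inverse is
#' [coordinate_matrix()].
#'
#' @param nodes a `nodeset` or an N x 3 matrix.
#' @return numeric vector of length 3N.
#' @export
to_coordinate_vector <- function(nodes) {
  m <- if (inherits(nodes, "nodeset")) nodes$coords else as.matrix(nodes)
  as.vector(t(m))
}

#' Reshape a 3N coordinate vector back to an N x 3 matrix
#' @param q numeric vector with length divisible by 3.
#' @return N x 3 matrix.
#' @export
coordinate_matrix <- function(q) {
  if (length(q) %% 3 != 0) stop("coordinate vector length must be 3N")
  matrix(q, ncol = 3, byrow = TRUE)
}

# minimal fixed-width sanity check so malformed ATOM records fail with the
# offending line number rather than propagating NA coordinates
validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: fewer than 54 columns", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinates", i))
  }
  invisible(TRUE)
}

# altloc resolution: among records sharing (chain, resno, insert, atom name)
# keep the highest occupancy; ties (and missing occupancies) go to the first
# record in file order
resolve_altloc <- function(atom) {
  if (all(atom$alt %in% c("", " ", NA))) return(atom)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = ":")
  occ <- atom$o
  occ[is.na(occ)] <- 0
  keep <- unlist(lapply(split(seq_len(nrow(atom)), key)[unique(key)],
                        function(idx) idx[which.max(occ[idx])]))
  atom[sort(keep), , drop = FALSE]
}

atom_table_from_pdb <- function(pdb, selection) {
  atom <- pdb$atom
  atom$row_ <- seq_len(nrow(atom))   # row index into pdb$xyz triplets
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- "A"
  atom <- resolve_altloc(atom)
  if (selection == "calpha") {
    atom <- atom[atom$elety == "CA" & atom$resid != "HOH", , drop = FALSE]
  }
  if (nrow(atom) == 0)
    stop(sprintf("empty selection: no atoms match '%s'", selection))
  atom
}

#' Read a structure from a PDB file
#'
#' Parses fixed-width ATOM/HETATM records (via bio3d), resolves alternate
#' locations to the highest-occupancy record (first record wins ties) and
#' coarse-grains to one node per selected atom, in file order. For
#' multi-MODEL files only the first model is returned; use
#' [read_ensemble()] to get one ensemble member per model.
#'
#' @param path path to a PDB file.
#' @param selection `"calpha"` (default, one node per residue at the C-alpha)
#'   or `"all"` (every atom record).
#' @return a [nodeset()].
#' @export
read_structure <- function(path, selection = c("calpha", "all")) {
  selection <- match.arg(selection)
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  atom <- atom_table_from_pdb(pdb, selection)
  nodeset(as.matrix(atom[, c("x", "y", "z")]),
          pdb_labels(atom, selection))
}

pdb_labels <- function(atom, selection) {
  labs <- data.frame(chain = atom$chain, resno = atom$resno,
                     resname = atom$resid, insert = atom$insert,
                     stringsAsFactors = FALSE)
  if (selection == "all") labs$atom <- atom$elety
  labs
}

#' Write a nodeset as a PDB file
#'
#' One ATOM record per node. The B-factor column can carry an arbitrary
#' per-node scalar (for example a mean-square fluctuation profile); values
#' are clamped to the PDB field range \[0, 999.99\].
#'
#' @param nodes a [nodeset()].
#' @param file output path.
#' @param bfactor optional numeric per-node scalar for the B-factor column.
#' @return invisibly, the output path.
#' @export
write_structure <- function(nodes, file, bfactor = NULL) {
  n <- n_nodes(nodes)
  b <- if (is.null(bfactor)) rep(0, n) else pmin(pmax(bfactor, 0), 999.99)
  if (length(b) != n) stop("bfactor length must equal N")
  bio3d::write.pdb(file = file, xyz = to_coordinate_vector(nodes),
                   resno = nodes$labels$resno, chain = nodes$labels$chain,
                   resid = nodes$labels$resname, insert = nodes$labels$insert,
                   elety = rep("CA", n), b = b)
  invisible(file)
}

#' Aligned conformational ensemble
#'
#' M conformations over a shared set of N nodes, stored as an M x N x 3
#' array, plus an M x N logical presence mask. Columns flagged absent in any
#' member are excluded from "common core" analyses (superposition means,
#' covariances).
#'
#' @param coords M x N x 3 numeric array (Angstrom). Entries for absent
#'   nodes may be NA.
#' @param labels node label data.frame as in [nodeset()].
#' @param mask optional M x N logical; defaults to all-present.
#' @param reference index of the reference member (default 1).
#' @return an object of class `gd_ensemble`.
#' @export
gd_ensemble <- function(coords, labels = NULL, mask = NULL, reference = 1L) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an M x N x 3 array")
  m <- dim(coords)[1]; n <- dim(coords)[2]
  if (m < 1 || n < 1) stop("ensemble needs M >= 1 and N >= 1")
  if (is.null(mask)) mask <- matrix(TRUE, m, n)
  if (!all(dim(mask) == c(m, n))) stop("mask must be M x N")
  if (is.null(labels))
    labels <- data.frame(chain = rep("A", n), resno = seq_len(n),
                         resname = rep("ALA", n), insert = rep("", n),
                         stringsAsFactors = FALSE)
  structure(list(coords = coords, labels = labels, mask = mask,
                 reference = as.integer(reference)),
            class = "gd_ensemble")
}

#' @export
print.gd_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> M=%d members, N=%d nodes, core=%d\n",
              dim(x$coords)[1], dim(x$coords)[2], sum(core_columns(x))))
  invisible(x)
}

#' Number of ensemble members
#' @param ensemble a `gd_ensemble`.
#' @return integer M.
#' @export
n_members <- function(ensemble) dim(ensemble$coords)[1]

#' Common-core column flags
#'
#' A column belongs to the common core when it is present in every member.
#'
#' @param ensemble a `gd_ensemble`.
#' @return logical vector of length N.
#' @export
core_columns <- function(ensemble) apply(ensemble$mask, 2, all)

#' Extract one member as a nodeset
#' @param ensemble a `gd_ensemble`.
#' @param i member index.
#' @param core_only drop non-core columns (default FALSE).
#' @return a [nodeset()].
#' @export
ensemble_member <- function(ensemble, i, core_only = FALSE) {
  keep <- if (core_only) core_columns(ensemble) else rep(TRUE, dim(ensemble$coords)[2])
  nodeset(ensemble$coords[i, keep, , drop = TRUE],
          ensemble$labels[keep, , drop = FALSE])
}

#' Build an ensemble from a list of structures
#'
#' Without an alignment every member must carry an identical label sequence.
#' With an alignment table, members are mapped onto common-core columns; a
#' column with no residue in some member is flagged absent in the mask and
#' excluded from downstream covariance analysis.
#'
#' @param structures list of [nodeset()] objects.
#' @param alignment optional data.frame with columns `member` (index into
#'   `structures`), `column` (core column index), `chain`, `resno` and
#'   optionally `insert`, mapping member residues to core columns. Each core
#'   column maps to at most one residue per member.
#' @return a [gd_ensemble()].
#' @export
build_ensemble <- function(structures, alignment = NULL) {
  if (!length(structures)) stop("need at least one structure")
  if (is.null(alignment)) {
    ns <- vapply(structures, n_nodes, integer(1))
    if (length(unique(ns)) != 1)
      stop(sprintf("members have inconsistent node counts (%s); supply an alignment",
                   paste(unique(ns), collapse = ", ")))
    keys <- lapply(structures, function(s) node_keys(s$labels))
    if (!all(vapply(keys[-1], identical, logical(1), keys[[1]])))
      stop("members have differing labels; supply an alignment")
    m <- length(structures); n <- ns[1]
    coords <- array(NA_real_, c(m, n, 3))
    for (i in seq_len(m)) coords[i, , ] <- structures[[i]]$coords
    return(gd_ensemble(coords, structures[[1]]$labels))
  }
  alignment <- as.data.frame(alignment, stringsAsFactors = FALSE)
  if (is.null(alignment$insert)) alignment$insert <- ""
  alignment$insert[is.na(alignment$insert)] <- ""
  m <- length(structures)
  n <- max(alignment$column)
  coords <- array(NA_real_, c(m, n, 3))
  mask <- matrix(FALSE, m, n)
  labels <- data.frame(chain = rep("A", n), resno = seq_len(n),
                       resname = rep("UNK", n), insert = rep("", n),
                       stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    rows <- alignment[alignment$member == i, , drop = FALSE]
    if (anyDuplicated(rows$column))
      stop(sprintf("member %d maps more than one residue to a core column", i))
    skey <- node_keys(structures[[i]]$labels)
    akey <- paste(rows$chain, rows$resno, rows$insert, sep = ":")
    idx <- match(akey, skey)
    if (anyNA(idx))
      stop(sprintf("alignment references unknown residue(s) in member %d: %s",
                   i, paste(akey[is.na(idx)], collapse = ", ")))
    coords[i, rows$column, ] <- structures[[i]]$coords[idx, , drop = FALSE]
    mask[i, rows$column] <- TRUE
    labels[rows$column, ] <- structures[[i]]$labels[idx, c("chain", "resno", "resname", "insert")]
  }
  gd_ensemble(coords, labels, mask)
}

#' Read a multi-MODEL PDB file as an ensemble
#'
#' Each MODEL record becomes one ensemble member; all models must share the
#' same atoms.
#'
#' @inheritParams read_structure
#' @return a [gd_ensemble()].
#' @export
read_ensemble <- function(path, selection = c("calpha", "all")) {
  selection <- match.arg(selection)
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  atom <- atom_table_from_pdb(pdb, selection)
  sel_xyz <- as.vector(t(cbind((atom$row_ - 1) * 3 + 1,
                               (atom$row_ - 1) * 3 + 2,
                               (atom$row_ - 1) * 3 + 3)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  m <- nrow(xyz); n <- nrow(atom)
  coords <- array(NA_real_, c(m, n, 3))
  for (i in seq_len(m))
    coords[i, , ] <- matrix(xyz[i, sel_xyz], ncol = 3, byrow = TRUE)
  gd_ensemble(coords, pdb_labels(atom, selection))
}

#' Write an ensemble as a multi-MODEL PDB file
#' @param ensemble a [gd_ensemble()].
#' @param file output path.
#' @return invisibly, the output path.
#' @export
write_ensemble <- function(ensemble, file) {
  m <- n_members(ensemble)
  n <- dim(ensemble$coords)[2]
  xyz <- matrix(NA_real_, m, 3 * n)
  for (i in seq_len(m)) xyz[i, ] <- as.vector(t(ensemble$coords[i, , ]))
  xyz[is.na(xyz)] <- 0
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = ensemble$labels$resno, chain = ensemble$labels$chain,
                   resid = ensemble$labels$resname,
                   insert = ensemble$labels$insert,
                   elety = rep("CA", n))
  invisible(file)
}
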