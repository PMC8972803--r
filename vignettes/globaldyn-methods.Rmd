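---
title: "Models and methods behind globaldyn"
author: "globaldyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind globaldyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globaldyn)
```

# Scope

`globaldyn` analyses the slow, collective ("global") motions of protein
structures at coarse resolution. It covers five connected method families:
elastic network normal mode analysis (ANM/GNM), essential-dynamics PCA of
structural ensembles, comparative signature dynamics across families,
vibrational subsystem analysis, and neural-gas pseudoatom fitting of
density maps. This vignette documents the models, every tunable parameter
that matters, the numerical conventions, what the synthetic fixtures do
and do not emulate, and the design choices made where the design was
genuinely open.

# Elastic network models

A structure is one node per residue (at the C-alpha) or per atom, flattened
to the coordinate vector $q \in \mathbb{R}^{3N}$ in interleaved order
$(x_1, y_1, z_1, \dots)$ — interleaving keeps each node a contiguous
3-block, matching the 3×3 super-element structure of the Hessian.

The ANM treats the observed structure as an energy minimum of the harmonic
potential $V = (\gamma/2)\sum_{r^0_{ij} \le r_c} (r_{ij} - r^0_{ij})^2$.
Its Hessian has off-diagonal super-elements
$H_{ij} = -(\gamma/(r^0_{ij})^2)\, x^0_{ij} (x^0_{ij})^\top$ inside the
cutoff and diagonal blocks $H_{ii} = -\sum_{j \ne i} H_{ij}$, which makes
$H$ symmetric, positive semi-definite, and exactly translation-invariant.
The GNM replaces this with the $N \times N$ Kirchhoff (graph Laplacian)
matrix of the contact network and reports isotropic fluctuation magnitudes
only.

Parameters, units and defaults:

* `gamma` (force constant) — 1 in reduced units. It only scales energies
  and inverse variances; fluctuations are reported in $k_BT/\gamma = 1$
  units.
* `r_cut` — 15 Å (ANM) and 10 Å (GNM). These are the standard
  residue-level literature defaults for the two models; they must grow
  with coarser graining (see pseudoatoms below).
* Zero-mode tolerance — an eigenvalue below $10^{-6}\lambda_{max}$ counts
  as a rigid-body mode. The count is sanity-checked against the
  expectation (6 for ANM, 1 for GNM) and a warning is raised on mismatch
  rather than silently proceeding: collinear geometries and disconnected
  contact graphs legitimately have larger null spaces, and the two-node
  toy system has only one internal mode (5 zero modes), not $3N-6 = 0$.
* Eigenvector sign — the largest-magnitude component of each mode is made
  positive, so outputs are identical across eigensolvers.
* Modes are sorted ascending by eigenvalue after zero-mode removal, so
  "mode 1" is the softest internal motion (what full-atom numbering would
  call mode 7).

`msf()` reports per-node mean-square fluctuations,
$\mathrm{MSF}_i = \sum_k \lambda_k^{-1} \lVert p_k^{(i)}\rVert^2$ for ANM.
For GNM we report $3\,(\Gamma^+)_{ii}$: the Kirchhoff pseudo-inverse gives
a per-coordinate isotropic variance, and the factor 3 converts it to a
per-node value so ANM and GNM profiles are on the same scale. This
convention is a package choice and is stated here because both
conventions circulate in the literature.

# Vibrational subsystem analysis

`vsa_reduce()` integrates environment degrees of freedom out of the
Hessian with the generalized Schur complement
$H_\mathrm{eff} = H_{ss} - H_{se} H_{ee}^{+} H_{es}$, the standard remedy
for "tip effects" where floppy termini or loops dominate the soft modes.
The pseudo-inverse is used for $H_{ee}$ because the environment block of a
free network can be singular.

A subtlety worth recording: for a free (unanchored) network the naive
identity "$\mathrm{pinv}(H_\mathrm{eff})$ equals the subsystem block of
$\mathrm{pinv}(H)$" is **false**, because the two Moore–Penrose inverses
remove different rigid-body null spaces (those of the full system vs those
of the subsystem), and the restriction of a vector orthogonal to the full
rigid space is not orthogonal to the subsystem's rigid space. The exact
statement, which the package tests enforce to $10^{-8}$ (it holds to
machine precision), is the rigid-projected identity

$$\mathrm{pinv}(H_\mathrm{eff}) = P\, [\mathrm{pinv}(H)]_{ss}\, P,$$

where $P$ projects out the subsystem's six rigid-body motions. Physically:
VSA preserves all *internal* subsystem covariances; the rigid components
are frame bookkeeping, not dynamics.

# Essential dynamics of ensembles

Ensembles are built over a common set of columns, either from structures
with identical labels or through a user-supplied alignment table; columns
absent from any member are masked out of all "common core" analyses.
`iterative_superpose()` alternates Kabsch fits of every member onto the
running mean with mean updates until the mean moves by less than `tol`
(default $10^{-5}$ Å, far below PDB coordinate precision) or `max_iter`
(50) is reached; non-convergence is flagged, not raised. The initial
reference is the ensemble's reference member (member 1 by default) for
determinism. Kabsch rotations are always proper: when the SVD solution is
a reflection the smallest singular direction is flipped.

The covariance uses the $1/M$ normalization (the average of deviation
outer products), switchable to $1/(M-1)$. PCA is taken about the ensemble
mean; at most $\min(3N, M-1)$ components are non-zero, minus the ~6 rigid
degrees removed by superposition. Projections are reported in Å along
unit modes; dividing by $\sqrt{N}$ converts a score to the RMSD that
component contributes.

`generate_conformer()` supports two coefficient conventions: raw Å along
unit modes, or a *variance fraction* where coefficient $f$ displaces by
$\sqrt{f\,\sigma_k}$ — an r.m.s. amplitude carrying a fraction $f$ of the
mode's variance. The fraction reading is the package default
interpretation for phrases like "1/8 of its variance"; both are exposed
because the amplitude-vs-variance reading is a genuine ambiguity.

`landscape_density()` estimates occupancy of the 2-D projection space by
histogram (25×25 bins) or Gaussian KDE (Scott's rule bandwidth,
$\hat\sigma M^{-1/6}$ per axis), and converts to relative free energy
$G = -\ln(\rho/\rho_{max})$ in $k_BT$, with empty bins at $+\infty$. These
are first sketches of a landscape; they are only meaningful for large,
unbiased ensembles.

# Signature dynamics

Mode similarity uses the absolute correlation cosine (eigenvector sign is
arbitrary). Mode matching is greedy on the overlap matrix — repeatedly
take the global maximum among unmatched rows/columns, ties broken to the
lowest row then column index — which is deterministic and easy to verify
exhaustively. Family-level comparison uses Hess's covariance overlap
$\Omega$ over the leading $k$ modes with variances $1/\lambda$ (ENM) or
$\sigma$ (PCA); $k$ defaults to 20, emphasising the soft modes where
family dynamics are most conserved, and is exposed everywhere. Note that
truncations that cut through a *degenerate* eigenvalue block are
basis-dependent; symmetric structures should be compared with $k$ spanning
whole blocks (or all modes).

The dynamics distance is $d = 1 - \Omega$, the simplest monotone choice,
and trees are built by UPGMA (size-weighted average linkage) with a
lexicographic tie-break on the smallest leaf label of each cluster, giving
ultrametric, bit-reproducible Newick output. Neighbour joining is out of
scope. One numerical convention: for identical mode sets the $\Omega$
radicand cancels to rounding error and the square root would amplify
$10^{-16}$ to $10^{-8}$, so radicands below $10^{-12}$ are snapped to zero.

# Pseudoatoms from density maps

`read_density()`/`write_density()` implement MRC2014 (modes 0/1/2, both
endiannesses, arbitrary axis order normalized to x-fastest storage,
voxel-center origin convention in Å). `synth_density()` renders a
structure as a sum of isotropic Gaussians with
$\sigma = \mathrm{resolution}/(2\sqrt{2\ln 2})$ (FWHM = nominal
resolution), each normalized to its weight, and requires
voxel ≤ resolution/2 for adequate sampling.

`trn_fit()` is the annealed neural-gas rule: sample a point from the
above-threshold voxels with probability proportional to density (with
within-voxel jitter, on by default, to avoid lattice-locked codebooks),
rank all K codebooks by distance, and move each by
$\varepsilon(t)\,e^{-\mathrm{rank}/\lambda(t)}(x - w)$ with exponential
decay of $\varepsilon$ from 0.3 to 0.005 and of $\lambda$ from $K/3$ to
0.01 over $\max(200K, 2000)$ steps. The final rate and the step floor
follow the original neural-gas literature; this matters quantitatively
because the converged codebook position is effectively an annealed average
over roughly $2/\varepsilon_f$ samples, so a final rate of 0.05 would
leave each codebook jittering by a sizeable fraction of the local density
spread (about $\sigma/6$ per axis), visibly degrading centroid recovery,
whereas 0.005 brings it well under half a voxel for the map scales used
here. Weights are assigned post hoc as the density mass of each codebook's
Voronoi cell, so they conserve the total above-threshold mass exactly, and
the whole fit is bit-reproducible from its seed. The threshold defaults to
0 (all strictly positive density); real maps should use an absolute
threshold above their noise floor.

`pseudoatom_anm()` hands the codebook positions to the ANM with a cutoff
of 2.0 × the mean nearest-neighbour codebook distance, because ENM cutoffs
must scale with the coarse-graining level; the residue-level 15 Å default
would be meaningless between pseudoatoms tens of Å apart. K is a required
user input; the package does not try to choose it.

# Synthetic fixtures and what they show

All generators take explicit seeds (never global RNG state) and attach
their planted ground truth to the object (`write_truth()` serializes it).

* `make_lattice_structure()` — a cubic lattice with C-alpha-like 3.8 Å
  spacing: the simplest non-collinear, connected geometry with exactly
  known distances. Note its point-group symmetry produces degenerate ANM
  eigenvalues (see the truncation caveat above).
* `make_two_state_ensemble()` — two conformations at
  $\pm(\mathrm{amplitude}/2)$ along a planted unit 3N direction plus
  i.i.d. isotropic Gaussian coordinate noise. With zero noise the
  covariance is rank 1 with eigenvalue $\mathrm{amplitude}^2/4$ under the
  $1/M$ convention. `random_internal_direction()` supplies the natural
  planted direction: a random unit vector with the six rigid-body
  components projected out, since a genuine conformational change carries
  no net rigid motion and superposition would silently strip any rigid
  component from a naive random direction, biasing recovery scores
  (by about $\sqrt{6/3N}$ in overlap).
* `make_blob_map()` — Gaussian blobs with explicit σ. The package's
  reference conditions for fitting demonstrations are σ = 2 Å blobs on a
  1 Å grid (≈4.7 Å FWHM features, 1 Å sampling, the regime pseudoatom
  pipelines target), with well-separated centers 20 Å apart.

The standard recovery conditions used throughout the tests are: N = 64
nodes, M = 50 members, amplitude 4 Å with the total noise-vector norm at
amplitude/10 (per-coordinate σ = 0.4/√(3N) ≈ 0.029 Å). Under these
conditions PC1 recovers the planted direction with overlap > 0.99 and
> 90% of the variance. The noise magnitude is deliberately stated as a
*vector norm*: with a per-coordinate σ of amplitude/10 the accumulated
noise variance $3N\sigma^2$ would dwarf the planted signal
($a^2/4$), capping the PC1 variance fraction near 0.13 — a useful reminder
that in 3N dimensions "10:1 signal-to-noise" must be a statement about
totals, not per-coordinate scales.

What the fixtures do **not** emulate: real protein geometry (chain
connectivity, secondary structure, side chains), anisotropic or
position-dependent experimental noise, map solvent noise and B-factor
falloff, or insertions/deletions beyond what the alignment-table path
exercises. Passing tests therefore demonstrate the correctness of the
algorithms and their contracts, not field performance on experimental
ensembles.

# Numerical choices and degenerate inputs

* Altloc records resolve to the highest occupancy, ties to the first
  record in file order; insertion codes are preserved in labels.
* Coincident nodes (< $10^{-6}$ Å) are a hard error for ENM construction.
* Collinear structures warn (rotation about the axis is undefined) but
  still return the least-squares solution.
* Disconnected contact graphs are allowed with a warning; the zero-mode
  count grows with the component count.
* Dense symmetric `eigen()` is used throughout; problem sizes in the
  package's tests (N ≤ 64, maps ≤ 51³ voxels, 1000-trial property loops)
  keep the full suite under ~20 s and the acceptance script under ~10 s.

# Known limitations

* No mmCIF input; PDB fixed-width only (via bio3d).
* No sequence/structure alignment computation — alignment tables are
  inputs, produced elsewhere.
* No MD trajectory readers, no adaptive transition sampling, no
  distance-dependent force constants, no membrane lattice models, no
  GMM-based pseudoatom fitting; these are adjacent methods, not part of
  this package's scope.
* UPGMA assumes roughly ultrametric dissimilarities; strongly non-clock
  dynamics distances will distort branch lengths (topology is still
  well-defined).
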