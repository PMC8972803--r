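test_that("deformation vectors subtract coordinates after superposition", {
  a <- random_nodeset(9, seed = 31)
  expect_equal(deformation_vector(a, a)$values, rep(0, 27))
  b <- nodeset(a$coords + rep(c(1, 0, 0), each = 9))
  dv <- deformation_vector(a, b, superpose = FALSE)
  expect_equal(dv$values[seq(1, 27, 3)], rep(1, 9))
  expect_equal(dv$values[-seq(1, 27, 3)], rep(0, 18))
  rot <- nodeset(sweep(a$coords %*% t(random_rotation(3)), 2, c(2, -1, 0), "+"))
  expect_lt(sqrt(sum(deformation_vector(a, rot)$values^2)), 1e-8)
})

test_that("morphs hit both endpoints and move monotonically", {
  a <- random_nodeset(7, seed = 32)
  set.seed(33)
  b <- nodeset(a$coords + matrix(rnorm(21), ncol = 3))
  two <- morph(a, b, n_frames = 2, superpose = FALSE)
  expect_equal(two$coords[1, , ], a$coords, ignore_attr = TRUE)
  expect_equal(two$coords[2, , ], b$coords, ignore_attr = TRUE)

  three <- morph(a, b, n_frames = 3, superpose = FALSE)
  expect_equal(three$coords[2, , ], (a$coords + b$coords) / 2,
               ignore_attr = TRUE)

  eleven <- morph(a, b, n_frames = 11)
  d <- vapply(1:11, function(t) rmsd(eleven$coords[t, , ], a$coords), numeric(1))
  expect_true(all(diff(d) > 0))
  bs <- kabsch_superpose(b, a)$nodes
  expect_equal(eleven$coords[11, , ], bs$coords, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(morph(a, b, n_frames = 1), "2 frames")
})

test_that("ensemble covariance follows the 1/M average of outer products", {
  a <- random_nodeset(5, seed = 34)
  idem <- build_ensemble(replicate(4, a, simplify = FALSE))
  expect_equal(max(abs(ensemble_covariance(idem)$matrix)), 0)

  # two members at mean +/- d/2 along a fixed direction: C = (1/4) d d^T
  set.seed(35)
  delta <- rnorm(15)
  qa <- to_coordinate_vector(a)
  coords <- array(NA_real_, c(2, 5, 3))
  coords[1, , ] <- coordinate_matrix(qa + delta / 2)
  coords[2, , ] <- coordinate_matrix(qa - delta / 2)
  pair <- gd_ensemble(coords)
  C <- ensemble_covariance(pair)
  expect_equal(C$matrix, tcrossprod(delta) / 4, tolerance = 1e-10)
  expect_equal(qr(C$matrix)$rank, 1)

  # trace identity: total variance
  ens <- make_two_state_ensemble(a, delta, 2, 0.3, M = 16, seed = 36)
  Ce <- ensemble_covariance(ens)
  expect_equal(sum(diag(Ce$matrix)), ensemble_variance(ens), tolerance = 1e-10)
})

test_that("covariance refuses single-member ensembles", {
  a <- random_nodeset(4, seed = 37)
  one <- build_ensemble(list(a))
  expect_error(ensemble_covariance(one), "M >= 2")
})

test_that("PCA recovers a planted rank-1 covariance exactly", {
  base <- random_nodeset(6, seed = 38)
  set.seed(39)
  delta <- rnorm(18)
  ens <- make_two_state_ensemble(base, delta, amplitude = 3,
                                 noise_sigma = 0, M = 10, seed = 40)
  C <- ensemble_covariance(ens)
  pm <- pca_modes(C)
  u <- delta / sqrt(sum(delta^2))
  expect_gt(abs(sum(pm$vectors[, 1] * u)), 1 - 1e-10)
  expect_equal(pm$variance_fraction[1], 1.0, tolerance = 1e-8)
  expect_equal(pm$eigenvalues[1], 3^2 / 4, tolerance = 1e-10)
})

test_that("PCA eigenvalues conserve the total variance", {
  base <- random_nodeset(5, seed = 41)
  set.seed(42)
  ens <- make_two_state_ensemble(base, rnorm(15), 2, 0.4, M = 20, seed = 43)
  C <- ensemble_covariance(ens)
  pm <- pca_modes(C)
  expect_equal(sum(pm$eigenvalues), sum(diag(C$matrix)), tolerance = 1e-10)
  expect_lte(sum(pm$eigenvalues > 1e-10 * pm$eigenvalues[1]), 20 - 1)
})

test_that("PCA on an ENM-derived covariance recovers the ENM modes", {
  nodes <- random_nodeset(8, seed = 44)
  em <- compute_modes(build_anm_hessian(nodes))
  C <- covariance_from_modes(em)
  pm <- pca_modes(structure(list(matrix = C, mean = nodes, M = 99L),
                            class = "covariance_matrix"),
                  n = ncol(em$vectors))
  # overlap matrix is a signed permutation within degenerate blocks
  O <- overlap_matrix(pm, em)
  expect_equal(sort(apply(O, 1, max), decreasing = TRUE), rep(1, ncol(O)),
               tolerance = 1e-6)
  expect_equal(colSums(O^2), rep(1, ncol(O)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("projections are orthonormal coordinates with full reconstruction", {
  base <- make_lattice_structure(2)
  set.seed(45)
  ens <- make_two_state_ensemble(base, rnorm(24), 3, 0.2, M = 12, seed = 46)
  sup <- iterative_superpose(ens)
  C <- ensemble_covariance(sup$ensemble)
  pm <- pca_modes(C)
  proj <- project_ensemble(sup$ensemble, pm)

  # mean structure projects to the origin
  mean_ens <- gd_ensemble(array(rep(t(C$mean$coords), 1), c(1, 8, 3)))
  mean_ens$coords[1, , ] <- C$mean$coords
  p0 <- project_ensemble(mean_ens, pm)
  expect_lt(max(abs(p0$coordinates)), 1e-10)

  # conformer at mean + c * p1 projects to (c, 0, ..., 0)
  conf <- generate_conformer(C$mean, pm, 1.7)
  ce <- gd_ensemble(array(0, c(1, 8, 3)))
  ce$coords[1, , ] <- conf$coords
  pc <- project_ensemble(ce, pm)
  expect_equal(pc$coordinates[1, 1], 1.7, tolerance = 1e-10)
  expect_lt(max(abs(pc$coordinates[1, -1])), 1e-8)

  # full-rank reconstruction
  qmu <- to_coordinate_vector(C$mean)
  for (i in seq_len(n_members(ens))) {
    rec <- qmu + as.vector(pm$vectors %*% proj$coordinates[i, ])
    expect_lt(max(abs(rec - to_coordinate_vector(sup$ensemble$coords[i, , ]))),
              1e-8)
  }
})

test_that("conformer generation displaces by |c|/sqrt(N) rmsd and mirrors", {
  nodes <- random_nodeset(9, seed = 47)
  em <- compute_modes(build_anm_hessian(nodes))
  ref <- nodes
  expect_equal(generate_conformer(ref, em, c(0, 0))$coords, ref$coords)
  cplus <- generate_conformer(ref, em, 2.4)
  expect_equal(rmsd(cplus, ref), 2.4 / sqrt(9), tolerance = 1e-10)
  cminus <- generate_conformer(ref, em, -2.4)
  expect_equal(cplus$coords - ref$coords, -(cminus$coords - ref$coords),
               tolerance = 1e-12)
  # variance-fraction scaling: f of the mode variance -> sqrt(f sigma)
  cf <- generate_conformer(ref, em, 1 / 8, variance_fraction = TRUE)
  expect_equal(rmsd(cf, ref), sqrt(em$variances[1] / 8) / sqrt(9),
               tolerance = 1e-10)
  expect_error(generate_conformer(ref, em, rep(1, 99)), "coefficients")
})

test_that("landscape densities normalize and find planted basins", {
  pts <- matrix(rep(c(1.5, -2), each = 20), ncol = 2)
  h <- landscape_density(pts, "histogram", bins = 9)
  expect_equal(sum(h$density), 1, tolerance = 1e-6)
  expect_equal(sum(h$density > 0), 1)      # all mass in one bin
  expect_equal(min(h$free_energy), 0)

  set.seed(48)
  two <- rbind(cbind(rnorm(200, -5, 0.5), rnorm(200, 0, 0.5)),
               cbind(rnorm(200, 5, 0.5), rnorm(200, 0, 0.5)))
  for (meth in c("histogram", "kde")) {
    d <- landscape_density(two, meth, bins = 25)
    total <- if (meth == "histogram") sum(d$density)
             else sum(d$density) * diff(d$x[1:2]) * diff(d$y[1:2])
    expect_equal(total, 1, tolerance = 1e-6)
    # local maxima land within one bin of the planted centers
    z <- d$density
    locmax <- which(z == max(z), arr.ind = TRUE)[1, ]
    expect_lt(abs(abs(d$x[locmax[1]]) - 5), 2 * diff(d$x[1:2]))
  }
  expect_error(landscape_density(two[, 1, drop = FALSE]), "k = 2")
})
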