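test_that("MRC2014 round-trip preserves values, origin and voxel size", {
  grid <- make_blob_map(rbind(c(10, 0, 0)), sigma = 2, voxel = 1)
  f <- tempfile(fileext = ".mrc")
  write_density(grid, f)
  back <- read_density(f)
  expect_equal(back$values, grid$values, tolerance = 1e-6)
  expect_equal(back$origin, grid$origin, tolerance = 1e-5)
  expect_equal(back$voxel, grid$voxel, tolerance = 1e-6)
})

test_that("truncated MRC files raise a format error", {
  grid <- make_blob_map(rbind(c(0, 0, 0)), sigma = 2, voxel = 2)
  f <- tempfile(fileext = ".mrc")
  write_density(grid, f)
  sz <- file.size(f)
  raw <- readBin(f, "raw", sz)
  f2 <- tempfile(fileext = ".mrc")
  writeBin(raw[1:(sz - 200)], f2)
  expect_error(read_density(f2), "truncated data")
  f3 <- tempfile(fileext = ".mrc")
  writeBin(raw[1:100], f3)
  expect_error(read_density(f3), "truncated header")
})

test_that("non-canonical axis order is normalized on read", {
  grid <- make_blob_map(rbind(c(4, 0, 0), c(-4, 2, 1)), sigma = 2, voxel = 2)
  f <- tempfile(fileext = ".mrc")
  write_density(grid, f)
  # rewrite the header axis codes to (z, x, y) and permute data to match
  raw <- readBin(f, "raw", file.size(f))
  con <- file(f, "wb")
  arr <- aperm(grid$values, c(3, 1, 2))
  d <- dim(arr)
  writeBin(raw, con)
  seek(con, 0); writeBin(as.integer(d), con, size = 4, endian = "little")
  seek(con, 64); writeBin(as.integer(c(3, 1, 2)), con, size = 4, endian = "little")
  seek(con, 1024)
  writeBin(as.vector(arr), con, size = 4, endian = "little")
  close(con)
  back <- read_density(f)
  expect_equal(back$values, grid$values, tolerance = 1e-6)
})

test_that("synthetic density maps integrate to the node weights", {
  one <- random_nodeset(1, seed = 61)
  g <- synth_density(one, resolution = 6, voxel = 2, pad = 12)
  peak <- arrayInd(which.max(g$values), dim(g$values))
  center <- g$origin + (peak - 1) * g$voxel
  expect_lt(max(abs(center - one$coords[1, ])), max(g$voxel))

  several <- random_nodeset(5, seed = 62)
  gs <- synth_density(several, resolution = 6, voxel = 1.5, pad = 10,
                      weights = c(1, 2, 3, 4, 5))
  integral <- sum(gs$values) * prod(gs$voxel)
  expect_equal(integral, 15, tolerance = 0.01 * 15)

  # mirror symmetry for two identical nodes
  twin <- nodeset(rbind(c(-3, 0, 0), c(3, 0, 0)))
  gt <- synth_density(twin, resolution = 4, voxel = 1, pad = 8)
  flipped <- gt$values[dim(gt$values)[1]:1, , ]
  expect_lt(max(abs(gt$values - flipped)), 1e-6)

  expect_error(synth_density(one, resolution = 4, voxel = 3), "voxel too coarse")
})

test_that("zero-weight blobs contribute nothing", {
  ctr <- rbind(c(0, 0, 0), c(10, 0, 0))
  with_blob <- make_blob_map(ctr, weights = c(1, 0), sigma = 2, voxel = 1,
                             pad = 8)
  # same grid extents, only the live blob
  without <- globaldyn:::gaussian_map(ctr, 2, 1, 8, weights = c(1, 0))
  expect_lt(max(abs(with_blob$values - without$values)), 1e-12)
})

test_that("TRN with K=1 recovers the density-weighted centroid", {
  grid <- make_blob_map(rbind(c(2, -1, 3)), sigma = 2, voxel = 1)
  cen <- grid_centroid(grid)
  fit <- trn_fit(grid, K = 1, seed = 42)
  expect_lt(sqrt(sum((fit$positions[1, ] - cen)^2)), 0.5)
  expect_equal(sum(fit$weights), sum(grid$values[grid$values > 0]),
               tolerance = 1e-6)
})

test_that("TRN recovers well-separated planted blobs", {
  ctrs <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  grid <- make_blob_map(ctrs, sigma = 2, voxel = 1)
  fit <- trn_fit(grid, K = 4, seed = 7)
  d <- as.matrix(stats::dist(rbind(fit$positions, ctrs)))[1:4, 5:8]
  nearest <- unname(apply(d, 1, which.min))
  expect_equal(sort(nearest), 1:4)          # distinct blobs
  expect_true(all(d[cbind(1:4, nearest)] <= 1))
  # equal blobs carry equal mass within sampling error
  expect_equal(fit$weights / sum(fit$weights), rep(0.25, 4), tolerance = 0.02)
})

test_that("TRN quantization error is near a Lloyd k-means oracle", {
  ctrs <- rbind(c(0, 0, 0), c(18, 0, 0), c(0, 18, 0))
  grid <- make_blob_map(ctrs, sigma = 2, voxel = 1)
  fit <- trn_fit(grid, K = 3, seed = 11)
  v <- as.vector(grid$values); sel <- which(v > 0)
  set.seed(12)
  idx <- sample(sel, 1e4, replace = TRUE, prob = v[sel] / sum(v[sel]))
  X <- globaldyn:::voxel_centers(grid, idx) +
    matrix(runif(3e4, -0.5, 0.5), ncol = 3)
  qe <- mean(rowSums((X - fit$positions[globaldyn:::nearest_index(X, fit$positions), ])^2))
  km <- stats::kmeans(X, centers = 3, nstart = 10, iter.max = 100,
                      algorithm = "Lloyd")
  expect_lt(qe, (km$tot.withinss / nrow(X)) * 1.10)
})

test_that("TRN errors and determinism behave as documented", {
  grid <- make_blob_map(rbind(c(0, 0, 0)), sigma = 2, voxel = 2, pad = 4)
  expect_error(trn_fit(grid, K = 1e6, seed = 1), "exceeds")
  zero <- density_grid(array(0, c(4, 4, 4)), voxel = 1)
  expect_error(trn_fit(zero, K = 1, seed = 1), "no density above threshold")
  a <- trn_fit(grid, K = 3, seed = 9)
  b <- trn_fit(grid, K = 3, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$weights, b$weights)
})

test_that("quantization error decreases in expectation from K to 2K", {
  ctrs <- rbind(c(0, 0, 0), c(14, 0, 0), c(0, 14, 0), c(7, 7, 10))
  grid <- make_blob_map(ctrs, sigma = 2, voxel = 1.5)
  qk <- vapply(1:5, function(s) trn_fit(grid, 4, seed = s)$meta$quantization_error,
               numeric(1))
  q2k <- vapply(1:5, function(s) trn_fit(grid, 8, seed = s)$meta$quantization_error,
                numeric(1))
  expect_lt(stats::median(q2k), stats::median(qk))
})

test_that("atom-to-pseudoatom mapping equals the brute-force minimum", {
  nodes <- random_nodeset(30, seed = 63)
  model <- pseudoatom_model(nodes$coords[c(3, 11, 20), ], weights = rep(1, 3))
  mp <- map_pseudoatoms_to_atoms(model, nodes)
  expect_equal(mp$atom_to_pseudo[c(3, 11, 20)], 1:3)
  brute <- apply(nodes$coords, 1, function(x)
    which.min(colSums((t(model$positions) - x)^2)))
  expect_equal(mp$atom_to_pseudo, brute)
  expect_equal(sort(unlist(mp$members)), 1:30)

  one <- pseudoatom_model(matrix(c(0, 0, 0), 1), weights = 1)
  expect_true(all(map_pseudoatoms_to_atoms(one, nodes)$atom_to_pseudo == 1))
})

test_that("pseudoatom ANM inherits elastic-model behaviour", {
  two <- pseudoatom_model(rbind(c(0, 0, 0), c(8, 0, 0)), weights = c(1, 1))
  m <- suppressWarnings(pseudoatom_anm(two))
  expect_equal(length(m$eigenvalues), 1)
  axis <- coordinate_matrix(m$vectors[, 1])
  expect_lt(max(abs(axis[, 2:3])), 1e-10)

  # connected configuration: jittered lattice of pseudoatoms
  set.seed(64)
  lat <- make_lattice_structure(2, spacing = 6)
  many <- pseudoatom_model(lat$coords + matrix(rnorm(24, sd = 0.3), ncol = 3),
                           weights = rep(1, 8))
  mm <- pseudoatom_anm(many)
  expect_equal(mm$n_zero, 6L)
  n <- 8
  tx <- rep(c(1, 0, 0), n) / sqrt(n)
  H <- build_anm_hessian(pseudoatom_nodes(many),
                         enm_parameters(r_cut = 100))$matrix
  expect_lt(max(abs(H %*% tx)), 1e-8)
})
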