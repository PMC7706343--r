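test_that("PCA axes recover object orientation", {
  # axis-aligned ellipsoid cloud: first axis within 2 degrees of x
  m <- make_ellipsoid_mask(c(4, 2, 1.2), spacing = 0.3)
  coords <- (which(m, arr.ind = TRUE) - 1) * 0.3
  ax <- pca_axes(coords)
  expect_lt(acos(min(abs(ax$axes[1, 1]), 1)) * 180 / pi, 2)
  expect_true(all(diff(ax$eigenvalues) <= 0))
  # rotating the cloud rotates the recovered axes accordingly
  R <- random_rotation(11)
  axr <- pca_axes(coords %*% t(R))
  for (j in 1:3) {
    cosang <- abs(sum((R %*% ax$axes[, j]) * axr$axes[, j]))
    expect_lt(acos(min(cosang, 1)) * 180 / pi, 2)
  }
  # sphere: eigenvalues near-equal, axes orthonormal
  ms <- make_ellipsoid_mask(c(3, 3, 3), spacing = 0.3)
  axs <- pca_axes((which(ms, arr.ind = TRUE) - 1) * 0.3)
  expect_lt(diff(range(axs$eigenvalues)) / axs$eigenvalues[1], 0.05)
  expect_equal(crossprod(axs$axes), diag(3), tolerance = 1e-8)
  expect_error(pca_axes(matrix(0, 3, 3)), "degenerate grain")
  flat <- cbind(expand.grid(1:5, 1:5), 0)
  expect_error(pca_axes(as.matrix(flat)), "degenerate grain")
})

test_that("oriented dimensions measure boxes to within half a voxel", {
  idx <- as.matrix(expand.grid(1:20, 1:10, 1:6))
  coords <- (idx - 1) * 0.3
  ax <- pca_axes(coords)
  dims <- grain_dimensions(coords, ax$axes, 0.3)
  expect_equal(unname(dims), c(6.0, 3.0, 1.8), tolerance = 0.15 / 1.8)
  expect_true(all(diff(dims) <= 0))
  # the same box rotated 45 degrees about z: within one voxel
  th <- pi / 4
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  # rasterize the rotated box on the lattice
  n <- 48
  grid <- (as.matrix(expand.grid(1:n, 1:n, 1:12)) - 1) * 0.3
  ctr <- c(n, n, 12) / 2 * 0.3
  local <- sweep(grid, 2, ctr) %*% Rz
  inside <- abs(local[, 1]) <= 3.0 & abs(local[, 2]) <= 1.5 &
    abs(local[, 3]) <= 0.9
  coords45 <- grid[inside, ]
  dims45 <- grain_dimensions(coords45, pca_axes(coords45)$axes, 0.3)
  expect_equal(unname(dims45), c(6.0, 3.0, 1.8), tolerance = 0.3 / 1.8)
})

test_that("grain volume is exact voxel counting", {
  lab <- label_volume(array(rep(c(0L, 1L), c(24, 1000 - 24)) , c(10, 10, 10)),
                      spacing = 0.3)
  expect_equal(grain_volume(lab, 1), (1000 - 24) * 0.027)
  expect_error(grain_volume(lab, 9), "not present")
  # voxelized 3 mm sphere within 3% of analytic
  m <- make_ellipsoid_mask(c(3, 3, 3), spacing = 0.3)
  expect_lt(abs(sum(m) * 0.027 / (4 / 3 * pi * 27) - 1), 0.03)
})

test_that("iso-surface areas are accurate, closed and convergent", {
  # sphere r = 5 mm at 0.3 mm: within 4% of 4*pi*r^2
  m <- make_ellipsoid_mask(c(5, 5, 5), spacing = 0.3)
  a <- grain_surface_area(m, 0.3)
  expect_lt(abs(as.numeric(a) / (4 * pi * 25) - 1), 0.04)
  expect_equal(attr(a, "open_edges"), 0)
  # doubling resolution moves the area closer to analytic
  m2 <- make_ellipsoid_mask(c(5, 5, 5), spacing = 0.15)
  a2 <- grain_surface_area(m2, 0.15)
  expect_lt(abs(as.numeric(a2) / (4 * pi * 25) - 1),
            abs(as.numeric(a) / (4 * pi * 25) - 1))
  # rice ellipsoid vs the Knud Thomsen value (1.1% approximation + mesh)
  mr <- make_ellipsoid_mask(c(3.5, 1.5, 1), spacing = 0.3,
                            rotation = random_rotation(4))
  ar <- grain_surface_area(mr, 0.3)
  expect_lt(abs(as.numeric(ar) / kt_area(3.5, 1.5, 1) - 1), 0.05)
  # single voxel: a closed surface with positive area not exceeding the
  # voxel's own 6 dx^2
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  asv <- grain_surface_area(sv, 1)
  expect_equal(attr(asv, "open_edges"), 0)
  expect_gt(as.numeric(asv), 0)
  expect_lte(as.numeric(asv), 6)
  expect_error(grain_surface_area(array(FALSE, c(3, 3, 3)), 1), "empty")
})

test_that("hull volume and solidity follow convexity", {
  idx <- as.matrix(expand.grid(1:20, 1:10, 1:6))
  h <- grain_hull_and_solidity((idx - 1) * 0.3, 1200 * 0.027, 0.3)
  expect_gte(h$solidity, 0.95)
  expect_lte(h$solidity, 1.02)
  # C-shaped blob: solidity well below 1
  m <- array(TRUE, c(20, 20, 8)); m[5:20, 6:15, ] <- FALSE
  idxc <- which(m, arr.ind = TRUE)
  hc <- grain_hull_and_solidity((idxc - 1) * 0.3, nrow(idxc) * 0.027, 0.3)
  expect_lt(hc$solidity, 0.8)
  # containment: hull volume >= grain volume for random blobs
  set.seed(3)
  for (i in 1:5) {
    mb <- array(FALSE, c(12, 12, 12))
    seed_idx <- cbind(sample(3:10, 40, TRUE), sample(3:10, 40, TRUE),
                      sample(3:10, 40, TRUE))
    mb[seed_idx] <- TRUE
    idxb <- which(mb, arr.ind = TRUE)
    vb <- nrow(idxb) * 0.027
    hb <- grain_hull_and_solidity((idxb - 1) * 0.3, vb, 0.3)
    expect_gte(hb$convex_hull_volume, vb - 1e-9)
  }
  expect_error(grain_hull_and_solidity(cbind(1:5, 1, 1), 1, 1),
               "degenerate hull")
})

test_that("mean gray and aggregation identities hold", {
  arr <- array(100, c(12, 12, 6))
  lab <- array(0L, c(12, 12, 6))
  lab[2:5, 2:5, 2:5] <- 1L; arr[2:5, 2:5, 2:5] <- 20000
  lab[8:11, 8:11, 2:5] <- 2L; arr[8:11, 8:11, 2:5] <- 30000
  v <- ct_volume(arr, spacing = 0.3)
  lv <- label_volume(lab, spacing = 0.3)
  expect_equal(grain_mean_gray(v, lv, 1), 20000)
  expect_equal(grain_mean_gray(v, lv, 2), 30000)
  rec <- grain_records(v, lv)
  tr <- aggregate_panicle(rec, "p")
  expect_equal(tr$MGG, 25000)
  expect_equal(tr$GN, 2)
  expect_equal(tr$TGV, sum(rec$volume))
  expect_equal(tr$GN * tr$MGV, tr$TGV, tolerance = 1e-12)
  # single grain: SDs are zero, means equal the grain
  tr1 <- aggregate_panicle(rec[1, ], "q")
  expect_equal(tr1$SGL, 0)
  expect_equal(tr1$SGV, 0)
  expect_equal(tr1$MGL, rec$length[1])
  # two identical grains: doubled totals, zero SDs
  tr2 <- aggregate_panicle(rbind(rec[1, ], rec[1, ]), "r")
  expect_equal(tr2$TGV, 2 * rec$volume[1])
  expect_equal(tr2$SGV, 0)
  expect_error(aggregate_panicle(rec[0, ], "s"), "no grain records")
})

test_that("traits are rotation-invariant and ordered on phantom grains", {
  spec0 <- single_grain_phantom_spec(21, noise_sigma = 0)
  ph0 <- generate_phantom(spec0)
  spec1 <- single_grain_phantom_spec(22, noise_sigma = 0)
  ph1 <- generate_phantom(spec1)   # same grain, different rotation
  get_rec <- function(ph) {
    lab <- segment_grains(ph$volume)
    grain_records(ph$volume, lab)
  }
  r0 <- get_rec(ph0); r1 <- get_rec(ph1)
  for (f in c("length", "width", "thickness"))
    expect_lt(abs(r0[[f]] - r1[[f]]), 0.3)           # one voxel
  expect_lt(abs(r0$volume / r1$volume - 1), 0.03)
  expect_true(all(r0$length >= r0$width, r0$width >= r0$thickness))
  # isoperimetric inequality with mesh tolerance
  min_area <- (36 * pi * r0$volume^2)^(1 / 3)
  expect_gt(r0$surface_area, 0.98 * min_area)
  # equivalent diameter is defined exactly from the volume
  expect_equal(r0$equivalent_diameter, (6 * r0$volume / pi)^(1 / 3))
})
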