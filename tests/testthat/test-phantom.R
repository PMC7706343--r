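test_that("voxelized sphere volume matches the analytic value", {
  g <- list(center = c(16, 16, 16), semi_axes = c(5, 5, 5),
            rotation = diag(3), intensity = 1000)
  idx <- voxelize_ellipsoid(g, c(33, 33, 33), 1)
  expect_lt(abs(nrow(idx) / (4 / 3 * pi * 125) - 1), 0.02)
})

test_that("degenerate and symmetric voxelizations behave as defined", {
  g <- list(center = c(8, 8, 8), semi_axes = c(1e-6, 1e-6, 1e-6),
            rotation = diag(3), intensity = 1000)
  expect_warning(idx <- voxelize_ellipsoid(g, c(16, 16, 16), 1), "empty")
  expect_equal(nrow(idx), 0L)
  # identity rotation and its transpose give identical voxel sets on a sphere
  R <- random_rotation(3)
  gs <- list(center = c(8, 8, 8), semi_axes = c(4, 4, 4), intensity = 1)
  i1 <- voxelize_ellipsoid(c(gs, list(rotation = R)), c(17, 17, 17), 1)
  i2 <- voxelize_ellipsoid(c(gs, list(rotation = t(R))), c(17, 17, 17), 1)
  expect_identical(i1[order(i1[, 1], i1[, 2], i1[, 3]), ],
                   i2[order(i2[, 1], i2[, 2], i2[, 3]), ])
})

test_that("phantom rendering is deterministic and honors its spec", {
  spec <- panicle_phantom_spec(6, 1, shape = c(96, 96, 96), seed = 9)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_equal(a$truth$grain_count, 6L)
  expect_equal(max(a$truth$labels$labels), 6L)
  # zero grains, no noise: background + holder only
  empty <- phantom_spec(shape = c(32, 32, 16), spacing = 0.3,
                        holder = list(inner_radius = 3, wall_thickness = 0.9,
                                      intensity = 12000),
                        background_intensity = 100, seed = 1)
  e <- generate_phantom(empty)
  expect_equal(e$truth$grain_count, 0L)
  expect_setequal(unique(as.vector(e$volume$data)), c(100, 12000))
})

test_that("noise-free phantom histogram is separable by Otsu", {
  spec <- phantom_spec(shape = c(48, 48, 48), spacing = 0.3,
                       holder = NULL,
                       grains = list(list(center = c(7, 7, 7),
                                          semi_axes = c(3, 1.5, 1),
                                          rotation = diag(3),
                                          intensity = 30000)),
                       background_intensity = 100, seed = 1)
  ph <- generate_phantom(spec)
  thr <- otsu_threshold(intensity_histogram(ph$volume))
  expect_gte(thr, 100)
  expect_lt(thr, 30000)
  mask <- segment_foreground(ph$volume, exclude_zero = FALSE)
  expect_identical(unclass(mask)[TRUE], (ph$truth$labels$labels > 0)[TRUE])
})

test_that("truth voxel volumes converge to analytic volumes with resolution", {
  err <- vapply(c(0.3, 0.15), function(h) {
    spec <- phantom_spec(shape = rep(round(12 / h), 3), spacing = h,
                         holder = NULL,
                         grains = list(list(center = c(6, 6, 6),
                                            semi_axes = c(3.5, 1.5, 1),
                                            rotation = random_rotation(5),
                                            intensity = 30000)),
                         background_intensity = 100, seed = 1)
    ph <- generate_phantom(spec)
    abs(ph$truth$traits$voxel_count * h^3 / ph$truth$traits$volume - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[1], 0.05)
})

test_that("overlapping grains give disputed voxels to the nearer center", {
  spec <- phantom_spec(shape = c(40, 40, 40), spacing = 1, holder = NULL,
                       grains = list(
                         list(center = c(16, 20, 20), semi_axes = c(6, 6, 6),
                              rotation = diag(3), intensity = 30000),
                         list(center = c(24, 20, 20), semi_axes = c(6, 6, 6),
                              rotation = diag(3), intensity = 30000)),
                       background_intensity = 100, seed = 1)
  ph <- generate_phantom(spec)
  lab <- ph$truth$labels$labels
  idx <- which(lab > 0, arr.ind = TRUE)
  d1 <- sqrt(rowSums(sweep(idx - 1, 2, c(16, 20, 20))^2))
  d2 <- sqrt(rowSums(sweep(idx - 1, 2, c(24, 20, 20))^2))
  got <- lab[idx]
  expect_true(all(got[d1 < d2] == 1L))
  expect_true(all(got[d2 < d1] == 2L))
})
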