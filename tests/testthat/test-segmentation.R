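test_that("Otsu threshold equals the exhaustive scan, with the tie rule", {
  # delta peaks: any threshold between them is equivalent; tie rule picks
  # the lowest, and both routes must agree
  h <- numeric(65536)
  h[100 + 1] <- 5000
  h[30000 + 1] <- 3000
  t1 <- otsu_threshold(h)
  expect_identical(t1, brute_force_otsu(h))
  expect_gte(t1, 100)
  expect_lt(t1, 30000)
  # two equal peaks symmetric about 32768
  h2 <- numeric(65536)
  h2[20000 + 1] <- 1000
  h2[45536 + 1] <- 1000
  expect_identical(otsu_threshold(h2), brute_force_otsu(h2))
  expect_error(otsu_threshold(c(0, 5, 0)), "degenerate")
  # random noisy bimodal histograms: exact equality with the oracle
  for (seed in 1:25)
    expect_identical(otsu_threshold(random_bimodal_histogram(seed)),
                     brute_force_otsu(random_bimodal_histogram(seed)))
})

test_that("foreground segmentation matches truth and excludes dim branches", {
  spec <- phantom_spec(shape = c(48, 48, 48), spacing = 0.3, holder = NULL,
                       grains = list(list(center = c(7.2, 7.2, 7.2),
                                          semi_axes = c(3, 1.5, 1),
                                          rotation = diag(3),
                                          intensity = 30000)),
                       branches = list(list(from = c(2, 2, 2),
                                            to = c(7, 7, 7), radius = 0.4,
                                            intensity = 12000)),
                       background_intensity = 100, seed = 1)
  ph <- generate_phantom(spec)
  mask <- segment_foreground(ph$volume, exclude_zero = FALSE)
  truth <- ph$truth$labels$labels > 0
  # branch voxels (at 40% of grain intensity) fall below the Otsu threshold
  branch <- ph$volume$data == 12000
  expect_true(all(!mask[branch]))
  expect_gt(mean(mask[truth]), 0.999)
  # zeroed-out voxels can never be foreground
  v2 <- ph$volume
  v2$data[1:5, 1:5, 1:5] <- 0
  m2 <- segment_foreground(v2)
  expect_true(all(!m2[1:5, 1:5, 1:5]))
})

test_that("distance transforms match brute force and analytic values", {
  # single foreground voxel
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_equal(distance_transform(m, "chessboard")[3, 3, 3], 1)
  expect_equal(distance_transform(m, "euclidean")[3, 3, 3], 1)
  # 7x7x7 cube: center at chessboard distance 4, verified by full scan
  mc <- array(FALSE, c(11, 11, 11)); mc[3:9, 3:9, 3:9] <- TRUE
  dc <- distance_transform(mc, "chessboard")
  expect_equal(dc[6, 6, 6], 4)
  bg <- which(!mc, arr.ind = TRUE)
  fg <- which(mc, arr.ind = TRUE)
  brute <- vapply(seq_len(nrow(fg)), function(i)
    min(apply(abs(t(bg) - fg[i, ]), 2, max)), numeric(1))
  expect_equal(dc[mc], brute)
  # random mask: exact Euclidean against all-pairs scan
  set.seed(7)
  mr <- array(runif(12^3) > 0.55, c(12, 12, 12))
  de <- distance_transform(mr, "euclidean")
  bgr <- which(!mr, arr.ind = TRUE)
  fgr <- which(mr, arr.ind = TRUE)
  bruter <- vapply(seq_len(nrow(fgr)), function(i)
    sqrt(min(colSums((t(bgr) - fgr[i, ])^2))), numeric(1))
  expect_equal(de[mr], bruter, tolerance = 1e-12)
  # sphere r = 6: max euclidean distance within one voxel of 6
  ms <- make_ellipsoid_mask(c(6, 6, 6), spacing = 1)
  expect_lt(abs(max(distance_transform(ms, "euclidean")) - 6), 1)
  expect_true(all(distance_transform(ms, "chessboard")[!ms] == 0))
})

test_that("maxima merging unifies in-grain maxima but not touching grains", {
  # sphere with spurious noise maxima: merged to one marker
  ph <- generate_phantom(single_grain_phantom_spec(17))
  mask <- largest_component(segment_foreground(ph$volume))
  dist <- distance_transform(mask)
  raw <- merged_maxima(dist, 0)
  merged <- merged_maxima(dist, 1 / 0.3)   # threshold = minor radius
  expect_gt(max(raw), 1)                   # this seed over-segments raw
  expect_equal(max(merged), 1L)
  # merge_threshold 0 is the identity on regional maxima
  expect_identical(raw, merged_maxima(dist, 0))
  # two spheres touching at a point stay two markers
  two <- phantom_spec(shape = c(40, 40, 24), spacing = 1, holder = NULL,
                      grains = list(
                        list(center = c(13, 20, 12), semi_axes = c(7, 7, 7),
                             rotation = diag(3), intensity = 30000),
                        list(center = c(27, 20, 12), semi_axes = c(7, 7, 7),
                             rotation = diag(3), intensity = 30000)),
                      background_intensity = 100, seed = 1)
  ph2 <- generate_phantom(two)
  m2 <- segment_foreground(ph2$volume, exclude_zero = FALSE)
  d2 <- distance_transform(m2)
  mk2 <- merged_maxima(d2, 5)
  expect_equal(max(mk2), 2L)
  # monotonicity: more merging never increases the marker count
  counts <- vapply(c(0, 1, 2, 3, 5, 8), function(t)
    max(merged_maxima(d2, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed assigns every reachable voxel exactly once", {
  ph <- generate_phantom(panicle_phantom_spec(6, 3, shape = c(96, 96, 96),
                                              seed = 4))
  hc <- clear_holder(ph$volume)
  mask <- segment_foreground(hc$volume)
  dist <- distance_transform(mask)
  markers <- merged_maxima(dist, NULL)
  lab <- watershed_split(mask, markers, dist)
  # conservation: the partition neither loses nor creates voxels
  expect_identical(sum(lab > 0), sum(mask))
  expect_true(all(lab[!mask] == 0L))
  # one marker -> label volume identical to that component of the mask
  single <- largest_component(mask)
  ds <- distance_transform(single)
  mk1 <- merged_maxima(ds, NULL)
  l1 <- watershed_split(single, mk1, ds)
  expect_identical(l1 > 0, single)
  # empty marker set falls back to a single grain with a warning
  expect_warning(l0 <- watershed_split(single, array(0L, dim(single)), ds),
                 "empty marker")
  expect_identical(l0, array(as.integer(single), dim(single)))
})

test_that("touching pairs split at the contact and recover their volumes", {
  spec <- panicle_phantom_spec(2, 1, shape = c(80, 80, 80), seed = 8)
  ph <- generate_phantom(spec)
  hc <- clear_holder(ph$volume)
  res <- segment_grains(hc$volume)
  expect_equal(count_grains(res), 2L)
  truth <- ph$truth$labels$labels
  for (k in 1:2) {
    own <- truth[res$labels == k]
    own <- own[own > 0]
    # each output label is dominated by one truth grain (splits only at
    # the overlap interface)
    expect_gt(max(table(own)) / length(own), 0.95)
  }
  vols <- tabulate(res$labels[res$labels > 0], 2) * prod(res$spacing)
  expect_lt(max(abs(sort(vols) / sort(ph$truth$traits$volume) - 1)), 0.10)
})

test_that("component labeling connectivity and size filter behave as defined", {
  m <- array(FALSE, c(30, 10, 10))
  m[1:5, 1:5, 1:5] <- TRUE                 # 125 voxels
  m[10:14, 1:4, 1:4] <- TRUE               # 80 voxels
  m[20, 1, 1] <- TRUE                      # dust
  lab <- label_and_filter(m, min_volume = 10)
  expect_equal(max(lab), 2L)
  expect_identical(sort(unique(as.integer(lab))), c(0L, 1L, 2L))
  # corner-sharing voxels: one component at 26, two at 6
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(max(label_and_filter(m2, 26, min_volume = 1)), 1L)
  expect_equal(max(label_and_filter(m2, 6, min_volume = 1)), 2L)
  expect_equal(count_grains(label_and_filter(array(FALSE, c(3, 3, 3)))), 0L)
})
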