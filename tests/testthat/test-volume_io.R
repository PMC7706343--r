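test_that("ct_volume and label_volume enforce their invariants", {
  expect_error(ct_volume(matrix(0, 2, 2)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(ct_volume(array(-5, c(2, 2, 2))), "\\[0, 65535\\]")
  expect_error(ct_volume(array(70000, c(2, 2, 2))), "\\[0, 65535\\]")
  lab <- label_volume(array(c(0L, 2L, 2L, 5L), c(2, 2, 1)))
  expect_equal(sort(unique(as.integer(lab$labels))), c(0L, 1L, 2L))
  expect_equal(count_grains(lab), 2L)
})

test_that("DICOM stack round trip is lossless and tag-ordered", {
  spec <- phantom_spec(shape = c(24, 20, 6), spacing = c(0.3, 0.25, 0.4),
                       grains = list(list(center = c(3.6, 2.5, 1.2),
                                          semi_axes = c(1.5, 1, 0.8),
                                          rotation = diag(3),
                                          intensity = 30000)),
                       background_intensity = 100, noise_sigma = 500,
                       seed = 4)
  ph <- generate_phantom(spec)
  td <- withr::local_tempdir()
  write_dicom_stack(ph$volume, td)
  rt <- read_dicom_stack(td)
  expect_identical(round(rt$data), round(ph$volume$data))
  expect_equal(rt$spacing, c(0.3, 0.25, 0.4))

  # slices written in shuffled instance order come back sorted by tag,
  # whatever the file names say
  td2 <- withr::local_tempdir()
  fname <- c("c.dcm", "a.dcm", "b.dcm")
  for (i in seq_along(fname))
    panicleCT:::dicom_write_file(
      file.path(td2, fname[i]), ph$volume$data[, , c(2, 1, 3)[i]],
      instance = c(2, 1, 3)[i], spacing = ph$volume$spacing,
      position = c(0, 0, 0))
  rt2 <- read_dicom_stack(td2)
  expect_equal(dim(rt2$data)[3], 3L)
  expect_identical(round(rt2$data), round(ph$volume$data[, , 1:3]))
})

test_that("DICOM reader rejects bad inputs with clear errors", {
  expect_error(read_dicom_stack(tempfile()), "no slices")
  td <- withr::local_tempdir()
  expect_error(read_dicom_stack(td), "no slices")
  # ragged stack: two slices of different shapes
  m1 <- matrix(0L, 8, 8); m2 <- matrix(0L, 4, 4)
  panicleCT:::dicom_write_file(file.path(td, "a.dcm"), m1, 1, rep(0.3, 3),
                               c(0, 0, 0))
  panicleCT:::dicom_write_file(file.path(td, "b.dcm"), m2, 2, rep(0.3, 3),
                               c(0, 0, 0.3))
  expect_error(read_dicom_stack(td), "ragged stack")
  # not a DICOM file
  td3 <- withr::local_tempdir()
  writeLines("plain text", file.path(td3, "x.dcm"))
  expect_error(read_dicom_stack(td3), "not a DICOM")
})

test_that("label volumes round-trip losslessly with their spacing", {
  set.seed(1)
  lv <- label_volume(array(sample(0:4, 512, TRUE), c(8, 8, 8)),
                     spacing = c(0.3, 0.3, 0.3))
  tf <- withr::local_tempfile(fileext = ".nii")
  write_label_volume(lv, tf)
  back <- read_label_volume(tf)
  expect_identical(back$labels, lv$labels)
  expect_identical(back$spacing, lv$spacing)
  # all-background volume
  lv0 <- label_volume(array(0L, c(4, 4, 4)))
  tf0 <- withr::local_tempfile(fileext = ".nii")
  write_label_volume(lv0, tf0)
  expect_identical(read_label_volume(tf0)$labels, lv0$labels)
  expect_error(read_label_volume(tempfile()), "cannot read")
})

test_that("trait CSV has the 22 fixed columns and round-trips", {
  rec <- data.frame(label = 1, length = 7, width = 3, thickness = 2,
                    length_width_ratio = 7 / 3, width_thickness_ratio = 1.5,
                    volume = 20, surface_area = 50,
                    equivalent_diameter = (6 * 20 / pi)^(1 / 3),
                    solidity = 0.97, convex_hull_volume = 21,
                    mean_gray = 30000)
  tr1 <- aggregate_panicle(rec, "p1")
  tr2 <- aggregate_panicle(rbind(rec, rec), "p2")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_traits_csv(list(tr1, tr2), tf)
  back <- read_traits_csv(tf)
  expect_equal(nrow(back), 2L)
  expect_identical(names(back),
                   c("panicle", panicleCT:::PANICLE_TRAIT_NAMES))
  expect_identical(back$panicle, c("p1", "p2"))   # input order kept
  expect_equal(back$TGV, c(20, 40))
  expect_error(write_traits_csv(list(), tempfile()), "nothing to write")
})
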