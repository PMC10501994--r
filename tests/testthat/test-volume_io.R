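# Label-volume construction, validation, file round-trips, resampling.

test_that("label_volume validates labels, spacing and shape", {
  v <- label_volume(array(0:1, dim = c(2, 2, 2)), spacing = c(0.7, 0.7, 1))
  expect_s3_class(v, "label_volume")
  expect_error(label_volume(array(7L, dim = c(2, 2, 2))), "7")
  expect_error(label_volume(array(0L, dim = c(2, 2))), "3D")
  expect_error(label_volume(array(0L, dim = c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
})

test_that("NIfTI round-trip preserves voxels, spacing and origin", {
  set.seed(1)
  vox <- array(sample(0:2, 4 * 5 * 6, replace = TRUE), dim = c(4, 5, 6))
  v <- label_volume(vox, spacing = c(0.7, 0.7, 1.0), origin = c(-3, 2, 10))
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(v, path)
  r <- read_label_volume(path)
  expect_identical(r$voxels, v$voxels)
  expect_equal(r$spacing, c(0.7, 0.7, 1.0), tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)
})

test_that("NIfTI with inferior-increasing z is flipped to superior-increasing", {
  vox <- array(0L, dim = c(3, 3, 4))
  vox[2, 2, 1] <- 1L # most inferior slice in the canonical frame
  img <- RNifti::asNifti(vox)
  xf <- diag(c(1, 1, -1, 1)) # z axis pointing inferior
  RNifti::qform(img) <- structure(xf, code = 2L)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  r <- read_label_volume(path)
  expect_equal(which(r$voxels != 0L, arr.ind = TRUE)[1, 3], 4L,
               ignore_attr = TRUE) # flipped to the superior end
})

test_that("MetaImage round-trip preserves voxels and metadata", {
  set.seed(2)
  vox <- array(sample(0:2, 60, replace = TRUE), dim = c(3, 4, 5))
  v <- label_volume(vox, spacing = c(1.1, 0.9, 2), origin = c(1, 2, 3))
  path <- file.path(tempdir(), "roundtrip.mhd")
  write_metaimage_volume(v, path)
  r <- read_label_volume(path)
  expect_identical(r$voxels, v$voxels)
  expect_equal(r$spacing, v$spacing)
  expect_equal(r$origin, v$origin)
})

test_that("split_labels separates lumen and thrombus and conserves counts", {
  set.seed(3)
  vox <- array(sample(0:2, 4^3, replace = TRUE), dim = c(4, 4, 4))
  v <- label_volume(vox, spacing = c(1, 1, 1))
  parts <- split_labels(v)
  expect_equal(sum(parts$lumen$voxels), sum(vox == 1))
  expect_equal(sum(parts$thrombus$voxels), sum(vox == 2))
  expect_equal(sum(parts$lumen$voxels) + sum(parts$thrombus$voxels),
               sum(vox != 0))

  empty <- label_volume(array(0L, dim = c(3, 3, 3)))
  pe <- split_labels(empty)
  expect_equal(sum(pe$lumen$voxels), 0)
  expect_equal(sum(pe$thrombus$voxels), 0)

  lumen_only <- label_volume(array(c(0L, 1L), dim = c(2, 2, 2)))
  expect_equal(sum(split_labels(lumen_only)$thrombus$voxels), 0)
})

test_that("resample_isotropic preserves labels and physical volume", {
  # already isotropic at target: identity
  v <- label_volume(array(1L, dim = c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(v, 1)$voxels, v$voxels)

  # 10 mm cube at (1, 1, 2) mm resampled to 1 mm: volume within 5%
  vox <- array(0L, dim = c(16, 16, 9))
  vox[4:13, 4:13, 3:7] <- 1L # 10 x 10 x 10 mm solid
  v2 <- label_volume(vox, spacing = c(1, 1, 2))
  r2 <- resample_isotropic(v2, 1)
  vol_before <- sum(v2$voxels) * prod(v2$spacing)
  vol_after <- sum(r2$voxels) * prod(r2$spacing)
  expect_lte(abs(vol_after - 1000) / 1000, 0.05)
  expect_lte(abs(vol_after - vol_before) / vol_before, 0.05)
  expect_true(all(unique(as.vector(r2$voxels)) %in% 0:2))
  expect_error(resample_isotropic(v2, -1), "positive")
})

test_that("manifest reading validates and normalizes columns", {
  dir <- tempdir()
  path <- file.path(dir, "manifest.csv")
  write.csv(data.frame(case_id = "a", lumen_path = "a_lumen.nii.gz",
                       thrombus_path = ""), path, row.names = FALSE)
  m <- read_manifest(path)
  expect_true(is.na(m$thrombus_path[1]))
  expect_true(grepl(dir, m$lumen_path[1], fixed = TRUE)) # relative resolved
  write.csv(data.frame(foo = 1), path, row.names = FALSE)
  expect_error(read_manifest(path), "case_id")
})
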