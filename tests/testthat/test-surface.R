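# Mask fusion, morphological smoothing, isosurface extraction, mesh utilities.

test_that("fuse_lumen_thrombus is a binary union", {
  dims <- c(6, 6, 6)
  lum <- array(0L, dims); lum[2:3, 2:3, 2:6] <- 1L
  thr <- array(0L, dims); thr[5, 5, 1:2] <- 1L
  l <- label_volume(lum); t2 <- label_volume(thr)
  fused <- fuse_lumen_thrombus(l, t2)
  expect_equal(sum(fused$voxels), sum(lum) + sum(thr)) # disjoint

  empty <- label_volume(array(0L, dims))
  expect_identical(fuse_lumen_thrombus(l, empty)$voxels, l$voxels)

  overlap <- label_volume(lum)
  expect_lte(sum(fuse_lumen_thrombus(l, overlap)$voxels), sum(lum) + sum(lum))
  expect_equal(sum(fuse_lumen_thrombus(l, overlap)$voxels), sum(lum))

  shifted <- label_volume(thr, origin = c(1, 0, 0))
  expect_error(fuse_lumen_thrombus(l, shifted), "grid")
})

test_that("smooth_mask matches a brute-force closing+opening oracle", {
  sp <- c(1, 1, 1)
  # ball with a single-voxel surface pit (at a smooth surface spot, not an
  # axis extremity where the voxel has no same-radius neighbours)
  ball <- ball_volume(r = 6, spacing = 1, pad = 4)
  d <- dim(ball$voxels)
  ctr <- round((d + 1) / 2)
  pit <- ball
  surf_vox <- ctr + c(4, 4, 2)
  stopifnot(pit$voxels[surf_vox[1], surf_vox[2], surf_vox[3]] == 1L)
  pit$voxels[surf_vox[1], surf_vox[2], surf_vox[3]] <- 0L
  sm <- smooth_mask(pit, 2)
  oracle <- brute_dilate(pit$voxels, sp, 2)
  oracle <- brute_erode(oracle, sp, 2) # closing
  oracle <- brute_erode(oracle, sp, 2)
  oracle <- brute_dilate(oracle, sp, 2) # then opening
  expect_identical(sm$voxels != 0L, oracle)
  expect_equal(sm$voxels[surf_vox[1], surf_vox[2], surf_vox[3]], 1L) # pit filled

  # isolated voxel removed by the opening
  lone <- label_volume(array(0L, c(9, 9, 9)))
  lone$voxels[5, 5, 5] <- 1L
  expect_equal(sum(smooth_mask(lone, 1)$voxels), 0)

  # radius 0 is the identity
  expect_identical(smooth_mask(pit, 0)$voxels, pit$voxels)
  expect_error(smooth_mask(pit, -1), "radius")
})

test_that("smooth_mask is nearly idempotent on a tubular phantom", {
  ph <- control22_phantom()
  once <- smooth_mask(ph$lumen, 1.5)
  twice <- smooth_mask(once, 1.5)
  changed <- sum(once$voxels != twice$voxels)
  expect_lt(changed / sum(once$voxels), 0.01)
})

test_that("extract_surface reproduces sphere area and volume", {
  ball <- fixture("ball10", function() ball_volume(r = 10, spacing = 0.5))
  mesh <- extract_surface(ball)
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.03)
  # mesh volume also agrees with the voxel-count volume
  vox_vol <- sum(ball$voxels) * prod(ball$spacing)
  expect_lt(abs(mesh_volume(mesh) - vox_vol) / vox_vol, 0.05)
  expect_error(extract_surface(label_volume(array(0L, c(3, 3, 3)))), "foreground")
})

test_that("isosurface vertices stay near the mask boundary", {
  ball <- fixture("ball10", function() ball_volume(r = 10, spacing = 0.5))
  mesh <- extract_surface(ball)
  # for a digital ball the surface must sit within a voxel diagonal of r
  rad <- sqrt(rowSums(mesh$vertices^2))
  diag_mm <- sqrt(3) * 0.5
  expect_true(all(abs(rad - 10) <= diag_mm))
})

test_that("meshes round-trip through OBJ and export to VTP", {
  ball <- ball_volume(r = 4, spacing = 1)
  mesh <- extract_surface(ball)
  p <- tempfile(fileext = ".obj")
  write_surface_obj(mesh, p)
  back <- read_surface_obj(p)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-5)
  expect_identical(back$triangles, mesh$triangles)
  vtp <- tempfile(fileext = ".vtp")
  write_surface_vtp(mesh, vtp)
  expect_true(file.size(vtp) > 0)
  expect_match(readLines(vtp, n = 2)[2], "PolyData")
})
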