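# Axial bounds, skeletonization, endpoints, pruning, refined centerline.

test_that("find_axial_bounds localizes arch and iliac transitions", {
  arch <- arch_tube_volume(apex = 120, spacing = 1)
  b <- find_axial_bounds(arch)
  expect_true(b$arch_found)
  expect_lte(abs(b$z_arch - 120), 2 * arch$spacing[3]) # within 2 slices

  y <- ytube_volume(z_split = 20, spacing = 1)
  by <- find_axial_bounds(y)
  expect_true(by$iliac_found)
  expect_lte(abs(by$z_iliac - 20), 3.5) # limbs separate just below the apex

  cyl <- cylinder_volume(r = 6, L = 50, spacing = 1)
  bc <- find_axial_bounds(cyl)
  expect_false(bc$arch_found)
  expect_false(bc$iliac_found)
  zs <- cyl$origin[3] + (dim(cyl$voxels)[3] - 1) * cyl$spacing[3]
  expect_equal(bc$z_iliac, cyl$origin[3])
  expect_equal(bc$z_arch, zs)

  expect_error(find_axial_bounds(label_volume(array(0L, c(3, 3, 3)))), "empty")
})

test_that("skeleton of a straight cylinder is a thin axial chain", {
  cyl <- fixture("cyl10", function() cylinder_volume(r = 10, L = 80, spacing = 0.75))
  skel <- skeletonize_lumen(cyl)
  expect_gt(sum(skel$voxels), 0)
  # subset of the foreground
  expect_true(all(cyl$voxels[skel$voxels != 0L] != 0L))
  ijk <- which(skel$voxels != 0L, arr.ind = TRUE)
  mm <- aortascreen:::vox_to_mm(skel, ijk)
  expect_true(all(sqrt(mm[, 1]^2 + mm[, 2]^2) <= 1.5 * max(skel$spacing)))
  ep <- find_endpoints(skel)
  expect_equal(nrow(ep), 2)
  # endpoints near the end faces
  epz <- aortascreen:::vox_to_mm(skel, ep)[, 3]
  expect_lt(min(epz) - 0, 2 * skel$spacing[3] + 1e-9)
  expect_lt(80 - max(epz), 2 * skel$spacing[3] + 2)
  expect_error(skeletonize_lumen(label_volume(array(0L, c(3, 3, 3)))), "empty")
})

test_that("Y-tube skeleton has three limbs and three endpoints", {
  y <- ytube_volume(z_split = 20, spacing = 1)
  skel <- prune_skeleton(skeletonize_lumen(y), 5)
  ep <- find_endpoints(skel)
  expect_equal(nrow(ep), 3)
  # exactly one junction region: voxels with >= 3 neighbours, all adjacent
  g <- aortascreen:::skeleton_graph(skel)
  deg <- tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = length(g$idx))
  jct <- g$ijk[deg >= 3, , drop = FALSE]
  expect_gte(nrow(jct), 1)
  span <- apply(jct, 2, function(x) diff(range(x)))
  expect_true(all(span <= 3)) # one compact junction, not several
})

test_that("find_endpoints implements the fewer-than-2-neighbours rule", {
  chain <- chain_volume(cbind(3, 3, 3:12)) # straight 10-voxel chain
  expect_equal(nrow(find_endpoints(chain)), 2)

  lone <- chain_volume(cbind(3, 3, 3))
  expect_equal(nrow(find_endpoints(lone)), 1) # 0 neighbours: an endpoint

  yv <- chain_volume(rbind(
    cbind(5, 5, 1:6),                      # stem
    cbind(5 + 1:4, 5, 6 + 1:4),            # limb 1 (diagonal)
    cbind(5 - 1:4, 5, 6 + 1:4)))           # limb 2
  expect_equal(nrow(find_endpoints(yv)), 3)
})

test_that("short spurs are pruned before seeding", {
  sk <- chain_volume(rbind(
    cbind(10, 10, 1:20),          # main chain, 19 mm
    cbind(10 + 1:3, 10, 10 + 1:3) # 3-voxel spur off the middle
  ))
  pruned <- prune_skeleton(sk, 5)
  expect_equal(nrow(find_endpoints(pruned)), 2)
  # spur gone (at most the junction-adjacent voxel may remain)
  expect_lte(sum(pruned$voxels), 21)
  seeds <- centerline_seeds(sk, 5)
  expect_equal(nrow(seeds$targets), 1)
  expect_equal(seeds$source[3], 19) # highest-z endpoint is the source
})

test_that("centerline of a straight cylinder hugs the axis with true radius", {
  cyl <- fixture("cyl10", function() cylinder_volume(r = 10, L = 80, spacing = 0.75))
  cal <- compute_centerline(cyl, c(0, 0, 80), rbind(c(0, 0, 0)))
  b <- cal$branches[[1]]
  expect_true(all(sqrt(b$points[, 1]^2 + b$points[, 2]^2) <= 0.5))
  expect_true(all(abs(b$radius - 10) <= 0.5))
  # resampling: consecutive spacing near the 2.5 mm default
  expect_lt(abs(mean(diff(b$arc)) - 2.5) / 2.5, 0.2)
  # interior invariant: every point inside the mask
  d <- dim(cyl$voxels)
  v <- round(aortascreen:::mm_to_vox(cyl, b$points))
  expect_true(all(cyl$voxels[cbind(v[, 1], v[, 2], v[, 3])] != 0L))
})

test_that("quarter-torus centerline recovers the analytic arc length", {
  tor <- torus_volume(Rc = 50, rt = 8, spacing = 0.75)
  cal <- compute_centerline(tor, c(50, 0, 0), rbind(c(0, 0, 50)))
  b <- cal$branches[[1]]
  dev <- abs(sqrt(b$points[, 1]^2 + b$points[, 3]^2) - 50)
  expect_true(all(dev <= 0.5))
  expect_true(all(abs(b$points[, 2]) <= 0.5))
  expect_lt(abs(max(b$arc) - pi / 2 * 50) / (pi / 2 * 50), 0.03)
})

test_that("centerline parameters are validated", {
  expect_error(centerline_params(resampling_step = 0), "resampling_step")
  expect_error(centerline_params(smooth_factor = 2), "smooth_factor")
  p <- centerline_params()
  expect_equal(p$resampling_step, 2.5)
  expect_equal(p$smooth_factor, 0.5)
})

test_that("centerline CSV export has the documented columns", {
  cyl <- fixture("cyl10", function() cylinder_volume(r = 10, L = 80, spacing = 0.75))
  cal <- compute_centerline(cyl, c(0, 0, 80), rbind(c(0, 0, 0)))
  p <- tempfile(fileext = ".csv")
  write_centerline_csv(cal, p)
  df <- read.csv(p)
  expect_named(df, c("branch_id", "point_index", "x", "y", "z",
                     "arc_length_mm", "radius_mm"))
  expect_true(all(diff(df$arc_length_mm) > 0))
  vtp <- tempfile(fileext = ".vtp")
  write_centerline_vtp(cal, vtp)
  expect_match(paste(readLines(vtp), collapse = ""), "NumberOfLines=\"1\"")
})
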