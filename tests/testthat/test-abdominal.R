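# Branch decomposition, bifurcation planes, renal identification, clipping.

test_that("split_branches decomposes a two-target tree into three branches", {
  y <- ytube_volume(z_split = 20, spacing = 1)
  cal <- compute_centerline(y, c(0, 0, 68), rbind(c(20, 2, 10), c(-20, -2, 10)))
  cal <- split_branches(cal)
  expect_equal(length(cal$branch_decomp), 3) # trunk + two children
  expect_equal(length(cal$divergences), 1)
})

test_that("a single-target centerline is one branch with no divergence", {
  cyl <- fixture("cyl10", function() cylinder_volume(r = 10, L = 80, spacing = 0.75))
  cal <- compute_centerline(cyl, c(0, 0, 80), rbind(c(0, 0, 0)))
  cal <- split_branches(cal)
  expect_equal(length(cal$branch_decomp), 1)
  expect_equal(length(cal$divergences), 0)
  expect_equal(length(bifurcation_planes(NULL, cal)), 0)
})

test_that("the Y-tube bifurcation plane sits at the analytic split", {
  y <- ytube_volume(z_split = 20, spacing = 1)
  cal <- compute_centerline(y, c(0, 0, 68), rbind(c(20, 2, 10), c(-20, -2, 10)))
  cal <- split_branches(cal)
  planes <- bifurcation_planes(NULL, cal)
  expect_equal(length(planes), 1)
  expect_lt(abs(planes[[1]]$origin[3] - 20), 5)
  expect_equal(planes[[1]]$label, "iliac") # most inferior divergence
  expect_equal(sqrt(sum(planes[[1]]$normal^2)), 1, tolerance = 1e-6)
})

test_that("phantom renal and iliac planes are localized within 5 mm", {
  ph <- aaa50_phantom()
  res <- aaa50_result()
  expect_lt(abs(res$detail$renal$origin[3] - ph$truth$renal_z_mm), 5)
  expect_lt(abs(res$detail$iliac$origin[3] - ph$truth$iliac_z_mm), 5)
  # plane count matches the number of divergence points
  expect_equal(length(res$detail$planes),
               length(split_branches(res$detail$centerline)$divergences))
})

test_that("find_renal_plane returns the lowest non-iliac plane", {
  mk <- function(z, label = "other")
    structure(list(origin = c(0, 0, z), normal = c(0, 0, 1), label = label),
              class = "bifurcation_plane")
  planes <- list(mk(200), mk(95), mk(20, "iliac"))
  r <- find_renal_plane(planes)
  expect_equal(r$origin[3], 95)
  expect_equal(r$label, "renal")
  # invariant to ordering
  r2 <- find_renal_plane(rev(planes))
  expect_equal(r2$origin[3], 95)
  # single non-iliac plane: that plane
  expect_equal(find_renal_plane(list(mk(95), mk(20, "iliac")))$origin[3], 95)
  expect_error(find_renal_plane(list()), "renal")
  expect_error(find_renal_plane(list(mk(20, "iliac"))), "renal")
})

test_that("clip_mesh and crop_to_bounds cut at the requested planes", {
  cyl <- fixture("cyl10", function() cylinder_volume(r = 10, L = 80, spacing = 0.75))
  mesh <- fixture("cyl10_mesh", function()
    extract_surface(fixture("cyl10", function() cylinder_volume(r = 10, L = 80,
                                                                spacing = 0.75))))
  cropped <- crop_to_bounds(mesh, 60, 20)
  zr <- range(cropped$vertices[, 3])
  expect_lt(abs((zr[2] - zr[1]) - 40), 0.75) # 40 mm within one voxel
  expect_true(all(cropped$vertices[, 3] >= 20 - 1e-6 &
                    cropped$vertices[, 3] <= 60 + 1e-6))
  # planes outside the bounding box leave the mesh unchanged, with warnings
  w <- capture_warnings(un <- crop_to_bounds(mesh, 500, -500))
  expect_length(w, 2)
  expect_match(w, "extent", all = TRUE)
  expect_identical(un$vertices, mesh$vertices)
})

test_that("clip_abdominal isolates the tract between the planes", {
  ph <- aaa50_phantom()
  res <- aaa50_result()
  renal <- res$detail$renal
  iliac <- res$detail$iliac
  # recomputed abdominal centerline length ~ trunk distance between origins
  abd <- res$detail$abdominal_centerline
  expected <- abs(renal$origin[3] - iliac$origin[3])
  inset <- 8 + 2.5 # configured sectioning insets trimmed from the ends
  expect_lt(abs(max(abd$branches[[1]]$arc) - (expected - inset)) / expected, 0.08)
  # wrongly ordered planes are rejected
  expect_error(clip_abdominal(res$detail$surface, res$detail$centerline,
                              iliac, renal), "superior")
})

test_that("the abdominal tract excludes the thoracic surface", {
  res <- arch55_result()
  full <- res$detail$surface
  abd <- res$detail$abdominal_surface
  zr <- res$detail$renal$origin[3]
  tri_area_above <- function(mesh, z) {
    V <- mesh$vertices
    Tm <- mesh$triangles
    cz <- (V[Tm[, 1], 3] + V[Tm[, 2], 3] + V[Tm[, 3], 3]) / 3
    a <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
    b <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
    ar <- sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                 (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                 (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2) / 2
    sum(ar[cz > z])
  }
  thoracic_full <- tri_area_above(full, zr + 2)
  thoracic_abd <- tri_area_above(abd, zr + 2)
  expect_gt(thoracic_full, 0)
  expect_lt(thoracic_abd / thoracic_full, 0.05) # >= 95% excluded
  # the aneurysm bulge is retained
  expect_gt(max(res$detail$profile$diameter_mm), 50)
})
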