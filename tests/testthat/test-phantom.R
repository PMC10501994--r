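# Synthetic phantom generation and its analytic ground truth.

test_that("phantom truth follows the construction", {
  # straight tube of constant lumen radius 11 -> outer diameter 22
  sp <- phantom_spec(base_radius = 11, noise = 0, branches = list())
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$max_outer_diameter_mm, 22, tolerance = 1e-9)
  expect_equal(ph$truth$true_class, "control")
  expect_equal(sum(ph$thrombus$voxels), 0)

  # bulge raising outer radius to 25 -> 50 mm, classed AAA
  ph2 <- generate_phantom(case_phantom_spec(50, noise = 0))
  expect_equal(ph2$truth$max_outer_diameter_mm, 50, tolerance = 1e-6)
  expect_equal(ph2$truth$true_class, "AAA")
  expect_gt(sum(ph2$thrombus$voxels), 0)
})

test_that("phantom generation is deterministic for a fixed seed", {
  s <- case_phantom_spec(40, seed = 123)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$lumen$voxels, b$lumen$voxels)
  expect_identical(a$thrombus$voxels, b$thrombus$voxels)
  expect_identical(a$truth$max_outer_diameter_mm, b$truth$max_outer_diameter_mm)
})

test_that("a bulge overlapping a branch take-off is rejected", {
  expect_error(phantom_spec(bulge_amplitude = 10, bulge_center = 100,
                            bulge_width = 14), "take-off")
})

test_that("phantom thrombus voxel volume matches the analytic integral", {
  ph <- aaa50_phantom()
  rel <- abs(thrombus_volume(ph$thrombus) - ph$truth$thrombus_volume_ml) /
    ph$truth$thrombus_volume_ml
  expect_lt(rel, 0.05)
})

test_that("cohort_factory produces classed cases with truth and manifest", {
  dir <- file.path(tempdir(), "cf_test")
  cf <- cohort_factory(2, 2, seed = 5, dir = dir,
                       spacing = 1.5) # coarse grid: generation-only test
  expect_equal(nrow(cf$manifest), 4)
  expect_equal(sum(cf$manifest$true_class == "AAA"), 2)
  expect_true(all(cf$manifest$manual_diameter_mm[cf$manifest$true_class == "AAA"] > 30))
  expect_true(all(cf$manifest$manual_diameter_mm[cf$manifest$true_class == "control"] < 30))
  expect_true(all(file.exists(cf$manifest$lumen_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # AAA cases carry thrombus files, controls do not
  expect_true(all(!is.na(cf$manifest$thrombus_path[cf$manifest$true_class == "AAA"])))
  expect_true(all(is.na(cf$manifest$thrombus_path[cf$manifest$true_class == "control"])))

  empty <- cohort_factory(0, 0, seed = 1)
  expect_equal(nrow(empty$manifest), 0)
})

test_that("phantom masks load back through the manifest reader", {
  dir <- file.path(tempdir(), "cf_roundtrip")
  cf <- cohort_factory(1, 0, seed = 9, dir = dir, spacing = 1.5)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  masks <- aortascreen:::load_case_masks(m[1, ])
  expect_s3_class(masks$lumen, "label_volume")
  expect_gt(sum(masks$lumen$voxels), 0)
  expect_gt(sum(masks$thrombus$voxels), 0)
  expect_true(aortascreen:::same_grid(masks$lumen, masks$thrombus))
})
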