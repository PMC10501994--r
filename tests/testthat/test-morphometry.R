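# Cross-sections, Feret diameters, thrombus volume, measure_case.

test_that("cylinder sections have the analytic disc area and centred contours", {
  cyl <- fixture("cyl20", function() cylinder_volume(r = 20, L = 100, spacing = 0.75))
  mesh <- extract_surface(cyl)
  cal <- compute_centerline(cyl, c(0, 0, 100), rbind(c(0, 0, 0)))
  secs <- suppressWarnings(generate_sections(mesh, cal, step = 2.5))
  expect_gt(length(secs), 35) # ~40 sections over ~97 mm of centerline
  areas <- vapply(secs, function(s) s$area, numeric(1))
  # interior sections (cap-adjacent planes may graze the end rings)
  mid <- vapply(secs, function(s) s$center[3] > 5 && s$center[3] < 95, logical(1))
  expect_true(all(abs(areas[mid] - pi * 400) / (pi * 400) < 0.03))
  # each contour centroid close to its centerline point
  cen_err <- vapply(secs[mid], function(s)
    sqrt(sum((colMeans(s$contour) - s$center)^2)), numeric(1))
  expect_true(all(cen_err < 2))
  # coefficient of variation of diameters along the uniform tube
  diams <- vapply(secs[mid], function(s) s$diameter, numeric(1))
  expect_lt(sd(diams) / mean(diams), 0.02)
})

test_that("sections of a tilted cylinder stay circular (no ellipse elongation)", {
  # axis 30 degrees off z in the xz plane, radius 20
  s <- seq(0, 100, by = 0.4)
  dirn <- c(sin(pi / 6), 0, cos(pi / 6))
  pts <- outer(s, dirn)
  sp <- 0.75
  lo <- apply(pts, 2, min) - 25; hi <- apply(pts, 2, max) + 25
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  v <- aortascreen:::cpp_voxelize_tubes(dims, rep(sp, 3), lo,
    list(list(points = pts, radius = rep(20, length(s)),
              thickness = rep(0, length(s)))))
  tube <- label_volume(array(v$lumen, dim = dims), rep(sp, 3), lo)
  mesh <- extract_surface(tube)
  cal <- compute_centerline(tube, pts[nrow(pts), ], rbind(pts[1, ]))
  secs <- suppressWarnings(generate_sections(mesh, cal, step = 5))
  arcs <- vapply(secs, function(x) x$arc_length, numeric(1))
  mid <- arcs > 15 & arcs < max(arcs) - 15
  diams <- vapply(secs[mid], function(x) x$diameter, numeric(1))
  expect_true(all(abs(diams - 40) / 40 < 0.02))
})

test_that("section_diameter is the maximum Feret diameter", {
  # analytic circle, 360 points
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- 17.3
  circ <- structure(list(
    center = c(0, 0, 0), normal = c(0, 0, 1),
    contour = cbind(r * cos(th), r * sin(th), 0),
    diameter = NA, equiv_diameter = NA, area = NA, arc_length = 0),
    class = "cross_section")
  expect_lt(abs(section_diameter(circ) - 2 * r) / (2 * r), 0.001)

  # ellipse: matches the brute-force all-pairs maximum
  a <- 21; b <- 9
  ell <- circ
  ell$contour <- cbind(a * cos(th), b * sin(th), 0)
  pts <- ell$contour
  brute <- 0
  for (i in seq_len(nrow(pts)))
    brute <- max(brute, sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2))
  expect_equal(section_diameter(ell), brute, tolerance = 1e-9)
  expect_lt(abs(section_diameter(ell) - 2 * a) / (2 * a), 0.005)

  deg <- circ
  deg$contour <- cbind(c(0, 1), c(0, 0), c(0, 0))
  expect_error(section_diameter(deg), "contour")
})

test_that("max_abdominal_diameter takes the argmax with superior tie-break", {
  mk <- function(d, z) structure(list(center = c(0, 0, z), normal = c(0, 0, 1),
                                      contour = diag(3), diameter = d,
                                      equiv_diameter = d, area = 1,
                                      arc_length = z),
                                 class = "cross_section")
  out <- max_abdominal_diameter(list(mk(20, 10), mk(35, 20), mk(30, 30)))
  expect_equal(out$diameter, 35)
  # uniform diameters: tie broken toward the most superior section
  tie <- max_abdominal_diameter(list(mk(20, 10), mk(20, 50), mk(20, 30)))
  expect_equal(tie$section$center[3], 50)
  # monotone cone: most dilated end wins
  cone <- max_abdominal_diameter(lapply(1:10, function(i) mk(10 + i, i * 5)))
  expect_equal(cone$diameter, 20)
  expect_error(max_abdominal_diameter(list()), "section")
})

test_that("thrombus volume is voxel count times voxel volume in mL", {
  empty <- label_volume(array(0L, c(4, 4, 4)))
  expect_equal(thrombus_volume(empty), 0)
  expect_equal(thrombus_volume(NULL), 0)
  # 8000 voxels at (0.5 mm)^3 -> exactly 1 mL
  v <- label_volume(array(1L, dim = c(20, 20, 20)), spacing = rep(0.5, 3))
  expect_identical(thrombus_volume(v), 1)
  # phantom annulus within 5% of the analytic integral
  ph <- aaa50_phantom()
  expect_lt(abs(thrombus_volume(ph$thrombus) - ph$truth$thrombus_volume_ml) /
              ph$truth$thrombus_volume_ml, 0.05)
})

test_that("measure_case recovers phantom diameters and thrombus usage", {
  ctrl <- control22_phantom()
  resc <- control22_result()
  expect_false(resc$used_thrombus)
  expect_lt(abs(resc$max_diameter_mm - ctrl$truth$max_outer_diameter_mm),
            max(0.02 * ctrl$truth$max_outer_diameter_mm, sqrt(3) * 0.75))
  expect_equal(resc$predicted_class, "control")

  ph <- aaa50_phantom()
  res <- aaa50_result()
  expect_true(res$used_thrombus)
  # tracks the outer (thrombus) wall, not the lumen
  lumen_d <- 2 * (9 + 0.6 * (25 - 9)) # lumen bulge peak diameter by design
  expect_gt(res$max_diameter_mm, lumen_d + 5)
  expect_lt(abs(res$max_diameter_mm - ph$truth$max_outer_diameter_mm),
            max(0.02 * ph$truth$max_outer_diameter_mm, sqrt(3) * 0.75))
  expect_equal(res$predicted_class, "AAA")
})

test_that("measure_case is deterministic and ignores an empty thrombus mask", {
  ctrl <- control22_phantom()
  r1 <- measure_case(ctrl$lumen, ctrl$thrombus, case_id = "a")
  r2 <- measure_case(ctrl$lumen, ctrl$thrombus, case_id = "a")
  expect_identical(r1$max_diameter_mm, r2$max_diameter_mm) # bitwise
  expect_identical(r1$detail$profile, r2$detail$profile)
  # empty thrombus mask == no thrombus at all
  r3 <- measure_case(ctrl$lumen, NULL, case_id = "a")
  expect_lt(abs(r3$max_diameter_mm - r1$max_diameter_mm), 0.1)
})

test_that("case reports serialize to JSON and CSV", {
  res <- control22_result()
  dir <- file.path(tempdir(), "case_report")
  paths <- write_case_report(res, dir)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(paths[1])
  expect_equal(rep$predicted_class, "control")
  expect_equal(rep$max_diameter_mm, res$max_diameter_mm)
  prof <- read.csv(paths[2])
  expect_true(all(c("arc_length_mm", "diameter_mm", "area_mm2") %in% names(prof)))
})
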