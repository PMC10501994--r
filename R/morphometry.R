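# Perpendicular cross-sections, wall-to-wall diameters, thrombus volume, and
# the per-case measurement pipeline.

#' Generate cross-sections perpendicular to a centerline
#'
#' At each centerline point (equidistant along arc length) the surface is
#' intersected with the plane through the point perpendicular to the local
#' tangent; of the resulting intersection loops only the closed loop
#' containing the centerline point is kept (grazing loops through other limbs
#' are discarded). Sections whose plane misses the surface, or that only
#' produce open chains (cut boundaries), are skipped with a warning.
#'
#' @param surface a [surface_mesh()].
#' @param centerline a [compute_centerline()] result; its first branch is
#'   sectioned.
#' @param step section spacing along arc length in mm (default: the
#'   centerline's own resampling step).
#' @return list of `cross_section` objects: `center`, `normal`, `contour`
#'   (k x 3 mm), `diameter` (mm), `equiv_diameter` (mm), `area` (mm^2),
#'   `arc_length` (mm).
#' @export
generate_sections <- function(surface, centerline, step = NULL) {
  stopifnot(inherits(surface, "surface_mesh"), inherits(centerline, "centerline"))
  br <- centerline$branches[[1]]
  if (is.null(step)) step <- centerline$params$resampling_step
  if (!is.finite(step) || step <= 0) stop("step must be > 0")
  total <- max(br$arc)
  s_out <- seq(0, total, by = step)
  pts <- vapply(1:3, function(c2) approx(br$arc, br$points[, c2], xout = s_out)$y,
                numeric(length(s_out)))
  pts <- matrix(pts, ncol = 3)
  tgs <- path_tangents(pts)
  sections <- list()
  skipped <- 0
  for (r in seq_len(nrow(pts))) {
    sec <- section_at(surface, pts[r, ], tgs[r, ], s_out[r])
    if (is.null(sec)) { skipped <- skipped + 1; next }
    sections[[length(sections) + 1]] <- sec
  }
  if (skipped > 0)
    warning(skipped, " section plane(s) missed the surface or were unclosed; skipped")
  sections
}

# Single cross-section of `surface` at point `center` with plane normal `nrm`.
section_at <- function(surface, center, nrm, arc_length = NA_real_) {
  loops <- mesh_plane_contours(surface, center, nrm)
  loops <- Filter(function(l) isTRUE(l$closed) && nrow(l$points) >= 3, loops)
  if (length(loops) == 0) return(NULL)
  basis <- plane_basis(nrm)
  hit <- NULL
  for (l in loops) {
    rel <- sweep(l$points, 2, center)
    xs <- as.vector(rel %*% basis$u)
    ys <- as.vector(rel %*% basis$v)
    if (point_in_polygon(0, 0, xs, ys)) {
      hit <- list(loop = l, xs = xs, ys = ys)
      break
    }
  }
  if (is.null(hit)) return(NULL)
  area <- polygon_area(hit$xs, hit$ys)
  diam <- contour_max_feret(hit$xs, hit$ys)
  structure(list(center = center, normal = nrm, contour = hit$loop$points,
                 diameter = diam, equiv_diameter = 2 * sqrt(area / pi),
                 area = area, arc_length = arc_length),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> arc %.1f mm: diameter %.2f mm, area %.1f mm^2\n",
              x$arc_length, x$diameter, x$area))
  invisible(x)
}

# Maximum Feret diameter of a planar contour given 2D coordinates.
contour_max_feret <- function(xs, ys) {
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  m <- length(h)
  best <- 0
  for (i in seq_len(m))
    best <- max(best, max((hx - hx[i])^2 + (hy - hy[i])^2))
  sqrt(best)
}

#' Wall-to-wall diameter of a cross-section
#'
#' Maximum pairwise Euclidean distance between contour points (maximum Feret
#' diameter in the section plane), matching the clinical wall-to-wall
#' definition.
#'
#' @param section a `cross_section`.
#' @return diameter in mm.
#' @export
section_diameter <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (nrow(section$contour) < 3) stop("degenerate contour: need >= 3 points")
  basis <- plane_basis(section$normal)
  rel <- sweep(section$contour, 2, section$center)
  contour_max_feret(as.vector(rel %*% basis$u), as.vector(rel %*% basis$v))
}

#' Maximum abdominal diameter over sections
#'
#' Argmax of section diameters; ties are broken toward the more superior
#' (higher z) section.
#'
#' @param sections list of `cross_section`s.
#' @return list with `diameter` (mm) and `section` (the argmax section).
#' @export
max_abdominal_diameter <- function(sections) {
  if (length(sections) == 0) stop("no sections to measure")
  diams <- vapply(sections, function(s) s$diameter, numeric(1))
  zs <- vapply(sections, function(s) s$center[3], numeric(1))
  best <- which(diams > max(diams) - 1e-9)
  best <- best[which.max(zs[best])]
  list(diameter = diams[best], section = sections[[best]])
}

#' Thrombus volume in millilitres
#'
#' Foreground voxel count times voxel volume; an empty mask (aneurysm without
#' thrombus, or control) gives 0.
#'
#' @param thrombus binary [label_volume()] (or NULL).
#' @return volume in mL (1 mL = 1000 mm^3).
#' @export
thrombus_volume <- function(thrombus) {
  if (is.null(thrombus)) return(0)
  stopifnot(inherits(thrombus, "label_volume"))
  sum(thrombus$voxels != 0L) * prod(thrombus$spacing) / 1000
}

#' Measure one case: maximum abdominal diameter and thrombus volume
#'
#' Runs the full geometric pipeline on a lumen mask and an optional thrombus
#' mask: fuse, smooth, resample isotropic, bound between arch and iliac
#' levels, build surfaces, skeletonize the lumen for seeds, compute the
#' refined centerline, decompose branches and locate the renal and iliac
#' planes, clip the abdominal tract, section it perpendicular to the
#' centerline, and report the maximum wall-to-wall diameter plus thrombus
#' volume. When a thrombus is present the outer (lumen + thrombus) model is
#' measured; otherwise the lumen surface alone.
#'
#' @param lumen binary [label_volume()] of the aortic lumen.
#' @param thrombus binary [label_volume()] of the thrombus, or NULL.
#' @param config a [screen_config()].
#' @param case_id identifier copied into the result.
#' @return `measurement_result`: `case_id`, `max_diameter_mm`,
#'   `max_arc_length_mm`, `max_z_mm`, `equiv_diameter_mm`,
#'   `thrombus_volume_ml`, `n_sections`, `used_thrombus`, `predicted_class`,
#'   plus a `detail` list (bounds, planes, section profile data.frame, and the
#'   geometry when `config$keep_geometry`).
#' @export
measure_case <- function(lumen, thrombus = NULL, config = screen_config(),
                         case_id = "case") {
  stopifnot(inherits(lumen, "label_volume"))
  if (sum(lumen$voxels != 0L) == 0) stop("[masks] empty lumen mask")
  if (is.null(thrombus))
    thrombus <- label_volume(array(0L, dim = vol_dim(lumen)),
                             spacing = lumen$spacing, origin = lumen$origin)
  if (!same_grid(lumen, thrombus)) stop("[masks] lumen/thrombus grid mismatch")
  used_thrombus <- sum(thrombus$voxels != 0L) > 0
  thr_vol_ml <- thrombus_volume(thrombus)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop("[", name, "] ", conditionMessage(e),
                                            call. = FALSE))
  }

  aorta <- stage("fuse", fuse_lumen_thrombus(lumen, thrombus))
  aorta <- stage("smooth", smooth_mask(aorta, config$smoothing_radius_mm))
  lum_s <- stage("smooth", smooth_mask(lumen, config$smoothing_radius_mm))
  iso_sp <- min(lumen$spacing)
  aorta <- stage("resample", resample_isotropic(aorta, iso_sp))
  lum_s <- stage("resample", resample_isotropic(lum_s, iso_sp))

  bounds <- stage("bounds", find_axial_bounds(aorta))
  z_hi <- if (bounds$arch_found) bounds$z_arch - config$arch_margin_mm else bounds$z_arch
  z_lo <- if (bounds$iliac_found) bounds$z_iliac - config$iliac_margin_mm else bounds$z_iliac
  aorta_c <- stage("crop", crop_axial(aorta, z_lo, z_hi, largest_component = TRUE))
  lum_c <- stage("crop", crop_axial(lum_s, z_lo, z_hi))
  # keep the lumen inside the retained aorta component
  lum_c$voxels <- array(as.integer(lum_c$voxels != 0L & aorta_c$voxels != 0L),
                        dim = vol_dim(lum_c))

  meas_mask <- if (used_thrombus) aorta_c else lum_c
  surface <- stage("surface", extract_surface(meas_mask, sigma_vox = config$surface_sigma_vox,
                                              provenance = if (used_thrombus) "aorta" else "lumen"))

  skel <- stage("skeleton", skeletonize_lumen(lum_c))
  seeds <- stage("seeds", centerline_seeds(skel, config$prune_length_mm))
  params <- centerline_params(config$resampling_step_mm, config$smooth_factor,
                              config$prune_length_mm)
  cal <- stage("centerline", compute_centerline(aorta_c, seeds$source, seeds$targets,
                                                params))
  cal <- stage("branches", split_branches(cal))
  planes <- stage("branches", bifurcation_planes(surface, cal))

  renal <- NULL
  iliac <- NULL
  if (length(planes) >= 2) {
    labs <- vapply(planes, function(p) p$label, character(1))
    iliac <- planes[[which(labs == "iliac")[1]]]
    renal <- tryCatch(find_renal_plane(planes, iliac), error = function(e) NULL)
  }
  if (!is.null(renal) && !is.null(iliac)) {
    abd <- stage("clip", clip_abdominal(surface, cal, renal, iliac,
                                        mask = meas_mask, params = params))
    abd_surface <- abd$surface
    abd_cl <- abd$centerline
    # inset the sectioned tract from the clip planes so sections clear the
    # renal ostia and the iliac apex neighbourhood
    br <- abd_cl$branches[[1]]
    keep <- br$arc >= config$renal_inset_mm &
      br$arc <= max(br$arc) - config$iliac_inset_mm
    if (sum(keep) >= 2) {
      br$points <- br$points[keep, , drop = FALSE]
      br$arc <- br$arc[keep] - min(br$arc[keep])
      br$tangents <- br$tangents[keep, , drop = FALSE]
      br$radius <- br$radius[keep]
      abd_cl$branches[[1]] <- br
    }
  } else {
    # degenerate geometry (no usable divergences): measure the full tract
    abd_surface <- surface
    trunk_id <- which.max(vapply(cal$branches, function(b) max(b$arc), numeric(1)))
    abd_cl <- cal
    abd_cl$branches <- cal$branches[trunk_id]
  }

  step <- if (is.null(config$section_step_mm)) config$resampling_step_mm
          else config$section_step_mm
  sections <- stage("sections", suppressWarnings(
    generate_sections(abd_surface, abd_cl, step)))
  if (length(sections) == 0) stop("[sections] no valid cross-sections")
  mx <- stage("diameter", max_abdominal_diameter(sections))

  profile <- data.frame(
    arc_length_mm = vapply(sections, function(s) s$arc_length, numeric(1)),
    diameter_mm = vapply(sections, function(s) s$diameter, numeric(1)),
    equiv_diameter_mm = vapply(sections, function(s) s$equiv_diameter, numeric(1)),
    area_mm2 = vapply(sections, function(s) s$area, numeric(1)),
    z_mm = vapply(sections, function(s) s$center[3], numeric(1)))

  detail <- list(bounds = bounds, planes = planes, renal = renal, iliac = iliac,
                 profile = profile)
  if (isTRUE(config$keep_geometry)) {
    detail$surface <- surface
    detail$abdominal_surface <- abd_surface
    detail$centerline <- cal
    detail$abdominal_centerline <- abd_cl
    detail$skeleton <- skel
  }
  structure(list(
    case_id = case_id,
    max_diameter_mm = mx$diameter,
    max_arc_length_mm = mx$section$arc_length,
    max_z_mm = mx$section$center[3],
    equiv_diameter_mm = mx$section$equiv_diameter,
    thrombus_volume_ml = thr_vol_ml,
    n_sections = length(sections),
    used_thrombus = used_thrombus,
    predicted_class = classify(mx$diameter, config),
    detail = detail), class = "measurement_result")
}

#' @export
print.measurement_result <- function(x, ...) {
  cat(sprintf("<measurement_result> %s\n", x$case_id))
  cat(sprintf("  max abdominal diameter: %.1f mm (z = %.1f mm) -> %s\n",
              x$max_diameter_mm, x$max_z_mm, x$predicted_class))
  cat(sprintf("  thrombus volume: %.1f mL (model measured: %s)\n",
              x$thrombus_volume_ml, if (x$used_thrombus) "lumen+thrombus" else "lumen only"))
  cat(sprintf("  %d sections\n", x$n_sections))
  invisible(x)
}

#' Write a per-case JSON report and section profile CSV
#'
#' @param result a [measure_case()] result.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_case_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, paste0(result$case_id, "_report.json"))
  cpath <- file.path(dir, paste0(result$case_id, "_profile.csv"))
  planes <- lapply(Filter(Negate(is.null),
                          list(renal = result$detail$renal, iliac = result$detail$iliac)),
                   function(p) list(origin = p$origin, normal = p$normal,
                                    label = p$label))
  jsonlite::write_json(list(
    case_id = result$case_id,
    max_diameter_mm = result$max_diameter_mm,
    max_z_mm = result$max_z_mm,
    equiv_diameter_mm = result$equiv_diameter_mm,
    thrombus_volume_ml = result$thrombus_volume_ml,
    n_sections = result$n_sections,
    used_thrombus = result$used_thrombus,
    predicted_class = result$predicted_class,
    planes = planes), jpath, auto_unbox = TRUE, digits = NA)
  write.csv(result$detail$profile, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}
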