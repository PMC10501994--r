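# Synthetic vascular phantoms: curved tubular lumen with optional fusiform
# aneurysmal dilation, thrombus annulus, renal-pair and iliac branches, and an
# optional thoracic arch. Every phantom carries analytic ground truth
# (centerline, maximum outer diameter, thrombus volume, branch levels) so the
# whole pipeline is testable without clinical data.

#' Phantom specification
#'
#' The lumen radius along the trunk is `base_radius` plus a Gaussian fusiform
#' bulge `bulge_amplitude * exp(-((s - bulge_center)/bulge_width)^2 / 2)`; the
#' thrombus annulus thickness follows the same Gaussian shape with amplitude
#' `thrombus_thickness`. Branches are straight tubes leaving the trunk at a
#' given arc length. Surface noise is a smooth random radial jitter
#' (spline through knots every 10 mm) of the given amplitude.
#'
#' @param trunk_length trunk length from iliac end to top, mm.
#' @param base_radius lumen radius away from the bulge, mm.
#' @param bulge_amplitude extra lumen radius at the bulge peak, mm (0 = none).
#' @param bulge_center,bulge_width Gaussian bulge centre/width along arc, mm.
#' @param thrombus_thickness peak annulus thickness at the bulge centre, mm.
#' @param thrombus_width Gaussian width of the annulus (default bulge_width).
#' @param branches list of `list(arc =, direction =, radius =, length =)`;
#'   see [standard_branches()].
#' @param arch include a thoracic arch (candy-cane bend plus ascending stub).
#' @param arch_bend_radius bend radius of the arch, mm.
#' @param bow lateral bowing amplitude of the trunk, mm.
#' @param spacing isotropic voxel spacing, mm (default 0.75, matching typical
#'   CTA slice thickness).
#' @param noise surface jitter amplitude, mm.
#' @param seed RNG seed for the jitter.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(trunk_length = 170, base_radius = 9,
                         bulge_amplitude = 0, bulge_center = 70, bulge_width = 14,
                         thrombus_thickness = 0, thrombus_width = bulge_width,
                         branches = standard_branches(), arch = FALSE,
                         arch_bend_radius = 30, bow = 3,
                         spacing = 0.75, noise = 0.3, seed = 1) {
  if (base_radius <= 0 || bulge_amplitude < 0 || thrombus_thickness < 0)
    stop("radii must be positive and amplitudes non-negative")
  if (spacing <= 0) stop("spacing must be > 0")
  if (bulge_amplitude > 0 || thrombus_thickness > 0) {
    support <- c(bulge_center - 2.5 * bulge_width, bulge_center + 2.5 * bulge_width)
    for (b in branches)
      if (b$arc >= support[1] && b$arc <= support[2])
        stop("bulge overlaps a branch take-off at arc ", b$arc,
             " mm: ground truth would be ambiguous")
  }
  structure(list(trunk_length = trunk_length, base_radius = base_radius,
                 bulge_amplitude = bulge_amplitude, bulge_center = bulge_center,
                 bulge_width = bulge_width, thrombus_thickness = thrombus_thickness,
                 thrombus_width = thrombus_width, branches = branches, arch = arch,
                 arch_bend_radius = arch_bend_radius, bow = bow, spacing = spacing,
                 noise = noise, seed = seed), class = "phantom_spec")
}

#' Standard branch set: renal pair and iliac pair
#'
#' Renal arteries leave the trunk at `renal_arc` (default 110 mm above the
#' iliac end) nearly laterally; the iliac limbs leave at `iliac_arc`
#' diverging downward (the most inferior divergence, as required).
#'
#' @param renal_arc,iliac_arc take-off arc lengths along the trunk, mm.
#' @return list of branch descriptors.
#' @export
standard_branches <- function(renal_arc = 110, iliac_arc = 30) {
  list(
    list(arc = iliac_arc, direction = c(0.8, 0.2, -1), radius = 6, length = 35,
         label = "iliac"),
    list(arc = iliac_arc, direction = c(-0.8, -0.2, -1), radius = 6, length = 35,
         label = "iliac"),
    list(arc = renal_arc, direction = c(1, 0.1, 0.2), radius = 3.2, length = 26,
         label = "renal"),
    list(arc = renal_arc, direction = c(-1, -0.1, 0.2), radius = 3.2, length = 26,
         label = "renal"))
}

# Trunk polyline sampled at `by` mm arc steps, bottom (z = 0) to top;
# continues over the arch when requested. Returns points and cumulative arc.
phantom_trunk <- function(spec, by = 0.5) {
  L <- spec$trunk_length
  z <- seq(0, L, by = by)
  pts <- cbind(spec$bow * sin(pi * z / L), 0, z)
  if (spec$arch) {
    R <- spec$arch_bend_radius
    # bend: half-circle from the trunk top over the apex into the ascending side
    theta <- seq(0, pi, by = by / R)[-1]
    bend <- cbind(R - R * cos(theta), 0, L + R * sin(theta))
    desc_len <- 40
    zd <- seq(L - by, L - desc_len, by = -by)
    down <- cbind(2 * R, 0, zd)
    pts <- rbind(pts, bend, down)
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(points = pts, arc = arc)
}

# Smooth random radial jitter: natural spline through N(0, amp^2) knots.
radial_jitter <- function(arc, amplitude, seed, knot_spacing = 10) {
  if (amplitude <= 0) return(rep(0, length(arc)))
  knots <- seq(min(arc), max(arc), by = knot_spacing)
  if (length(knots) < 4) return(rep(0, length(arc)))
  vals <- rnorm(length(knots), 0, amplitude)
  spline(knots, vals, xout = arc)$y
}

#' Generate a phantom case
#'
#' Voxelizes the phantom (a voxel is lumen if its distance to the composite
#' centre curve is at most the local lumen radius; thrombus if between the
#' lumen radius and lumen radius + annulus thickness) and records analytic
#' ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `lumen` and `thrombus` [label_volume()]s and `truth`:
#'   `max_outer_diameter_mm` (+ its arc/z), `thrombus_volume_ml` (0.01 mm-step
#'   annulus integral), `renal_z_mm`, `iliac_z_mm`, `arch_apex_z_mm` (when
#'   arched), `centerline` (trunk sampled at 0.5 mm), `true_class`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  trunk <- phantom_trunk(spec, by = 0.5)
  abd_arc <- pmin(trunk$arc, spec$trunk_length) # profiles act on the abdominal tract
  r_prof <- function(s) spec$base_radius +
    spec$bulge_amplitude * exp(-((s - spec$bulge_center) / spec$bulge_width)^2 / 2)
  t_prof <- function(s) spec$thrombus_thickness *
    exp(-((s - spec$bulge_center) / spec$thrombus_width)^2 / 2)
  jit <- radial_jitter(trunk$arc, spec$noise, spec$seed)
  radius <- r_prof(abd_arc) + jit
  thick <- t_prof(abd_arc)
  thick[trunk$arc > spec$trunk_length] <- 0 # no thrombus over the arch

  # the trunk ends at the iliac take-off: the aorta does not continue below
  # its bifurcation
  il <- vapply(spec$branches, function(b) identical(b$label, "iliac"), logical(1))
  start_arc <- if (any(il))
    min(vapply(spec$branches[il], `[[`, numeric(1), "arc")) else 0

  # adaptive resampling for voxelization speed: coarser where the tube is wide
  pick <- adaptive_pick(trunk$arc, radius + thick)
  pick <- pick[trunk$arc[pick] >= start_arc - 1e-9]
  curves <- list(list(points = trunk$points[pick, , drop = FALSE],
                      radius = radius[pick], thickness = thick[pick]))
  for (b in spec$branches) {
    i0 <- which.min(abs(trunk$arc - b$arc))
    dirn <- b$direction / sqrt(sum(b$direction^2))
    s <- seq(0, b$length, by = 0.5)
    bp <- sweep(outer(s, dirn), 2, trunk$points[i0, ], `+`)
    curves[[length(curves) + 1]] <-
      list(points = bp, radius = rep(b$radius, length(s)),
           thickness = rep(0, length(s)))
  }

  allpts <- do.call(rbind, lapply(curves, `[[`, "points"))
  allrad <- unlist(lapply(curves, function(c2) c2$radius + c2$thickness))
  lo <- apply(allpts - allrad, 2, min) - 3 * spec$spacing
  hi <- apply(allpts + allrad, 2, max) + 3 * spec$spacing
  dims <- as.integer(ceiling((hi - lo) / spec$spacing)) + 1L
  vox <- cpp_voxelize_tubes(dims, rep(spec$spacing, 3), lo, curves)
  lumen <- label_volume(array(vox$lumen, dim = dims),
                        spacing = rep(spec$spacing, 3), origin = lo)
  thrombus <- label_volume(array(vox$thrombus, dim = dims),
                           spacing = rep(spec$spacing, 3), origin = lo)

  # analytic truth on the noisy profile (the noise is part of the geometry),
  # over the infrarenal tract (iliac take-off to renal take-off): the
  # measurement territory of abdominal screening
  labs_all <- vapply(spec$branches, function(b)
    if (!is.null(b$label)) b$label else "other", character(1))
  top_arc <- if (any(labs_all == "renal"))
    min(vapply(spec$branches[labs_all == "renal"], `[[`, numeric(1), "arc"))
    else spec$trunk_length
  s_fine <- seq(start_arc, top_arc, by = 0.01)
  jit_fine <- spline(trunk$arc, jit, xout = s_fine)$y
  r_fine <- r_prof(s_fine) + jit_fine
  outer_fine <- r_fine + t_prof(s_fine)
  imax <- which.max(outer_fine)
  # thrombus volume: 0.01 mm-step numerical integral of the annulus between
  # lumen and outer radius (exact for the nearest-point tube construction on
  # a gently curved axis)
  thr_vol <- sum(pi * (outer_fine^2 - r_fine^2)) * 0.01 / 1000
  z_at <- function(s) approx(trunk$arc, trunk$points[, 3], xout = s)$y
  branch_arcs <- vapply(spec$branches, `[[`, numeric(1), "arc")
  branch_labs <- vapply(spec$branches, function(b)
    if (!is.null(b$label)) b$label else "other", character(1))
  truth <- list(
    max_outer_diameter_mm = 2 * outer_fine[imax],
    max_arc_mm = s_fine[imax],
    max_z_mm = z_at(s_fine[imax]),
    thrombus_volume_ml = thr_vol,
    renal_z_mm = if (any(branch_labs == "renal"))
      min(z_at(branch_arcs[branch_labs == "renal"])) else NA_real_,
    iliac_z_mm = if (any(branch_labs == "iliac"))
      min(z_at(branch_arcs[branch_labs == "iliac"])) else NA_real_,
    arch_apex_z_mm = if (spec$arch) spec$trunk_length + spec$arch_bend_radius
      else NA_real_,
    trunk_top_z_mm = spec$trunk_length,
    centerline = trunk$points[trunk$arc <= spec$trunk_length &
                                trunk$arc >= start_arc - 1e-9, , drop = FALSE],
    true_class = if (2 * outer_fine[imax] > 30) "AAA" else "control")
  list(lumen = lumen, thrombus = thrombus, truth = truth, spec = spec)
}

# Indices subsampling a dense curve so that the local sample step is fine
# relative to the tube radius (scalloping error ~ h^2 / (8 r)).
adaptive_pick <- function(arc, rad) {
  pick <- 1L
  s_next <- arc[1]
  for (i in seq_along(arc)) {
    if (arc[i] >= s_next) {
      pick <- c(pick, i)
      h <- max(0.4, rad[i] / 25)
      s_next <- arc[i] + h
    }
  }
  unique(c(pick, length(arc)))
}

#' Spec for a standard aneurysmal or control phantom of given outer diameter
#'
#' AAA phantoms get a fusiform bulge wrapped in a thrombus annulus (the
#' annulus contributes ~40% of the dilation); controls are plain tubes of the
#' requested diameter. Both keep the renal pair and iliac split.
#'
#' @param outer_diameter_mm target maximum outer diameter (analytic truth).
#' @param with_thrombus wrap the bulge in a thrombus annulus (AAA default).
#' @param arch include the thoracic arch.
#' @param seed,spacing,noise passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
case_phantom_spec <- function(outer_diameter_mm, with_thrombus = outer_diameter_mm > 30,
                              arch = FALSE, seed = 1, spacing = 0.75, noise = 0.3) {
  r_out <- outer_diameter_mm / 2
  if (outer_diameter_mm > 30) {
    base <- 9
    dil <- r_out - base # extra radius at the bulge peak
    if (dil <= 0) stop("aneurysmal phantom needs outer diameter > 18 mm")
    tt <- if (with_thrombus) 0.4 * dil else 0
    phantom_spec(base_radius = base, bulge_amplitude = dil - tt,
                 thrombus_thickness = tt, arch = arch, seed = seed,
                 spacing = spacing, noise = noise)
  } else {
    phantom_spec(base_radius = r_out, bulge_amplitude = 0, thrombus_thickness = 0,
                 arch = arch, seed = seed, spacing = spacing, noise = noise)
  }
}

#' Generate a synthetic screening cohort
#'
#' AAA cases draw their target maximum outer diameter uniformly from
#' `aaa_range` (default \[32, 90\] mm, with thrombus) and controls from
#' `control_range` (default \[16, 28\] mm, no thrombus), emulating reported
#' clinical screening cohorts. Masks are written as NIfTI with a truth JSON
#' per case and a manifest CSV; the analytic truth diameter doubles as the
#' reference ("manual") diameter.
#'
#' @param n_aaa,n_control case counts.
#' @param seed RNG seed for the diameter draws and per-case jitter seeds.
#' @param dir output directory (default: fresh tempdir subdirectory).
#' @param aaa_range,control_range diameter ranges, mm.
#' @param spacing voxel spacing, mm.
#' @param write write mask files (set FALSE to keep volumes in memory only).
#' @return list with `manifest` (data.frame: case_id, lumen_path,
#'   thrombus_path, manual_diameter_mm, true_class), `truths`, and (when
#'   `write = FALSE`) `cases` (the in-memory phantoms).
#' @export
cohort_factory <- function(n_aaa, n_control, seed = 1, dir = NULL,
                           aaa_range = c(32, 90), control_range = c(16, 28),
                           spacing = 0.75, write = TRUE) {
  if (n_aaa < 0 || n_control < 0) stop("counts must be >= 0")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  n <- n_aaa + n_control
  if (n == 0) {
    return(list(manifest = data.frame(case_id = character(0),
                                      lumen_path = character(0),
                                      thrombus_path = character(0),
                                      manual_diameter_mm = numeric(0),
                                      true_class = character(0)),
                truths = list()))
  }
  diams <- c(if (n_aaa > 0) runif(n_aaa, aaa_range[1], aaa_range[2]),
             if (n_control > 0) runif(n_control, control_range[1], control_range[2]))
  classes <- rep(c("AAA", "control"), c(n_aaa, n_control))
  case_seeds <- sample.int(1e6, n)
  if (write && is.null(dir)) dir <- file.path(tempdir(), paste0("cohort_", seed))
  if (write) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  truths <- list()
  cases <- list()
  for (i in seq_len(n)) {
    cid <- sprintf("%s_%02d", tolower(classes[i]), i)
    ph <- generate_phantom(case_phantom_spec(diams[i],
                                             with_thrombus = classes[i] == "AAA",
                                             seed = case_seeds[i], spacing = spacing))
    truths[[cid]] <- ph$truth
    lp <- tp <- NA_character_
    if (write) {
      lp <- file.path(dir, paste0(cid, "_lumen.nii.gz"))
      write_label_volume(ph$lumen, lp)
      if (classes[i] == "AAA") {
        tp <- file.path(dir, paste0(cid, "_thrombus.nii.gz"))
        write_label_volume(ph$thrombus, tp)
      }
      jsonlite::write_json(ph$truth[setdiff(names(ph$truth), "centerline")],
                           file.path(dir, paste0(cid, "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
    } else {
      cases[[cid]] <- ph
    }
    rows[[i]] <- data.frame(case_id = cid, lumen_path = lp, thrombus_path = tp,
                            manual_diameter_mm = ph$truth$max_outer_diameter_mm,
                            true_class = ph$truth$true_class)
  }
  manifest <- do.call(rbind, rows)
  if (write) write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  out <- list(manifest = manifest, truths = truths, dir = if (write) dir else NULL)
  if (!write) out$cases <- cases
  out
}
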