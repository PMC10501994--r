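# Centerline extraction: axial bounding between arch and iliac levels,
# skeletonization of the lumen, endpoint seeds, and the refined center aortic
# line (CAL) as a medial voxel path that is spline-smoothed and resampled.

#' Centerline extraction parameters
#'
#' @param resampling_step arc-length spacing of refined centerline points, mm
#'   (default 2.5).
#' @param smooth_factor spline smoothing strength in \[0, 1\]; 0 = none,
#'   1 = maximal (default 0.5).
#' @param prune_length_mm skeleton limbs shorter than this are removed before
#'   endpoint extraction (default 5).
#' @return list of class `centerline_params`.
#' @export
centerline_params <- function(resampling_step = 2.5, smooth_factor = 0.5,
                              prune_length_mm = 5) {
  if (!is.finite(resampling_step) || resampling_step <= 0)
    stop("resampling_step must be > 0")
  if (!is.finite(smooth_factor) || smooth_factor < 0 || smooth_factor > 1)
    stop("smooth_factor must lie in [0, 1]")
  structure(list(resampling_step = resampling_step, smooth_factor = smooth_factor,
                 prune_length_mm = prune_length_mm), class = "centerline_params")
}

#' Locate the aortic-arch and iliac-bifurcation axial levels
#'
#' Counts 8-connected components per axial slice. A level where the count
#' drops from >= 2 (below) to 1 marks either the arch apex (ascending and
#' descending limbs merging, with foreground ending shortly above) or the
#' iliac bifurcation apex (the single trunk continuing above). The most
#' superior arch-like transition and the most inferior trunk-continuing
#' transition are returned. With no usable transition the full foreground
#' extent is returned and flagged degenerate.
#'
#' @param aorta binary [label_volume()] of the (fused) aorta.
#' @return list with `z_arch`, `z_iliac` (mm), the slice indices
#'   `k_arch`/`k_iliac`, and logical flags `arch_found`, `iliac_found`.
#' @export
find_axial_bounds <- function(aorta) {
  stopifnot(inherits(aorta, "label_volume"))
  d <- vol_dim(aorta)
  counts <- cpp_slice_components(as.vector(aorta$voxels != 0L), d)
  fg <- which(counts > 0)
  if (length(fg) == 0) stop("empty mask: no axial bounds")
  k0 <- min(fg); k1 <- max(fg)
  zs <- aorta$origin[3] + (seq_len(d[3]) - 1) * aorta$spacing[3]
  # transitions: slice k has 1 component and the slice below has >= 2
  trans <- which(counts == 1L & c(Inf, counts[-d[3]]) >= 2L)
  trans <- trans[trans > k0 & trans <= k1]
  # at the arch apex the foreground ends within roughly a tube radius above
  # the merge; at the iliac apex the trunk continues far above it
  above_mm <- (k1 - trans) * aorta$spacing[3]
  arch_like <- above_mm <= 25
  k_iliac <- if (any(!arch_like)) min(trans[!arch_like]) else NA_integer_
  k_arch <- if (any(arch_like)) max(trans[arch_like]) else NA_integer_
  arch_found <- !is.na(k_arch)
  iliac_found <- !is.na(k_iliac) && (!arch_found || k_iliac < k_arch)
  if (!iliac_found) k_iliac <- k0
  if (!arch_found) k_arch <- k1
  if (k_arch <= k_iliac) { # inconsistent: fall back to full extent
    k_arch <- k1; k_iliac <- k0
    arch_found <- iliac_found <- FALSE
  }
  list(z_arch = zs[k_arch], z_iliac = zs[k_iliac], k_arch = k_arch,
       k_iliac = k_iliac, arch_found = arch_found, iliac_found = iliac_found)
}

#' Crop a label volume between two axial levels
#'
#' Keeps slices with `z_low <= z <= z_high` and, optionally, only the largest
#' connected component of the result (the descending/abdominal tract after
#' the arch apex is cut away, discarding the ascending stub).
#'
#' @param vol a [label_volume()].
#' @param z_low,z_high axial bounds in mm.
#' @param largest_component keep only the largest 26-connected component.
#' @return cropped [label_volume()].
#' @export
crop_axial <- function(vol, z_low, z_high, largest_component = FALSE) {
  stopifnot(inherits(vol, "label_volume"))
  d <- vol_dim(vol)
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  keep <- which(zs >= z_low - 1e-9 & zs <= z_high + 1e-9)
  if (length(keep) == 0) stop("axial crop removes the whole volume")
  vox <- vol$voxels[, , keep, drop = FALSE]
  out <- label_volume(vox, spacing = vol$spacing,
                      origin = c(vol$origin[1:2], zs[min(keep)]))
  if (largest_component && sum(out$voxels) > 0) {
    lc <- cpp_largest_component(as.vector(out$voxels != 0L), vol_dim(out))
    out$voxels <- array(as.integer(lc), dim = vol_dim(out))
  }
  out
}

#' Skeletonize a lumen mask to a raw center lumen line (CLL)
#'
#' The mask is resampled to isotropic spacing (3D thinning assumes isotropic
#' adjacency), then thinned by distance-ordered homotopic thinning: border
#' voxels are deleted in increasing distance-transform order whenever deletion
#' preserves topology, keeping chain endpoints. The result is a thin
#' 26-connected curve skeleton.
#'
#' @param lumen binary [label_volume()]; non-empty.
#' @param target_spacing isotropic spacing for thinning (default: min native).
#' @return skeleton as a binary [label_volume()] on the isotropic grid.
#' @export
skeletonize_lumen <- function(lumen, target_spacing = min(lumen$spacing)) {
  stopifnot(inherits(lumen, "label_volume"))
  if (sum(lumen$voxels != 0L) == 0) stop("empty lumen mask")
  iso <- resample_isotropic(lumen, target_spacing)
  d <- vol_dim(iso)
  mask <- as.vector(iso$voxels != 0L)
  dt2 <- cpp_edt_sq(!mask, d, iso$spacing) # distance to background
  skel <- cpp_thin(mask, d, dt2)
  label_volume(array(skel, dim = d), spacing = iso$spacing, origin = iso$origin)
}

# voxel linear index <-> (i,j,k) helpers (1-based)
idx_to_ijk <- function(idx, d) {
  idx0 <- idx - 1L
  cbind(idx0 %% d[1] + 1L,
        (idx0 %/% d[1]) %% d[2] + 1L,
        idx0 %/% (d[1] * d[2]) + 1L)
}

ijk_to_idx <- function(ijk, d) {
  ijk <- rbind(ijk)
  (ijk[, 1] - 1L) + d[1] * ((ijk[, 2] - 1L) + d[2] * (ijk[, 3] - 1L)) + 1L
}

# igraph over skeleton voxels, edges between 26-neighbours weighted by mm.
skeleton_graph <- function(skel) {
  d <- vol_dim(skel)
  idx <- which(as.vector(skel$voxels != 0L))
  if (length(idx) == 0) stop("empty skeleton")
  ijk <- idx_to_ijk(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- cbind(ijk[, 1] + o[1], ijk[, 2] + o[2], ijk[, 3] + o[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nidx <- ijk_to_idx(nb[ok, , drop = FALSE], d)
    src <- which(ok)
    hit <- match(nidx, idx)
    sel <- !is.na(hit) & hit > src # dedupe: undirected edge once
    if (any(sel)) {
      from <- c(from, src[sel]); to <- c(to, hit[sel])
      w <- c(w, rep(sqrt(sum((o * skel$spacing)^2)), sum(sel)))
    }
  }
  list(idx = idx, ijk = ijk, edges = cbind(from, to), weights = w)
}

#' Find skeleton endpoints
#'
#' Endpoints are foreground voxels with fewer than 2 foreground 26-neighbours
#' (chain ends and isolated voxels).
#'
#' @param skel skeleton [label_volume()].
#' @return matrix of endpoint voxel coordinates (i, j, k), one row each.
#' @export
find_endpoints <- function(skel) {
  g <- skeleton_graph(skel)
  deg <- tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = length(g$idx))
  g$ijk[deg < 2, , drop = FALSE]
}

#' Prune short skeleton limbs
#'
#' Removes endpoint-to-junction limbs shorter than `min_length_mm` (thinning
#' noise that would otherwise create spurious centerline seeds), iterating
#' until stable.
#'
#' @param skel skeleton [label_volume()].
#' @param min_length_mm limbs shorter than this are deleted (default 5).
#' @return pruned skeleton [label_volume()].
#' @export
prune_skeleton <- function(skel, min_length_mm = 5) {
  repeat {
    g <- skeleton_graph(skel)
    n <- length(g$idx)
    adj <- vector("list", n)
    for (e in seq_len(nrow(g$edges))) {
      a <- g$edges[e, 1]; b <- g$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    deg <- lengths(adj)
    removed <- integer(0)
    for (ep in which(deg == 1)) {
      path <- ep
      prev <- 0L
      cur <- ep
      len <- 0
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0) break # isolated chain: keep
        # reaching a junction (branching voxel, or several adjacent voxels)
        # within the length budget marks the limb as a spur
        if (length(nxt) > 1 || deg[nxt[1]] >= 3) { removed <- c(removed, path); break }
        step <- sqrt(sum(((g$ijk[cur, ] - g$ijk[nxt[1], ]) * skel$spacing)^2))
        len <- len + step
        if (len >= min_length_mm) break
        prev <- cur; cur <- nxt[1]; path <- c(path, cur)
      }
    }
    if (length(removed) == 0) break
    vox <- skel$voxels
    vox[g$idx[unique(removed)]] <- 0L
    skel <- label_volume(vox, spacing = skel$spacing, origin = skel$origin)
  }
  skel
}

#' Seed points for centerline computation
#'
#' Prunes the skeleton, extracts endpoints, and applies the source rule: the
#' endpoint with the highest z-coordinate is the source seed, the remaining
#' endpoints are target seeds.
#'
#' @param skel skeleton [label_volume()].
#' @param prune_length_mm passed to [prune_skeleton()].
#' @return list with `source` (length-3 mm point) and `targets` (matrix).
#' @export
centerline_seeds <- function(skel, prune_length_mm = 5) {
  skel <- prune_skeleton(skel, prune_length_mm)
  ep <- find_endpoints(skel)
  if (nrow(ep) < 2) stop("fewer than 2 skeleton endpoints: cannot seed centerline")
  mm <- vox_to_mm(skel, ep)
  src <- which.max(mm[, 3])
  list(source = mm[src, ], targets = mm[-src, , drop = FALSE])
}

# Project mm points to the nearest foreground voxel (linear index).
project_to_mask <- function(mask, pts_mm) {
  d <- vol_dim(mask)
  fg <- which(as.vector(mask$voxels != 0L))
  if (length(fg) == 0) stop("cannot project seeds into an empty mask")
  fg_mm <- vox_to_mm(mask, idx_to_ijk(fg, d))
  pts_mm <- rbind(pts_mm)
  vapply(seq_len(nrow(pts_mm)), function(r) {
    d2 <- (fg_mm[, 1] - pts_mm[r, 1])^2 + (fg_mm[, 2] - pts_mm[r, 2])^2 +
      (fg_mm[, 3] - pts_mm[r, 3])^2
    fg[which.min(d2)]
  }, numeric(1))
}

# Spline-smooth and arc-length-resample a polyline (n x 3, mm).
refine_path <- function(pts, step, smooth_factor) {
  if (nrow(pts) < 2) return(list(points = pts, arc = 0))
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                     pts[-nrow(pts), , drop = FALSE])^2))))
  if (smooth_factor > 0 && nrow(pts) >= 10) {
    # dense evaluation grid, then smoothing spline per coordinate
    grid <- seq(0, max(arc), by = min(step / 4, max(arc) / 50))
    sm <- vapply(1:3, function(c2) {
      fit <- smooth.spline(arc, pts[, c2], spar = 0.3 + 0.7 * smooth_factor)
      predict(fit, grid)$y
    }, numeric(length(grid)))
    pts <- sm
    arc <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                       pts[-nrow(pts), , drop = FALSE])^2))))
  }
  total <- max(arc)
  n_out <- max(2, round(total / step) + 1)
  s_out <- seq(0, total, length.out = n_out)
  out <- vapply(1:3, function(c2) approx(arc, pts[, c2], xout = s_out)$y,
                numeric(n_out))
  list(points = out, arc = s_out)
}

# Unit tangents of a polyline by central differences.
path_tangents <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(matrix(c(0, 0, 1), 1))
  fwd <- rbind(pts[-1, , drop = FALSE], pts[n, , drop = FALSE])
  bwd <- rbind(pts[1, , drop = FALSE], pts[-n, , drop = FALSE])
  tg <- fwd - bwd
  len <- sqrt(rowSums(tg^2))
  len[len < 1e-12] <- 1
  tg / len
}

# Trilinear interpolation of a scalar voxel field at mm points.
interp_field <- function(field, vol, pts_mm) {
  d <- dim(field)
  v <- mm_to_vox(vol, pts_mm)
  v[, 1] <- pmin(pmax(v[, 1], 1), d[1]); v[, 2] <- pmin(pmax(v[, 2], 1), d[2])
  v[, 3] <- pmin(pmax(v[, 3], 1), d[3])
  i0 <- floor(v)
  i0[, 1] <- pmin(i0[, 1], d[1] - 1); i0[, 2] <- pmin(i0[, 2], d[2] - 1)
  i0[, 3] <- pmin(i0[, 3], d[3] - 1)
  f <- v - i0
  out <- numeric(nrow(v))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    out <- out + w * field[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}

#' Compute the refined center aortic line (CAL)
#'
#' Medial paths from the source seed to each target seed through the interior
#' of the vessel mask: shortest paths on the foreground voxel graph
#' (26-neighbourhood) with edge cost `length / (clearance + eps)^2`, where
#' clearance is the Euclidean distance to the wall, so paths maximize their
#' distance from the wall. Each raw path is spline-smoothed
#' (`smooth_factor`) and resampled at `resampling_step` mm; the maximal
#' inscribed-sphere radius (wall distance) is recorded per point.
#'
#' @param mask binary [label_volume()] of the vessel (lumen or whole aorta).
#' @param source length-3 mm point (projected to the mask interior).
#' @param targets matrix of mm target points (one per row).
#' @param params a [centerline_params()].
#' @return An object of class `centerline` with one branch per target:
#'   `branches` is a list of lists with `points` (n x 3 mm), `arc` (mm),
#'   `tangents`, `radius` (mm); `raw_paths` holds the unsmoothed voxel paths.
#' @export
compute_centerline <- function(mask, source, targets, params = centerline_params()) {
  stopifnot(inherits(mask, "label_volume"))
  targets <- rbind(targets)
  d <- vol_dim(mask)
  maskv <- as.vector(mask$voxels != 0L)
  dt_mm <- sqrt(cpp_edt_sq(!maskv, d, mask$spacing))
  src_idx <- project_to_mask(mask, source)
  tgt_idx <- project_to_mask(mask, targets)
  res <- cpp_dijkstra(maskv, d, mask$spacing, dt_mm, as.integer(src_idx - 1),
                      as.integer(tgt_idx - 1), eps = 1e-3)
  dtf <- array(dt_mm, dim = d)
  branches <- list()
  raw_paths <- list()
  for (t in seq_along(res$paths)) {
    p <- res$paths[[t]]
    if (length(p) == 0) stop("no interior path from source to target ", t,
                             ": disconnected mask")
    pts <- vox_to_mm(mask, idx_to_ijk(p, d))
    raw_paths[[t]] <- pts
    ref <- refine_path(pts, params$resampling_step, params$smooth_factor)
    branches[[t]] <- list(points = ref$points, arc = ref$arc,
                          tangents = path_tangents(ref$points),
                          radius = interp_field(dtf, mask, ref$points))
  }
  structure(list(kind = "CAL", branches = branches, raw_paths = raw_paths,
                 source = source, targets = targets, params = params),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  lens <- vapply(x$branches, function(b) max(b$arc), numeric(1))
  cat(sprintf("<centerline:%s> %d branch(es), lengths %s mm\n", x$kind,
              length(x$branches), paste(sprintf("%.1f", lens), collapse = ", ")))
  invisible(x)
}

#' Export a centerline as CSV
#'
#' Columns: branch_id, point_index, x, y, z, arc_length_mm, radius_mm.
#'
#' @param cl a [centerline()] object from [compute_centerline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  rows <- do.call(rbind, lapply(seq_along(cl$branches), function(b) {
    br <- cl$branches[[b]]
    data.frame(branch_id = b, point_index = seq_len(nrow(br$points)),
               x = br$points[, 1], y = br$points[, 2], z = br$points[, 3],
               arc_length_mm = br$arc, radius_mm = br$radius)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export a centerline as VTK XML PolyData polylines (ASCII VTP)
#'
#' @param cl a [compute_centerline()] result.
#' @param path output `.vtp` path.
#' @return `path`, invisibly.
#' @export
write_centerline_vtp <- function(cl, path) {
  pts <- do.call(rbind, lapply(cl$branches, `[[`, "points"))
  lens <- vapply(cl$branches, function(b) nrow(b$points), integer(1))
  offsets <- cumsum(lens)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    '  <PolyData>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfLines="%d">', nrow(pts),
            length(lens)),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste(as.vector(t(pts)), collapse = " "),
    '        </DataArray>', '      </Points>', '      <Lines>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(seq_len(nrow(pts)) - 1L, collapse = " "),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste(offsets, collapse = " "),
    '        </DataArray>', '      </Lines>', '    </Piece>',
    '  </PolyData>', '</VTKFile>'), con)
  invisible(path)
}
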