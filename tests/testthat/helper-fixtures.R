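# Shared fixtures, built in code and cached across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Digital ball of radius r (mm) at isotropic spacing, centred at the origin.
ball_volume <- function(r = 10, spacing = 0.5, pad = 4) {
  n <- as.integer(ceiling(2 * (r + pad) / spacing))
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  label_volume(d2 <= r^2, spacing = rep(spacing, 3),
               origin = rep(ax[1], 3))
}

# Solid cylinder along z: radius r, length L (z from 0 to L).
cylinder_volume <- function(r = 10, L = 80, spacing = 0.75, pad = 4) {
  nxy <- as.integer(ceiling(2 * (r + pad) / spacing))
  if (nxy %% 2 == 0) nxy <- nxy + 1L # axis through a voxel centre
  nz <- as.integer(ceiling(L / spacing))
  ax <- (seq_len(nxy) - (nxy + 1) / 2) * spacing
  disk <- outer(ax^2, ax^2, "+") <= r^2
  vox <- array(disk, dim = c(nxy, nxy, nz))
  label_volume(vox, spacing = rep(spacing, 3), origin = c(ax[1], ax[1], 0))
}

# Quarter-torus tube in the xz plane: centre-curve radius Rc, tube radius rt.
torus_volume <- function(Rc = 50, rt = 8, spacing = 0.75) {
  th <- seq(0, pi / 2, length.out = 400)
  curve <- cbind(Rc * cos(th), 0, Rc * sin(th))
  n <- as.integer(ceiling((Rc + rt + 6) / spacing))
  dims <- c(n + 16L, as.integer(ceiling(2 * (rt + 5) / spacing)), n + 16L)
  orig <- c(-6, -rt - 5, -6)
  v <- aortascreen:::cpp_voxelize_tubes(dims, rep(spacing, 3), orig,
    list(list(points = curve, radius = rep(rt, nrow(curve)),
              thickness = rep(0, nrow(curve)))))
  label_volume(array(v$lumen, dim = dims), rep(spacing, 3), orig)
}

# Y-tube: vertical trunk splitting at z = z_split into two down-sloping limbs.
ytube_volume <- function(z_split = 20, z_top = 70, r = 2.5, spacing = 1) {
  s <- seq(0, z_top - z_split, by = 0.4)
  trunk <- cbind(0, 0, z_split + s)
  sb <- seq(0, 25, by = 0.4)
  dirn <- function(sg) cbind(sg * 2 * sb, 0.2 * sb, -sb) / sqrt(2^2 + 0.2^2 + 1)
  limb1 <- sweep(dirn(1), 2, c(0, 0, z_split), `+`)
  limb2 <- sweep(dirn(-1), 2, c(0, 0, z_split), `+`)
  curves <- lapply(list(trunk, limb1, limb2), function(p)
    list(points = p, radius = rep(r, nrow(p)), thickness = rep(0, nrow(p))))
  allp <- do.call(rbind, lapply(curves, `[[`, "points"))
  lo <- apply(allp, 2, min) - r - 3 * spacing
  hi <- apply(allp, 2, max) + r + 3 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  v <- aortascreen:::cpp_voxelize_tubes(dims, rep(spacing, 3), lo, curves)
  label_volume(array(v$lumen, dim = dims), rep(spacing, 3), lo)
}

# Inverted-U (candy-cane) tube with apex at z = apex; thin tube so the
# slice-component merge happens within a couple of slices of the apex.
arch_tube_volume <- function(apex = 120, bend_r = 30, r = 1.5, spacing = 1) {
  z0 <- apex - bend_r
  th <- seq(0, pi, by = 0.4 / bend_r)
  bend <- cbind(bend_r - bend_r * cos(th), 0, z0 + bend_r * sin(th))
  legs <- seq(0.4, 60, by = 0.4)
  left <- cbind(0, 0, z0 - legs)
  right <- cbind(2 * bend_r, 0, z0 - legs)
  pts <- rbind(left[nrow(left):1, ], bend, right)
  lo <- apply(pts, 2, min) - r - 3 * spacing
  hi <- apply(pts, 2, max) + r + 3 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  v <- aortascreen:::cpp_voxelize_tubes(dims, rep(spacing, 3), lo,
    list(list(points = pts, radius = rep(r, nrow(pts)),
              thickness = rep(0, nrow(pts)))))
  label_volume(array(v$lumen, dim = dims), rep(spacing, 3), lo)
}

# A hand-built voxel chain as a label volume (for endpoint tests).
chain_volume <- function(ijk, dims = NULL, spacing = 1) {
  ijk <- rbind(ijk)
  if (is.null(dims)) dims <- apply(ijk, 2, max) + 2L
  vox <- array(0L, dim = dims)
  vox[ijk] <- 1L
  label_volume(vox, spacing = rep(spacing, 3), origin = c(0, 0, 0))
}

# Cached standard phantoms and their measurements (expensive).
aaa50_phantom <- function() fixture("aaa50", function()
  generate_phantom(case_phantom_spec(50, seed = 7)))
aaa50_result <- function() fixture("aaa50_res", function() {
  ph <- aaa50_phantom()
  measure_case(ph$lumen, ph$thrombus, screen_config(keep_geometry = TRUE),
               case_id = "aaa50")
})
control22_phantom <- function() fixture("ctrl22", function()
  generate_phantom(case_phantom_spec(22, seed = 11)))
control22_result <- function() fixture("ctrl22_res", function() {
  ph <- control22_phantom()
  measure_case(ph$lumen, ph$thrombus, screen_config(keep_geometry = TRUE),
               case_id = "ctrl22")
})
arch55_phantom <- function() fixture("arch55", function()
  generate_phantom(case_phantom_spec(55, arch = TRUE, seed = 3)))
arch55_result <- function() fixture("arch55_res", function() {
  ph <- arch55_phantom()
  measure_case(ph$lumen, ph$thrombus, screen_config(keep_geometry = TRUE),
               case_id = "arch55")
})

# Brute-force morphological oracle (tiny grids only): ball-structuring-element
# dilation/erosion by direct neighbourhood maxima/minima.
brute_dilate <- function(vox, spacing, radius) {
  d <- dim(vox)
  out <- array(FALSE, dim = d)
  rs <- ceiling(radius / spacing)
  offs <- expand.grid(dx = -rs[1]:rs[1], dy = -rs[2]:rs[2], dz = -rs[3]:rs[3])
  offs <- offs[sqrt((offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 +
                      (offs$dz * spacing[3])^2) <= radius + 1e-9, ]
  fg <- which(vox != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(fg[, 1] + offs$dx[r], fg[, 2] + offs$dy[r], fg[, 3] + offs$dz[r])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    out[nb[ok, , drop = FALSE]] <- TRUE
  }
  out
}

brute_erode <- function(vox, spacing, radius) {
  !brute_dilate(!(vox != 0), spacing, radius)
}
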