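# Whole-aorta model building: mask fusion, morphological smoothing, isosurface
# extraction, and triangle-mesh utilities.

#' Fuse lumen and thrombus masks into a whole-aorta mask
#'
#' Binary union ("summation") of the two segmentations on a shared grid; the
#' thrombus mask may be empty.
#'
#' @param lumen,thrombus binary [label_volume()]s on the same grid.
#' @return binary [label_volume()] of the whole aorta.
#' @export
fuse_lumen_thrombus <- function(lumen, thrombus) {
  stopifnot(inherits(lumen, "label_volume"), inherits(thrombus, "label_volume"))
  if (!same_grid(lumen, thrombus))
    stop("lumen and thrombus masks must share grid (shape, spacing, origin)")
  label_volume(lumen$voxels != 0L | thrombus$voxels != 0L,
               spacing = lumen$spacing, origin = lumen$origin)
}

# Euclidean dilation/erosion with a ball of physical radius r (mm), realised
# by thresholding the exact distance transform.
dilate_ball <- function(vol, radius_mm) {
  d <- vol_dim(vol)
  dt2 <- cpp_edt_sq(as.vector(vol$voxels != 0L), d, vol$spacing)
  label_volume(array(dt2 <= radius_mm^2 + 1e-9, dim = d),
               spacing = vol$spacing, origin = vol$origin)
}

erode_ball <- function(vol, radius_mm) {
  d <- vol_dim(vol)
  dt2 <- cpp_edt_sq(as.vector(vol$voxels == 0L), d, vol$spacing)
  label_volume(array(vol$voxels != 0L & dt2 > radius_mm^2 + 1e-9, dim = d),
               spacing = vol$spacing, origin = vol$origin)
}

#' Morphologically smooth a binary mask
#'
#' Closing (dilation then erosion) followed by opening (erosion then
#' dilation) with a Euclidean ball of the given physical radius. Closing
#' fills surface pits and thin gaps; opening removes spikes and isolated
#' islands. Radius 0 returns the mask unchanged.
#'
#' @param mask binary [label_volume()].
#' @param radius_mm structuring-element radius in mm (default 1.5).
#' @return smoothed binary [label_volume()].
#' @export
smooth_mask <- function(mask, radius_mm = 1.5) {
  stopifnot(inherits(mask, "label_volume"))
  if (!is.finite(radius_mm) || radius_mm < 0) stop("radius must be >= 0")
  if (radius_mm == 0) return(mask)
  closed <- erode_ball(dilate_ball(mask, radius_mm), radius_mm)
  dilate_ball(erode_ball(closed, radius_mm), radius_mm)
}

#' Construct a triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param provenance free-form tag (`"lumen"`, `"aorta"`, ...).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, provenance = "aorta") {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3) stop("vertices/triangles must have 3 columns")
  if (nrow(triangles) > 0 && (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  structure(list(vertices = vertices, triangles = triangles, provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh:%s> %d vertices, %d triangles, area %.1f mm^2\n",
              x$provenance, nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Extract a triangulated isosurface from a binary mask
#'
#' The binary indicator is padded, lightly smoothed with a Gaussian (to
#' suppress voxel staircase artifacts; a flat boundary's 0.5 level set is
#' unmoved by this), and triangulated with a marching-tetrahedra variant of
#' the marching-cubes algorithm on the native anisotropic grid. Vertices are
#' in mm. The result is watertight for masks that do not touch the array
#' boundary (padding guarantees this).
#'
#' @param mask binary [label_volume()]; must contain foreground.
#' @param level iso level between the two labels (default 0.5).
#' @param sigma_vox Gaussian pre-smoothing sigma in voxels (default 1; 0
#'   disables smoothing and yields the raw mid-voxel staircase surface).
#' @param provenance tag stored on the mesh.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(mask, level = 0.5, sigma_vox = 1, provenance = "aorta") {
  stopifnot(inherits(mask, "label_volume"))
  if (sum(mask$voxels != 0L) == 0) stop("no foreground: cannot extract a surface")
  pad <- as.integer(max(2, ceiling(3 * sigma_vox) + 1))
  d <- vol_dim(mask)
  dp <- d + 2L * pad
  field <- array(0, dim = dp)
  field[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <-
    as.numeric(mask$voxels != 0L)
  if (sigma_vox > 0)
    field <- array(cpp_gauss3d(as.vector(field), dp, rep(sigma_vox, 3)), dim = dp)
  origin <- mask$origin - pad * mask$spacing
  res <- cpp_march_tetra(as.vector(field), dp, mask$spacing, origin, level - 1e-7)
  tri <- res$triangles
  keep <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  surface_mesh(res$vertices, tri[keep, , drop = FALSE], provenance = provenance)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  if (nrow(Tm) == 0) return(0)
  a <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Volume enclosed by a closed mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; the absolute value
#' is returned, so orientation does not matter for closed surfaces.
#'
#' @param mesh a closed [surface_mesh()].
#' @return numeric scalar (mm^3).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  if (nrow(Tm) == 0) return(0)
  v1 <- V[Tm[, 1], , drop = FALSE]
  v2 <- V[Tm[, 2], , drop = FALSE]
  v3 <- V[Tm[, 3], , drop = FALSE]
  s <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
       v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
       v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(s)) / 6
}

#' Check that every mesh edge is shared by exactly two triangles
#' @param mesh a [surface_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  Tm <- mesh$triangles
  if (nrow(Tm) == 0) return(FALSE)
  e <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Export a mesh as Wavefront OBJ
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (triangles only)
#' @param path OBJ file path.
#' @return A [surface_mesh()].
#' @export
read_surface_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  Tm <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  surface_mesh(V, Tm)
}

#' Export a mesh as VTK XML PolyData (ASCII VTP)
#' @param mesh a [surface_mesh()].
#' @param path output `.vtp` path.
#' @return `path`, invisibly.
#' @export
write_surface_vtp <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    '  <PolyData>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">', nv, nt),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">'), con)
  writeLines(paste(as.vector(t(mesh$vertices)), collapse = " "), con)
  writeLines(c('        </DataArray>', '      </Points>', '      <Polys>',
               '        <DataArray type="Int64" Name="connectivity" format="ascii">'), con)
  writeLines(paste(as.vector(t(mesh$triangles)) - 1L, collapse = " "), con)
  writeLines(c('        </DataArray>',
               '        <DataArray type="Int64" Name="offsets" format="ascii">'), con)
  writeLines(paste(seq_len(nt) * 3L, collapse = " "), con)
  writeLines(c('        </DataArray>', '      </Polys>', '    </Piece>',
               '  </PolyData>', '</VTKFile>'), con)
  invisible(path)
}
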