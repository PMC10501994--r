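# Mesh-plane intersection (cross-section contours) and half-space clipping
# with boundary capping.

# Orthonormal in-plane basis for a unit normal.
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3], n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, v = v)
}

# Intersect a triangle mesh with a plane. Returns a list of contours, each a
# list(points = k x 3 matrix in order, closed = logical).
mesh_plane_contours <- function(mesh, origin, normal) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  n <- normal / sqrt(sum(normal^2))
  dv <- as.vector(V %*% n) - sum(origin * n)
  dv[abs(dv) < 1e-9] <- 1e-9 # avoid vertices exactly on the plane
  pos <- dv > 0
  np <- pos[Tm[, 1]] + pos[Tm[, 2]] + pos[Tm[, 3]]
  sel <- which(np == 1L | np == 2L)
  if (length(sel) == 0) return(list())
  nv <- nrow(V)
  # crossing edges of the selected triangles
  pair_idx <- list(c(1, 2), c(2, 3), c(3, 1))
  rows <- list()
  for (k in 1:3) {
    a <- Tm[sel, pair_idx[[k]][1]]
    b <- Tm[sel, pair_idx[[k]][2]]
    crossing <- pos[a] != pos[b]
    if (any(crossing))
      rows[[k]] <- cbind(tri = sel[crossing], a = a[crossing], b = b[crossing])
  }
  rows <- do.call(rbind, rows)
  key <- pmin(rows[, "a"], rows[, "b"]) + (pmax(rows[, "a"], rows[, "b"])) * (nv + 1)
  ue <- unique(key)
  eid <- match(key, ue)
  # intersection point per unique edge
  first <- match(ue, key)
  A <- rows[first, "a"]; B <- rows[first, "b"]
  t <- dv[A] / (dv[A] - dv[B])
  P <- V[A, , drop = FALSE] + t * (V[B, , drop = FALSE] - V[A, , drop = FALSE])
  # per-triangle pair of unique-edge ids
  ord <- order(rows[, "tri"])
  reid <- eid[ord]
  # every selected triangle contributes exactly 2 crossing edges
  tpair <- matrix(reid, ncol = 2, byrow = TRUE)
  # adjacency: edge -> triangles (each cut edge belongs to <= 2 cut triangles)
  ntri <- nrow(tpair)
  edge_tris <- split(rep(seq_len(ntri), 2), c(tpair[, 1], tpair[, 2]))
  used <- logical(ntri)
  contours <- list()
  for (start in seq_len(ntri)) {
    if (used[start]) next
    # walk forward from this triangle
    walk_dir <- function(tri0, edge0) {
      pts <- integer(0)
      tri <- tri0; edge <- edge0
      repeat {
        used[tri] <<- TRUE
        other <- setdiff(tpair[tri, ], edge)
        if (length(other) == 0) other <- edge # degenerate duplicate pair
        edge <- other[1]
        pts <- c(pts, edge)
        nxt <- setdiff(edge_tris[[as.character(edge)]], tri)
        nxt <- nxt[!used[nxt]]
        if (length(nxt) == 0) break
        tri <- nxt[1]
      }
      pts
    }
    e_start <- tpair[start, 1]
    fwd <- walk_dir(start, e_start)
    chain <- c(e_start, fwd)
    closed <- FALSE
    if (length(chain) >= 4 && chain[length(chain)] == chain[1]) {
      closed <- TRUE
      chain <- chain[-length(chain)]
    }
    if (!closed) {
      # extend backwards from the start edge through the unused neighbour
      back_tris <- edge_tris[[as.character(e_start)]]
      back_tris <- back_tris[!used[back_tris]]
      if (length(back_tris) > 0) {
        bwd <- walk_dir(back_tris[1], e_start)
        chain <- c(rev(bwd), chain)
      }
    }
    contours[[length(contours) + 1]] <-
      list(points = P[chain, , drop = FALSE], closed = closed)
  }
  contours
}

# Test whether a 2D point lies inside a polygon (ray casting).
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Shoelace area of an ordered polygon.
polygon_area <- function(xs, ys) {
  n <- length(xs)
  j <- c(n, seq_len(n - 1))
  abs(sum(xs[j] * ys - xs * ys[j])) / 2
}

#' Clip a mesh with a plane, keeping the negative half-space
#'
#' Keeps vertices with `(p - origin) . normal <= 0`; crossing triangles are
#' split at the plane and the resulting boundary loops are capped with
#' triangle fans so the output stays closed.
#'
#' @param mesh a [surface_mesh()].
#' @param origin point on the clip plane (mm).
#' @param normal plane normal; the side it points to is removed.
#' @param cap triangulate the cut boundary (default TRUE).
#' @return clipped [surface_mesh()].
#' @export
clip_mesh <- function(mesh, origin, normal, cap = TRUE) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  n <- normal / sqrt(sum(normal^2))
  dv <- as.vector(V %*% n) - sum(origin * n)
  dv[abs(dv) < 1e-9] <- -1e-9
  keep <- dv <= 0
  nk <- keep[Tm[, 1]] + keep[Tm[, 2]] + keep[Tm[, 3]]
  if (all(nk == 3L)) return(mesh)
  if (all(nk == 0L)) return(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3),
                                         provenance = mesh$provenance))
  newV <- list()
  nv <- nrow(V)
  edge_cache <- new.env(hash = TRUE)
  cut_vertex <- function(a, b) {
    k <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
    hit <- edge_cache[[k]]
    if (!is.null(hit)) return(hit)
    t <- dv[a] / (dv[a] - dv[b])
    p <- V[a, ] + t * (V[b, ] - V[a, ])
    newV[[length(newV) + 1]] <<- p
    id <- nv + length(newV)
    edge_cache[[k]] <- id
    id
  }
  out_tris <- list()
  boundary <- list() # directed cut edges (kept-region boundary)
  full <- which(nk == 3L)
  if (length(full) > 0) out_tris[[1]] <- Tm[full, , drop = FALSE]
  for (tid in which(nk == 1L | nk == 2L)) {
    tri <- Tm[tid, ]
    kin <- keep[tri]
    # rotate so pattern starts at a kept vertex
    rot <- which(kin)[1]
    tri <- tri[((rot - 1 + 0:2) %% 3) + 1]
    kin <- keep[tri]
    if (sum(kin) == 1L) {
      a <- tri[1]; b <- tri[2]; c2 <- tri[3] # a kept, b/c out
      p1 <- cut_vertex(a, b)
      p2 <- cut_vertex(c2, a)
      out_tris[[length(out_tris) + 1]] <- matrix(c(a, p1, p2), 1)
      boundary[[length(boundary) + 1]] <- c(p1, p2)
    } else {
      # two kept: rotate so the single outside vertex is third
      while (keep[tri[3]]) tri <- tri[c(2, 3, 1)]
      a <- tri[1]; b <- tri[2]; c2 <- tri[3] # a,b kept, c out
      p1 <- cut_vertex(b, c2)
      p2 <- cut_vertex(c2, a)
      out_tris[[length(out_tris) + 1]] <- matrix(c(a, b, p1, a, p1, p2), 2, 3, byrow = TRUE)
      boundary[[length(boundary) + 1]] <- c(p1, p2)
    }
  }
  Vall <- rbind(V, do.call(rbind, newV))
  Tall <- do.call(rbind, out_tris)
  if (cap && length(boundary) > 0) {
    # chain directed boundary edges into loops and fan-triangulate
    be <- do.call(rbind, boundary)
    visited <- logical(nrow(be))
    for (s in seq_len(nrow(be))) {
      if (visited[s]) next
      loop <- be[s, 1]
      cur <- s
      repeat {
        visited[cur] <- TRUE
        endv <- be[cur, 2]
        if (endv == loop[1]) break
        loop <- c(loop, endv)
        nxt_idx <- match(endv, be[, 1])
        if (is.na(nxt_idx) || visited[nxt_idx]) break
        cur <- nxt_idx
      }
      if (length(loop) >= 3) {
        centroid <- colMeans(Vall[loop, , drop = FALSE])
        Vall <- rbind(Vall, centroid)
        cid <- nrow(Vall)
        fan <- cbind(loop, c(loop[-1], loop[1]), cid)
        # orient cap triangles to face along +normal (outward from kept side)
        a <- Vall[fan[, 2], , drop = FALSE] - Vall[fan[, 1], , drop = FALSE]
        b <- Vall[fan[, 3], , drop = FALSE] - Vall[fan[, 1], , drop = FALSE]
        cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
        cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
        cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
        flip <- (cx * n[1] + cy * n[2] + cz * n[3]) < 0
        fan[flip, ] <- fan[flip, c(1, 3, 2), drop = FALSE]
        Tall <- rbind(Tall, fan)
      }
    }
  }
  # drop unreferenced vertices
  used_v <- sort(unique(as.vector(Tall)))
  remap <- integer(nrow(Vall))
  remap[used_v] <- seq_along(used_v)
  Tall <- matrix(remap[Tall], ncol = 3)
  surface_mesh(Vall[used_v, , drop = FALSE], Tall, provenance = mesh$provenance)
}

#' Crop a mesh between two axial levels
#'
#' Clips with two horizontal planes at `z_arch` (above removed) and `z_iliac`
#' (below removed) and caps the cut rings. Planes outside the mesh extent are
#' skipped with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param z_arch,z_iliac axial bounds in mm, `z_arch > z_iliac`.
#' @return cropped [surface_mesh()].
#' @export
crop_to_bounds <- function(mesh, z_arch, z_iliac) {
  if (z_arch <= z_iliac) stop("z_arch must be above z_iliac")
  zr <- range(mesh$vertices[, 3])
  out <- mesh
  if (z_arch < zr[2]) out <- clip_mesh(out, c(0, 0, z_arch), c(0, 0, 1))
  else if (z_arch > zr[2]) warning("arch plane above mesh extent: no superior crop")
  if (z_iliac > zr[1]) out <- clip_mesh(out, c(0, 0, z_iliac), c(0, 0, -1))
  else if (z_iliac < zr[1]) warning("iliac plane below mesh extent: no inferior crop")
  out
}
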