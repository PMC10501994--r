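# Abdominal-tract isolation: branch decomposition of the centerline,
# bifurcation planes, renal-plane identification, and clipping of surface and
# centerline between the renal and iliac levels.

#' Decompose a centerline into branches at divergence points
#'
#' Paths from the common source to different targets share a prefix (they are
#' branches of one shortest-path tree); the centerline is split wherever
#' paths to different targets diverge. The tract between two consecutive
#' divergences is a single branch.
#'
#' @param cal a [compute_centerline()] result with >= 1 target.
#' @return `cal` with `branch_decomp` (list of branches: `points`, mm matrix;
#'   `targets`, indices of targets downstream) and `divergences` (list of
#'   divergence records: `point`, `children_targets`).
#' @export
split_branches <- function(cal) {
  stopifnot(inherits(cal, "centerline"))
  paths <- cal$raw_paths
  keys <- lapply(paths, function(p) paste(round(p[, 1], 4), round(p[, 2], 4),
                                          round(p[, 3], 4)))
  branches <- list()
  divergences <- list()
  rec <- function(idxs, from) {
    if (length(idxs) == 1) {
      p <- paths[[idxs]]
      if (from <= nrow(p))
        branches[[length(branches) + 1]] <<- list(
          points = p[max(1, from - 1):nrow(p), , drop = FALSE], targets = idxs)
      return(invisible())
    }
    k1 <- keys[[idxs[1]]]
    minlen <- min(vapply(idxs, function(i) length(keys[[i]]), numeric(1)))
    j <- from
    while (j <= minlen) {
      kj <- vapply(idxs, function(i) keys[[i]][j], character(1))
      if (!all(kj == kj[1])) break
      j <- j + 1
    }
    last_common <- j - 1
    p <- paths[[idxs[1]]]
    branches[[length(branches) + 1]] <<- list(
      points = p[max(1, from - 1):last_common, , drop = FALSE], targets = idxs)
    if (j > minlen && all(vapply(idxs, function(i) length(keys[[i]]), numeric(1)) ==
                          minlen)) return(invisible()) # all paths identical
    divergences[[length(divergences) + 1]] <<- list(
      point = p[last_common, ], children_targets = idxs)
    nxt <- vapply(idxs, function(i)
      if (length(keys[[i]]) >= j) keys[[i]][j] else "<end>", character(1))
    for (g in unique(nxt)) {
      sub <- idxs[nxt == g]
      if (g != "<end>") rec(sub, j)
    }
    invisible()
  }
  rec(seq_along(paths), 1)
  cal$branch_decomp <- branches
  cal$divergences <- divergences
  cal
}

# Move a tree-divergence point to the geometric separation of its child
# paths. The shortest-path tree can fork early (e.g. inside a wide aneurysmal
# chamber) while the child paths keep running together, or re-converge before
# splitting for good; the plane origin is therefore the LAST point along the
# first child at which every other child path is still within sep_tol_mm.
refine_divergence <- function(branched, dv, sep_tol_mm) {
  paths <- branched$raw_paths
  idxs <- dv$children_targets
  p0 <- dv$point
  segs <- lapply(idxs, function(i) {
    p <- paths[[i]]
    d2 <- rowSums(sweep(p, 2, p0)^2)
    i0 <- which.min(d2)
    p[i0:nrow(p), , drop = FALSE]
  })
  A <- segs[[1]]
  if (nrow(A) < 2 || length(segs) < 2) return(p0)
  last_ok <- NA
  for (r in seq_len(nrow(A))) {
    dmax <- 0
    for (b in 2:length(segs)) {
      B <- segs[[b]]
      if (nrow(B) == 0) next
      dmin <- min(sqrt((B[, 1] - A[r, 1])^2 + (B[, 2] - A[r, 2])^2 +
                         (B[, 3] - A[r, 3])^2))
      dmax <- max(dmax, dmin)
    }
    if (dmax <= sep_tol_mm) last_ok <- r
  }
  if (is.na(last_ok)) p0 else A[last_ok, ]
}

# Local unit tangent of the trunk raw path at a given point, oriented with
# positive z (superior).
trunk_tangent_at <- function(cal, point, window_mm = 6) {
  # use the longest raw path through this point as trunk reference
  best <- NULL; best_d <- Inf; best_i <- NA
  for (p in cal$raw_paths) {
    d2 <- rowSums(sweep(p, 2, point)^2)
    i <- which.min(d2)
    if (d2[i] < best_d) { best <- p; best_d <- d2[i]; best_i <- i }
  }
  arc <- c(0, cumsum(sqrt(rowSums((best[-1, , drop = FALSE] -
                                     best[-nrow(best), , drop = FALSE])^2))))
  lo <- which(arc >= arc[best_i] - window_mm)[1]
  hi <- tail(which(arc <= arc[best_i] + window_mm), 1)
  tg <- best[hi, ] - best[lo, ]
  tg <- tg / sqrt(sum(tg^2))
  if (tg[3] < 0) tg <- -tg
  tg
}

#' Compute bifurcation planes at centerline divergences
#'
#' One plane per divergence point, normal along the local trunk tangent. The
#' shortest-path tree can split while the two child paths still run side by
#' side inside the shared vessel, so the plane origin is refined from the
#' tree divergence to the point of geometric separation: the last point at
#' which the two child paths remain within `sep_tol_mm` of each other. The
#' most inferior divergence is labelled `iliac` (the iliac split is the
#' lowest division of the tract); all others are labelled `other` pending
#' [find_renal_plane()]. Planes are ordered by decreasing z.
#'
#' @param surface the aorta [surface_mesh()] (kept for interface symmetry;
#'   the planes derive from the centerline geometry).
#' @param branched a [split_branches()] result.
#' @param sep_tol_mm two child paths count as separated once they are more
#'   than this far apart (default 2.5 mm).
#' @return list of `bifurcation_plane` objects (fields `origin`, `normal`,
#'   `label`); empty when the centerline never diverges.
#' @export
bifurcation_planes <- function(surface, branched, sep_tol_mm = 2.5) {
  if (is.null(branched$divergences)) branched <- split_branches(branched)
  divs <- branched$divergences
  if (length(divs) == 0) return(list())
  planes <- lapply(divs, function(dv) {
    origin <- refine_divergence(branched, dv, sep_tol_mm)
    structure(list(origin = origin,
                   normal = trunk_tangent_at(branched, origin),
                   label = "other",
                   children_targets = dv$children_targets),
              class = "bifurcation_plane")
  })
  zs <- vapply(planes, function(p) p$origin[3], numeric(1))
  planes <- planes[order(zs, decreasing = TRUE)]
  planes[[length(planes)]]$label <- "iliac"
  planes
}

#' @export
print.bifurcation_plane <- function(x, ...) {
  cat(sprintf("<bifurcation_plane:%s> origin (%.1f, %.1f, %.1f) mm\n",
              x$label, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Identify the renal bifurcation plane
#'
#' The renal arteries are the last (most inferior) division of the aorta
#' above the iliac split, so the renal plane is the lowest non-iliac
#' bifurcation plane. Invariant to the ordering of `planes`.
#'
#' @param planes list of planes from [bifurcation_planes()].
#' @param iliac_plane the iliac plane to exclude (default: the one labelled
#'   `iliac`, or the most inferior).
#' @return the renal `bifurcation_plane`, relabelled `renal`.
#' @export
find_renal_plane <- function(planes, iliac_plane = NULL) {
  if (length(planes) == 0) stop("renal level not found: no bifurcation planes")
  if (is.null(iliac_plane)) {
    labs <- vapply(planes, function(p) p$label, character(1))
    if (any(labs == "iliac")) iliac_plane <- planes[[which(labs == "iliac")[1]]]
    else {
      zs <- vapply(planes, function(p) p$origin[3], numeric(1))
      iliac_plane <- planes[[which.min(zs)]]
    }
  }
  cand <- Filter(function(p) sqrt(sum((p$origin - iliac_plane$origin)^2)) > 1e-6,
                 planes)
  if (length(cand) == 0) stop("renal level not found")
  zs <- vapply(cand, function(p) p$origin[3], numeric(1))
  renal <- cand[[which.min(zs)]]
  renal$label <- "renal"
  renal
}

#' Clip surface and centerline to the abdominal tract
#'
#' The surface is clipped by the renal plane (normal facing inferior, tissue
#' above removed) and the iliac plane (normal facing superior, tissue below
#' removed), both perpendicular to the centerline. The abdominal centerline
#' is recomputed between the two plane origins (used as source and target
#' seeds) inside the mask restricted to the slab between the planes.
#'
#' @param surface aorta [surface_mesh()].
#' @param cal the (branched) [compute_centerline()] result.
#' @param renal,iliac `bifurcation_plane`s with `renal$origin[3] > iliac$origin[3]`.
#' @param mask binary [label_volume()] of the aorta used to recompute the
#'   centerline; when NULL the existing trunk is trimmed instead.
#' @param params [centerline_params()] for the recomputation.
#' @return list with `surface` (abdominal [surface_mesh()]) and `centerline`.
#' @export
clip_abdominal <- function(surface, cal, renal, iliac, mask = NULL,
                           params = centerline_params()) {
  if (renal$origin[3] <= iliac$origin[3])
    stop("renal plane must be superior to the iliac plane")
  n_r <- renal$normal / sqrt(sum(renal$normal^2))
  if (n_r[3] < 0) n_r <- -n_r # superior-pointing; clip keeps the inferior side
  n_i <- iliac$normal / sqrt(sum(iliac$normal^2))
  if (n_i[3] > 0) n_i <- -n_i # inferior-pointing; clip keeps the superior side
  surf <- clip_mesh(surface, renal$origin, n_r)
  surf <- clip_mesh(surf, iliac$origin, n_i)
  surf$provenance <- "abdominal"
  if (!is.null(mask)) {
    d <- vol_dim(mask)
    fgidx <- which(as.vector(mask$voxels != 0L))
    mm <- vox_to_mm(mask, idx_to_ijk(fgidx, d))
    below_renal <- (sweep(mm, 2, renal$origin) %*% n_r) <= 0
    above_iliac <- (sweep(mm, 2, iliac$origin) %*% n_i) <= 0
    vox <- array(0L, dim = d)
    vox[fgidx[below_renal & above_iliac]] <- 1L
    slab <- label_volume(vox, spacing = mask$spacing, origin = mask$origin)
    abd_cl <- compute_centerline(slab, renal$origin, rbind(iliac$origin), params)
  } else {
    # trim the trunk branch between the two plane origins
    trunk <- cal$branches[[which.max(vapply(cal$branches,
                                            function(b) max(b$arc), numeric(1)))]]
    dr <- as.vector(sweep(trunk$points, 2, renal$origin) %*% n_r)
    di <- as.vector(sweep(trunk$points, 2, iliac$origin) %*% n_i)
    keep <- dr <= 0 & di <= 0
    pts <- trunk$points[keep, , drop = FALSE]
    ref <- refine_path(pts, params$resampling_step, 0)
    abd_cl <- structure(list(kind = "CAL", branches = list(list(
      points = ref$points, arc = ref$arc, tangents = path_tangents(ref$points),
      radius = rep(NA_real_, length(ref$arc)))),
      raw_paths = list(pts), source = pts[1, ], targets = rbind(pts[nrow(pts), ]),
      params = params), class = "centerline")
  }
  list(surface = surf, centerline = abd_cl)
}
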