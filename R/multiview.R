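# Segmentation-side closed-form utilities: multi-view fusion, binarization,
# Dice similarity coefficient.

#' Fuse single-view prediction maps by voxelwise averaging
#'
#' The final prediction at each voxel is the arithmetic mean of the axial,
#' sagittal and coronal per-voxel probabilities:
#' `p_final(x) = (p_axial(x) + p_sagittal(x) + p_coronal(x)) / 3`.
#'
#' @param p_axial,p_sagittal,p_coronal [prob_map()]s on the same grid.
#' @return A [prob_map()] with the averaged probabilities.
#' @export
fuse_multiview <- function(p_axial, p_sagittal, p_coronal) {
  maps <- list(p_axial, p_sagittal, p_coronal)
  for (m in maps) stopifnot(inherits(m, "prob_map"))
  if (!same_grid(p_axial, p_sagittal) || !same_grid(p_axial, p_coronal))
    stop("prediction maps must share shape, spacing and origin")
  prob_map((p_axial$values + p_sagittal$values + p_coronal$values) / 3,
           spacing = p_axial$spacing, origin = p_axial$origin)
}

#' Binarize a probability map
#'
#' Foreground where probability strictly exceeds the threshold; values equal
#' to the threshold become background.
#'
#' @param p a [prob_map()].
#' @param threshold probability in (0, 1); default 0.5.
#' @return A binary [label_volume()].
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(inherits(p, "prob_map"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  label_volume(p$values > threshold, spacing = p$spacing, origin = p$origin)
}

#' Dice similarity coefficient between two binary masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`, ranging from 0 (no overlap) to 1
#' (perfect overlap). When both masks are empty the coefficient is defined as
#' 1 (perfect agreement on the absence of the structure).
#'
#' @param a,b binary [label_volume()]s of the same shape.
#' @return numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(vol_dim(a), vol_dim(b))) stop("masks must share the same shape")
  av <- a$voxels != 0L
  bv <- b$voxels != 0L
  na <- sum(av)
  nb <- sum(bv)
  if (na + nb == 0L) return(1.0)
  2 * sum(av & bv) / (na + nb)
}
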