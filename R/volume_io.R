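# Label volumes: construction, validation, NIfTI / MetaImage I/O, label
# splitting, isotropic resampling, cohort manifests.

#' Construct a label volume
#'
#' A `label_volume` carries a 3D integer voxel grid together with its physical
#' metadata. By package convention label 0 is background, 1 the aortic lumen
#' and 2 the intraluminal thrombus, and the z axis increases toward the
#' superior direction.
#'
#' @param voxels 3D integer array with labels in \{0, 1, 2\} (logical arrays
#'   are coerced, `TRUE` becoming label 1).
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, scanner-space position (mm) of voxel
#'   (1, 1, 1)'s centre.
#' @return An object of class `label_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.double(voxels) && max(abs(voxels - round(voxels))) > 1e-6)
    stop("voxels must be integer-valued labels")
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  # rebuild as a plain integer array (drops foreign classes/attributes)
  voxels <- array(as.integer(round(as.numeric(voxels))), dim = dim(voxels))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  bad <- setdiff(unique(as.vector(voxels)), c(0L, 1L, 2L))
  if (length(bad) > 0)
    stop("labels outside {0,1,2}: ", paste(sort(bad), collapse = ", "))
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(factor(as.vector(x$voxels), levels = 0:2))
  cat(sprintf("  labels: background %d, lumen %d, thrombus %d\n",
              tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

#' Construct a probability map
#'
#' Per-voxel probabilities in \[0, 1\] on the same physical grid convention as
#' [label_volume()]; used by the multi-view fusion utilities.
#'
#' @param values 3D numeric array with all values in \[0, 1\].
#' @inheritParams label_volume
#' @return An object of class `prob_map`.
#' @export
prob_map <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(!is.finite(values)) || min(values) < 0 || max(values) > 1)
    stop("probability values must lie in [0, 1]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<prob_map> %d x %d x %d voxels, values in [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

vol_dim <- function(vol) dim(vol$voxels)

same_grid <- function(a, b) {
  va <- if (inherits(a, "prob_map")) a$values else a$voxels
  vb <- if (inherits(b, "prob_map")) b$values else b$voxels
  identical(dim(va), dim(vb)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-6
}

# voxel (1-based ijk, possibly fractional) -> mm and back
vox_to_mm <- function(vol, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

mm_to_vox <- function(vol, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

#' Read a label volume from NIfTI or MetaImage
#'
#' Reads a segmentation mask and returns it in the package's canonical
#' orientation (z increasing toward superior). NIfTI files whose header
#' declares an inferior-increasing third axis are flipped along z. Labels are
#' validated against the \{0, 1, 2\} convention.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.mha`, or `.mhd`).
#' @param format `"auto"` (by extension), `"nifti"` or `"metaimage"`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    lower <- tolower(path)
    format <- if (grepl("\\.(mha|mhd)$", lower)) "metaimage" else "nifti"
  }
  if (format == "nifti") read_nifti_volume(path) else read_metaimage_volume(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) == 4L && dim(vox)[4] == 1L) vox <- vox[, , , 1L]
  hdr <- RNifti::niftiHeader(img)
  spacing <- as.numeric(hdr$pixdim[2:4])
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
  # world position of voxel (1,1,1) from the xform translation (axis-aligned
  # volumes assumed; only the z direction is canonicalized)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  orig_mm <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  if (nchar(orient) == 3 && substr(orient, 3, 3) == "I") {
    nz <- dim(vox)[3]
    vox <- vox[, , nz:1, drop = FALSE]
    orig_mm[3] <- orig_mm[3] - spacing[3] * (nz - 1)
  }
  label_volume(vox, spacing = spacing, origin = orig_mm)
}

#' Write a label volume to NIfTI
#'
#' @param vol a [label_volume()] or [prob_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  vox <- if (inherits(vol, "prob_map")) vol$values else vol$voxels
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal MetaImage reader: uncompressed MET_* element types, local or
# detached raw data. No R package in the stack reads this format.
read_metaimage_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  data_file <- NULL
  header_bytes <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of MetaImage header: ", path)
    header_bytes <- header_bytes + nchar(line, type = "bytes") + 1L
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  if (identical(toupper(hdr[["CompressedData"]]), "TRUE"))
    stop("compressed MetaImage data is not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D MetaImage volumes are supported")
  spacing <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  rt <- switch(type,
    "MET_UCHAR" = list(what = "integer", size = 1, signed = FALSE),
    "MET_CHAR" = list(what = "integer", size = 1, signed = TRUE),
    "MET_SHORT" = list(what = "integer", size = 2, signed = TRUE),
    "MET_USHORT" = list(what = "integer", size = 2, signed = FALSE),
    "MET_INT" = list(what = "integer", size = 4, signed = TRUE),
    "MET_FLOAT" = list(what = "numeric", size = 4, signed = TRUE),
    "MET_DOUBLE" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported MetaImage ElementType: ", type))
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw <- readBin(con, rt$what, n = n, size = rt$size, signed = rt$signed,
                   endian = "little")
  } else {
    dpath <- file.path(dirname(path), data_file)
    if (!file.exists(dpath)) stop("MetaImage data file not found: ", dpath)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    raw <- readBin(dcon, rt$what, n = n, size = rt$size, signed = rt$signed,
                   endian = "little")
  }
  if (length(raw) != n) stop("truncated MetaImage data in ", path)
  label_volume(array(raw, dim = dims), spacing = spacing, origin = origin)
}

#' Write a label volume as MetaImage (.mhd header + .raw data)
#'
#' @param vol a [label_volume()].
#' @param path output `.mhd` path; the raw data file is written alongside.
#' @return `path`, invisibly.
#' @export
write_metaimage_volume <- function(vol, path) {
  if (!grepl("\\.mhd$", tolower(path))) stop("path must end in .mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  d <- vol_dim(vol)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g", vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %g %g %g", vol$origin[1], vol$origin[2], vol$origin[3]),
    "ElementType = MET_UCHAR",
    paste0("ElementDataFile = ", raw_name))
  writeLines(hdr, path)
  dcon <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(dcon))
  writeBin(as.raw(as.vector(vol$voxels)), dcon)
  invisible(path)
}

#' Split a multi-label volume into lumen and thrombus masks
#'
#' @param vol a [label_volume()] with labels in \{0, 1, 2\}.
#' @return list with binary `lumen` (label 1) and `thrombus` (label 2)
#'   [label_volume()]s sharing `vol`'s grid metadata.
#' @export
split_labels <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  list(
    lumen = label_volume(vol$voxels == 1L, spacing = vol$spacing, origin = vol$origin),
    thrombus = label_volume(vol$voxels == 2L, spacing = vol$spacing, origin = vol$origin))
}

#' Resample a label volume to an isotropic grid
#'
#' Nearest-neighbour resampling preserving the physical extent. Used before
#' skeletonization, which assumes isotropic voxel adjacency.
#'
#' @param vol a [label_volume()].
#' @param target_spacing isotropic spacing in mm (default: the smallest
#'   component of the native spacing).
#' @return A [label_volume()] on the isotropic grid.
#' @export
resample_isotropic <- function(vol, target_spacing = min(vol$spacing)) {
  stopifnot(inherits(vol, "label_volume"))
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop("target_spacing must be positive")
  if (max(abs(vol$spacing - target_spacing)) < 1e-9) return(vol)
  d <- vol_dim(vol)
  newd <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  # nearest source index for each target voxel centre, per axis
  idx <- lapply(1:3, function(ax) {
    x <- ((seq_len(newd[ax]) - 1) * target_spacing) / vol$spacing[ax] + 1
    pmin(d[ax], pmax(1L, as.integer(floor(x + 0.5)))) # round half up: symmetric
  })
  vox <- vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  label_volume(vox, spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Read a cohort manifest
#'
#' A manifest CSV maps case IDs to mask paths: columns `case_id`,
#' `lumen_path`, optional `thrombus_path` (empty for cases without thrombus)
#' and optional `manual_diameter_mm`. A single multi-label file may be given
#' as `lumen_path` with `thrombus_path` empty and `multilabel` = TRUE.
#'
#' @param path manifest CSV path.
#' @return data.frame with normalized columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "lumen_path") %in% names(m)))
    stop("manifest must have columns case_id and lumen_path")
  if (is.null(m$thrombus_path)) m$thrombus_path <- NA_character_
  m$thrombus_path[!is.na(m$thrombus_path) & m$thrombus_path == ""] <- NA_character_
  if (is.null(m$manual_diameter_mm)) m$manual_diameter_mm <- NA_real_
  if (is.null(m$multilabel)) m$multilabel <- FALSE
  base <- dirname(path)
  rel <- function(p) ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
                            p, file.path(base, p))
  m$lumen_path <- rel(m$lumen_path)
  m$thrombus_path <- rel(m$thrombus_path)
  m
}

# Load the lumen/thrombus pair described by one manifest row.
load_case_masks <- function(row) {
  lum <- read_label_volume(row$lumen_path)
  if (isTRUE(row$multilabel)) {
    parts <- split_labels(lum)
    return(parts)
  }
  lum <- label_volume(lum$voxels != 0L, spacing = lum$spacing, origin = lum$origin)
  thr <- NULL
  if (!is.na(row$thrombus_path)) {
    thr <- read_label_volume(row$thrombus_path)
    thr <- label_volume(thr$voxels != 0L, spacing = thr$spacing, origin = thr$origin)
  }
  if (is.null(thr))
    thr <- label_volume(array(0L, dim = vol_dim(lum)), spacing = lum$spacing,
                        origin = lum$origin)
  list(lumen = lum, thrombus = thr)
}
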