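#' Voxel volume container
#'
#' A 3D intensity grid with voxel spacing and world origin. Voxel (i,j,k)
#' (1-based) has world position `origin + (i-1, j-1, k-1) * spacing`;
#' axes are world-aligned (no direction cosines in this pipeline).
#'
#' @param intensities 3D numeric array.
#' @param spacing length-3 voxel spacing (mm), all > 0.
#' @param origin length-3 world position of voxel (1,1,1) (mm).
#' @param polarity `"bone_bright"` (CBCT-like) or `"bone_dark"`
#'   (MRI-like).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0),
                         polarity = c("bone_bright", "bone_dark")) {
  polarity <- match.arg(polarity)
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L || any(dim(intensities) == 0L))
    stop("intensities must be a non-empty 3D array")
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), polarity = polarity),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "voxel_volume: %s voxels, spacing (%s) mm, origin (%s) mm, %s\n",
    paste(dim(x$intensities), collapse = " x "),
    paste(format(x$spacing), collapse = ", "),
    paste(format(x$origin), collapse = ", "), x$polarity))
  invisible(x)
}

#' Align a volume's origin to the global origin
#'
#' Sets the world origin to (0,0,0), shifting all voxel world coordinates
#' consistently (the first reorientation step applied to scan data).
#'
#' @param volume a `voxel_volume`.
#' @return the volume with origin (0,0,0); attribute `origin_shift` holds
#'   the translation removed.
#' @export
align_origin <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  shift <- volume$origin
  volume$origin <- c(0, 0, 0)
  attr(volume, "origin_shift") <- shift
  volume
}

#' Threshold a volume into a bone mask
#'
#' Marks voxels with intensity in `[lo, hi]`. The caller picks the band by
#' polarity: a high band for bone-bright (CBCT-like) data, a low band for
#' bone-dark (MRI-like) data.
#'
#' @param volume a `voxel_volume`.
#' @param lo,hi inclusive intensity band, `lo <= hi`.
#' @return a `segmentation_mask`: logical 3D array congruent with the
#'   volume plus provenance (thresholds, seeds, flags).
#' @export
threshold_bone <- function(volume, lo, hi = Inf) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (lo > hi) stop("lo must not exceed hi")
  m <- volume$intensities >= lo & volume$intensities <= hi
  prov <- list(lo = lo, hi = hi, seeds = NULL,
               empty = !any(m))
  if (prov$empty) warning("threshold band selects no voxels")
  segmentation_mask(m, volume, prov)
}

segmentation_mask <- function(mask, volume, provenance = list()) {
  structure(list(mask = mask, spacing = volume$spacing,
                 origin = volume$origin, provenance = provenance),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %s voxels, %d selected\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Default polarity-aware threshold band
#'
#' Convenience: half-way between the bone and background intensity bands
#' used by the phantom renderer; for measured data pass explicit `lo`/`hi`
#' to [threshold_bone()].
#'
#' @param volume a `voxel_volume`.
#' @return list with `lo` and `hi`.
#' @export
default_bone_band <- function(volume) {
  if (volume$polarity == "bone_bright") list(lo = 500, hi = Inf)
  else list(lo = -Inf, hi = 500)
}

#' Keep mask components connected to seed voxels
#'
#' Deterministic stand-in for the operator's brush: retains only the
#' 26-connected components of the thresholded mask that contain at least
#' one seed voxel, discarding neighbouring bone not belonging to the
#' structure of interest.
#'
#' @param mask a `segmentation_mask`.
#' @param seeds matrix (or vector) of 1-based voxel indices, one (i,j,k)
#'   row per seed.
#' @return the restricted `segmentation_mask`.
#' @export
seeded_select <- function(mask, seeds) {
  stopifnot(inherits(mask, "segmentation_mask"))
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  dims <- dim(mask$mask)
  if (any(seeds < 1L) || any(sweep(seeds, 2L, dims, ">")))
    stop("seed outside grid")
  lin <- (seeds[, 1L] - 1L) + dims[1L] * ((seeds[, 2L] - 1L) +
          dims[2L] * (seeds[, 3L] - 1L))
  onmask <- mask$mask[lin + 1L]
  if (any(!onmask)) {
    warning(sprintf("%d seed(s) fall on unselected voxels and are ignored",
                    sum(!onmask)))
    lin <- lin[onmask]
  }
  reached <- cpp_flood_fill(as.vector(mask$mask), dims, lin, 26L)
  mask$mask <- array(reached, dims)
  mask$provenance$seeds <- seeds
  mask
}

#' Fill internal cavities of a mask
#'
#' Background components not 6-connected to the grid boundary are enclosed
#' cavities; they are set to foreground so the segmented solid has no
#' internal holes.
#'
#' @param mask a `segmentation_mask`.
#' @return the filled `segmentation_mask`.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  dims <- dim(mask$mask)
  bg <- !mask$mask
  # all boundary voxels as candidate seeds
  idx <- arrayInd(which(bg), dims)
  onb <- idx[, 1L] == 1L | idx[, 1L] == dims[1L] |
         idx[, 2L] == 1L | idx[, 2L] == dims[2L] |
         idx[, 3L] == 1L | idx[, 3L] == dims[3L]
  seeds <- which(bg)[onb] - 1L
  outside <- cpp_flood_fill(as.vector(bg), dims, seeds, 6L)
  mask$mask <- array(!outside, dims)
  mask
}

#' Extract a surface mesh from a mask
#'
#' Iso-surface of the binary mask at level 0.5 (marching tetrahedra on the
#' 0/1 field), mapped to world millimetres via the mask's spacing and
#' origin. The mask is padded by one background layer first so the surface
#' is always closed; the result is watertight and outward-oriented.
#'
#' @param mask a `segmentation_mask`.
#' @param level iso level on the binary field (default 0.5).
#' @return a `triangle_mesh` in world coordinates.
#' @export
extract_mesh <- function(mask, level = 0.5) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (!any(mask$mask)) stop("cannot extract a mesh from an empty mask")
  dims <- dim(mask$mask)
  padded <- array(0, dims + 2L)
  padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <-
    as.numeric(mask$mask)
  res <- cpp_marching_tets(as.vector(padded), dim(padded), level)
  v <- res$vertices
  for (ax in 1:3)
    v[, ax] <- mask$origin[ax] + (v[, ax] - 1) * mask$spacing[ax]
  m <- triangle_mesh(v, res$faces, validate = FALSE)
  orient_outward(m)
  # marching tetrahedra orients towards increasing field = into the solid
  # here (mask is 1 inside); orient_outward fixes the global orientation
}

#' Segment a bone volume end to end
#'
#' The full segmentation chain: origin alignment, polarity-aware
#' thresholding, seeded selection, hole filling and mesh extraction.
#'
#' @param volume a `voxel_volume`.
#' @param lo,hi threshold band; defaults to [default_bone_band()].
#' @param seeds optional seed voxels for [seeded_select()]; `NULL` keeps
#'   all components.
#' @return a `triangle_mesh`; the final mask in attribute `mask`.
#' @export
segment_volume <- function(volume, lo = NULL, hi = NULL, seeds = NULL) {
  band <- default_bone_band(volume)
  lo <- lo %||% band$lo
  hi <- hi %||% band$hi
  volume <- align_origin(volume)
  m <- threshold_bone(volume, lo, hi)
  if (!is.null(seeds)) m <- seeded_select(m, seeds)
  m <- fill_holes(m)
  mesh <- extract_mesh(m)
  attr(mesh, "mask") <- m
  mesh
}

#' Mask volume in mm^3
#'
#' @param mask a `segmentation_mask`.
#' @return number of selected voxels times the voxel cell volume.
#' @export
mask_volume <- function(mask) {
  sum(mask$mask) * prod(mask$spacing)
}

# --- volume IO --------------------------------------------------------------

#' Write / read a voxel volume as NIfTI
#'
#' Spacing is stored in `pixdim` and the origin in the sform translation.
#' Polarity is not representable in NIfTI; supply it when reading.
#'
#' @param volume a `voxel_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param polarity polarity to attach on read.
#' @return `path` (write) or a `voxel_volume` (read).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  M <- diag(4)
  diag(M)[1:3] <- volume$spacing
  M[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(M, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, polarity = "bone_bright") {
  img <- RNifti::readNifti(path)
  M <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = abs(diag(M)[1:3]), origin = M[1:3, 4],
               polarity = polarity)
}
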