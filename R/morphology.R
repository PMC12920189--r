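#' Label connected components of a 3D mask
#'
#' 26-connectivity by default (faces, edges and corners all connect), with a
#' minimum-size filter: components smaller than `min_voxels` are discarded.
#'
#' @param mask A `binary_mask`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels Discard components with fewer voxels than this.
#' @return A list: `labels` (integer 3D array, 0 = background, components
#'   renumbered 1..k after filtering), `sizes` (integer voxel counts, one per
#'   surviving component), `n` (component count).
#' @export
connected_components <- function(mask, connectivity = 26, min_voxels = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  lab <- cpp_label_components(as.vector(mask$values), as.integer(d),
                              as.integer(connectivity))
  if (!any(lab > 0L))
    return(list(labels = array(0L, dim = d), sizes = integer(0), n = 0L))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab2 <- integer(length(lab))
  fg <- lab > 0L
  lab2[fg] <- remap[lab[fg]]
  list(labels = array(lab2, dim = d),
       sizes = sizes[keep], n = length(keep))
}

#' Physical volume of a mask in millilitres
#'
#' `voxel count * prod(spacing) / 1000`.
#'
#' @param mask A `binary_mask` (or logical array with `spacing` given).
#' @param spacing Voxel spacing in mm, used when `mask` is a bare array.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask, spacing = NULL) {
  if (inherits(mask, "binary_mask")) {
    n <- sum(mask$values)
    sp <- mask$spacing
  } else {
    stopifnot(!is.null(spacing))
    n <- sum(mask != 0)
    sp <- spacing
  }
  n * prod(sp) / 1000
}

#' Distance transform of a mask
#'
#' For every voxel, the Euclidean distance (mm, honouring anisotropic
#' spacing) to the nearest foreground voxel. Empty mask gives `Inf`
#' everywhere.
#'
#' @param mask A `binary_mask`.
#' @return Numeric 3D array of distances in mm.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  array(cpp_edt(as.vector(mask$values), as.integer(d), mask$spacing), dim = d)
}

#' Morphological dilation / erosion with a metric ball
#'
#' Uses the Euclidean distance transform, so the structuring element is a
#' ball of the given radius in mm.
#'
#' @param mask A `binary_mask`.
#' @param radius_mm Ball radius in mm (>= 0).
#' @return A `binary_mask`.
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"), radius_mm >= 0)
  if (radius_mm == 0 || !any(mask$values)) return(mask)
  dt <- distance_transform(mask)
  out <- mask
  out$values <- dt <= radius_mm
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"), radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  inv <- mask
  inv$values <- !mask$values
  if (!any(inv$values)) return(mask)
  dt <- distance_transform(inv)
  out <- mask
  out$values <- mask$values & (dt > radius_mm)
  out
}

mask_surface <- function(mask) {
  # face-connected boundary: foreground voxels with a background 6-neighbour
  # (volume borders count as boundary)
  v <- mask$values
  d <- dim(v)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  out <- mask
  out$values <- v & !core
  out
}
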