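#' Resample a volume to isotropic spacing
#'
#' Brings a volume onto an isotropic grid (1 mm by default), the first step of
#' the preprocessing chain. The output shape is
#' `round(shape * spacing / target_mm)` per axis. Intensities use trilinear
#' interpolation (`order = 1`); masks use nearest-neighbour (`order = 0`),
#' which preserves binarity.
#'
#' @param vol A `volume_grid`, `binary_mask` or `probability_map`.
#' @param target_mm Target voxel edge length in mm (> 0). Default 1.
#' @param order Interpolation order: 1 (trilinear) or 0 (nearest-neighbour).
#'   Defaults to 0 for masks, 1 otherwise.
#' @return An object of the same class as `vol` on the new grid.
#' @export
resample_isotropic <- function(vol, target_mm = 1,
                               order = if (inherits(vol, "binary_mask")) 0L else 1L) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!is.numeric(target_mm) || length(target_mm) != 1 || target_mm <= 0)
    abort("`target_mm` must be a positive scalar",
          class = "periseg_parameter_error")
  d <- dim(vol$values)
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing / target_mm)))
  vals <- vol$values
  storage.mode(vals) <- "double"
  out <- cpp_resample(as.vector(vals), as.integer(d), vol$spacing,
                      out_dim, rep(target_mm, 3), as.integer(order))
  out <- array(out, dim = out_dim)
  sp <- rep(target_mm, 3)
  if (inherits(vol, "binary_mask")) {
    binary_mask(out != 0, sp, vol$origin)
  } else if (inherits(vol, "probability_map")) {
    probability_map(pmin(pmax(out, 0), 1), sp, vol$origin)
  } else {
    volume_grid(out, sp, vol$origin)
  }
}

#' Tightly crop a volume around its content
#'
#' Finds the minimal axis-aligned bounding box of voxels strictly above
#' `background_level` (the head region, when the background is zero) and crops
#' to it. The returned region allows masks and probability maps computed on
#' the cropped grid to be mapped back onto the original one.
#'
#' @param vol A `volume_grid`-like object.
#' @param background_level Scalar; voxels \eqn{\le} this value are background.
#' @return A list with elements `volume` (cropped, same class) and `region`
#'   (a 3x2 integer matrix of 1-based inclusive index bounds per axis).
#' @export
tight_crop <- function(vol, background_level = 0) {
  stopifnot(inherits(vol, "volume_grid"))
  fg <- vol$values > background_level
  if (!any(fg))
    abort("volume has no content above background",
          class = "periseg_empty_error")
  idx <- which(fg, arr.ind = TRUE)
  region <- t(apply(idx, 2, range))
  dimnames(region) <- list(c("x", "y", "z"), c("lo", "hi"))
  cropped <- vol$values[region[1, 1]:region[1, 2],
                        region[2, 1]:region[2, 2],
                        region[3, 1]:region[3, 2], drop = FALSE]
  origin <- vol$origin + (region[, 1] - 1) * vol$spacing
  out <- vol
  out$values <- cropped
  out$origin <- origin
  list(volume = out, region = region)
}

#' Place a cropped volume back on its original grid
#'
#' Inverse of [tight_crop()]: embeds values computed on a cropped grid into a
#' full-size array (zero-filled outside the region).
#'
#' @param vol Cropped `volume_grid`-like object.
#' @param region 3x2 bounds matrix returned by [tight_crop()].
#' @param full_dim Integer length-3: shape of the original grid.
#' @param origin Origin of the original grid.
#' @return Object of the same class as `vol` on the full grid.
#' @export
uncrop <- function(vol, region, full_dim, origin = c(0, 0, 0)) {
  stopifnot(inherits(vol, "volume_grid"))
  full <- array(if (inherits(vol, "binary_mask")) FALSE else 0, dim = full_dim)
  full[region[1, 1]:region[1, 2],
       region[2, 1]:region[2, 2],
       region[3, 1]:region[3, 2]] <- vol$values
  out <- vol
  out$values <- full
  out$origin <- as.numeric(origin)
  out
}

#' Subtract one sequence from another to form a difference channel
#'
#' Produces the `t1d` difference channel (typically `t1c - t1w`), which
#' highlights true gadolinium enhancement. Applied after resampling/cropping
#' and before clipping/normalisation; negative values are preserved.
#'
#' @param a,b `volume_grid` objects on the same grid.
#' @return A `volume_grid` with values `a - b`.
#' @export
subtract_channel <- function(a, b) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  check_same_grid(a, b, "channels")
  out <- a
  out$values <- a$values - b$values
  out
}

#' Derive the t1d channel for a sequence set
#'
#' @param seqs A `sequence_set` containing `t1c` and `t1w`.
#' @return The `sequence_set` with a `t1d` member added.
#' @export
add_t1d <- function(seqs) {
  stopifnot(inherits(seqs, "sequence_set"))
  if (!all(c("t1c", "t1w") %in% names(seqs)))
    abort("t1d requires both t1c and t1w sequences",
          class = "periseg_input_error")
  out <- unclass(seqs)
  out$t1d <- subtract_channel(seqs$t1c, seqs$t1w)
  sequence_set(out)
}

#' Percentile intensity clipping and zero-mean normalisation
#'
#' Clips intensities to the \[0th, 99.5th\] percentile of the volume (computed
#' over all voxels, including zeros, with linear-interpolation percentiles),
#' then normalises the voxels that were nonzero before clipping to zero mean
#' and — optionally — unit variance. Exactly-zero background voxels stay zero.
#'
#' @param vol A `volume_grid`.
#' @param clip_pct Length-2 percentile bounds in \[0, 100\]. Default `c(0, 99.5)`.
#' @param unit_variance Divide nonzero voxels by their standard deviation
#'   (default TRUE). A constant nonzero foreground (zero variance) is
#'   mean-subtracted only, with a warning.
#' @return A `volume_grid` with normalised values.
#' @export
clip_and_normalize <- function(vol, clip_pct = c(0, 99.5),
                               unit_variance = TRUE) {
  stopifnot(inherits(vol, "volume_grid"))
  if (length(clip_pct) != 2 || any(clip_pct < 0) || any(clip_pct > 100) ||
      clip_pct[1] >= clip_pct[2])
    abort("`clip_pct` must be increasing percentiles in [0, 100]",
          class = "periseg_parameter_error")
  v <- vol$values
  nz <- v != 0
  if (!any(nz)) return(vol)
  bounds <- stats::quantile(v, probs = clip_pct / 100, names = FALSE, type = 7)
  v <- pmin(pmax(v, bounds[1]), bounds[2])
  fg <- v[nz]
  m <- mean(fg)
  s <- stats::sd(fg)
  if (unit_variance && isTRUE(s > 0)) {
    v[nz] <- (fg - m) / s
  } else {
    if (unit_variance && length(fg) > 1)
      warning("zero variance among nonzero voxels; skipping scaling",
              call. = FALSE)
    v[nz] <- fg - m
  }
  out <- vol
  out$values <- v
  out
}

#' Preprocess a sequence set
#'
#' Runs the full preprocessing chain in order: (i) resampling to isotropic
#' spacing, (ii) tight cropping around the head (union of sequence content),
#' (iii) t1d difference-channel computation when requested and available,
#' (iv) intensity clipping, and (v) zero-mean normalisation of nonzero voxels.
#'
#' @param seqs A `sequence_set`.
#' @param target_mm Isotropic target spacing (mm).
#' @param make_t1d Add the t1d channel when t1c and t1w are present.
#' @param clip_pct Percentile clipping bounds.
#' @param crop Perform tight cropping (default TRUE).
#' @return A list: `sequences` (preprocessed `sequence_set`), `region`
#'   (crop bounds on the resampled grid), `full_dim` (resampled shape).
#' @export
preprocess_sequences <- function(seqs, target_mm = 1, make_t1d = TRUE,
                                 clip_pct = c(0, 99.5), crop = TRUE) {
  stopifnot(inherits(seqs, "sequence_set"))
  res <- lapply(unclass(seqs), resample_isotropic, target_mm = target_mm)
  full_dim <- dim(res[[1]]$values)
  region <- NULL
  if (crop) {
    content <- Reduce(`+`, lapply(res, function(v) abs(v$values)))
    probe <- res[[1]]
    probe$values <- content
    cr <- tight_crop(probe, background_level = 0)
    region <- cr$region
    res <- lapply(res, function(v) {
      v$values <- v$values[region[1, 1]:region[1, 2],
                           region[2, 1]:region[2, 2],
                           region[3, 1]:region[3, 2], drop = FALSE]
      v$origin <- v$origin + (region[, 1] - 1) * v$spacing
      v
    })
  }
  ss <- sequence_set(res)
  if (make_t1d && all(c("t1c", "t1w") %in% names(ss))) ss <- add_t1d(ss)
  out <- lapply(unclass(ss), clip_and_normalize, clip_pct = clip_pct)
  list(sequences = sequence_set(out), region = region, full_dim = full_dim)
}
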