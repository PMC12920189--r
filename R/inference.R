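#' Pluggable patch predictor contract
#'
#' Wraps any callable producing per-voxel probabilities for one structure
#' from a multi-channel image patch. This is the seam where trained networks
#' plug in; the package itself ships an oracle predictor built from phantom
#' ground truth ([make_oracle_predictor()]).
#'
#' The callable receives `patch`, a 4D array (x, y, z, channel) of the
#' declared channels, and `offset`, the 0-based voxel coordinate of the patch
#' corner in the unpadded input grid (negative inside the padding margin).
#' It must return a 3D array of the patch's spatial shape with values in
#' \[0, 1\], deterministically.
#'
#' @param fn `function(patch, offset)` as described.
#' @param channels Character vector of required input sequence labels.
#' @param patch_shape Integer length-3 patch shape (default 160^3 voxels).
#' @return A `patch_predictor`.
#' @export
patch_predictor <- function(fn, channels, patch_shape = c(160, 160, 160)) {
  stopifnot(is.function(fn), length(patch_shape) == 3, all(patch_shape >= 1))
  structure(list(fn = fn, channels = channels,
                 patch_shape = as.integer(patch_shape)),
            class = "patch_predictor")
}

#' Inference configuration
#'
#' @param patch_shape Patch shape used for sliding-window inference; defaults
#'   to the predictor's own shape when NULL.
#' @param overlap Fractional overlap between consecutive patches per axis,
#'   in \[0, 1). Default 0.5.
#' @param tta_enabled Run test-time augmentation (default FALSE: no runtime
#'   augmentation over input samples).
#' @param tta_transforms Subset of `c("flip", "rotation", "gamma")`.
#' @param ensemble_mode `"average"` (voxel-wise mean) or `"amax"`
#'   (voxel-wise maximum) for model ensembling.
#' @param seed Integer seed controlling TTA sampling.
#' @return An `inference_config`.
#' @export
inference_config <- function(patch_shape = NULL, overlap = 0.5,
                             tta_enabled = FALSE,
                             tta_transforms = c("flip", "rotation", "gamma"),
                             ensemble_mode = c("average", "amax"),
                             seed = 1L) {
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1)
    abort("`overlap` must lie in [0, 1)", class = "periseg_parameter_error")
  ensemble_mode <- match.arg(ensemble_mode)
  bad <- setdiff(tta_transforms, c("flip", "rotation", "gamma"))
  if (length(bad))
    abort(paste("unknown TTA transform(s):", paste(bad, collapse = ", ")),
          class = "periseg_parameter_error")
  structure(list(patch_shape = patch_shape, overlap = overlap,
                 tta_enabled = isTRUE(tta_enabled),
                 tta_transforms = tta_transforms,
                 ensemble_mode = ensemble_mode, seed = as.integer(seed)),
            class = "inference_config")
}

channel_stack <- function(seqs, channels) {
  missing <- setdiff(channels, names(seqs))
  if (length(missing))
    abort(paste("missing input sequence(s):", paste(missing, collapse = ", ")),
          class = "periseg_input_error")
  d <- dim(seqs[[channels[1]]]$values)
  arr <- array(0, dim = c(d, length(channels)))
  for (i in seq_along(channels)) arr[, , , i] <- seqs[[channels[i]]]$values
  arr
}

window_starts <- function(extent, patch, stride) {
  if (extent <= patch) return(0L)
  s <- seq(0L, extent - patch, by = stride)
  unique(c(s, extent - patch))
}

#' Sliding-window whole-volume prediction
#'
#' Assembles a whole-volume probability map by running the patch predictor
#' over a regular grid of patches with the configured fractional overlap
#' (50% by default, i.e. a stride of half the patch per axis). Overlapping
#' predictions are combined by unweighted arithmetic mean. Volumes smaller
#' than one patch are zero-padded symmetrically and un-padded afterwards.
#'
#' @param seqs A `sequence_set` covering the predictor's declared channels.
#' @param predictor A `patch_predictor`.
#' @param cfg An `inference_config`.
#' @return A `probability_map` on the input grid.
#' @export
sliding_window_predict <- function(seqs, predictor, cfg = inference_config()) {
  stopifnot(inherits(seqs, "sequence_set"), inherits(predictor, "patch_predictor"))
  ref <- seqs[[1]]
  arr <- channel_stack(seqs, predictor$channels)
  ps <- if (is.null(cfg$patch_shape)) predictor$patch_shape
        else as.integer(cfg$patch_shape)
  d <- dim(arr)[1:3]
  nch <- dim(arr)[4]

  pad_lo <- pmax(0L, as.integer(ceiling((ps - d) / 2)))
  pad_hi <- pmax(0L, as.integer(ps - d - pad_lo))
  pd <- d + pad_lo + pad_hi
  if (any(pad_lo > 0 | pad_hi > 0)) {
    padded <- array(0, dim = c(pd, nch))
    padded[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
           pad_lo[3] + seq_len(d[3]), ] <- arr
    arr <- padded
  }

  stride <- pmax(1L, as.integer(round(ps * (1 - cfg$overlap))))
  sx <- window_starts(pd[1], ps[1], stride[1])
  sy <- window_starts(pd[2], ps[2], stride[2])
  sz <- window_starts(pd[3], ps[3], stride[3])

  acc <- array(0, dim = pd)
  cnt <- array(0L, dim = pd)
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    ix <- x0 + seq_len(ps[1]); iy <- y0 + seq_len(ps[2]); iz <- z0 + seq_len(ps[3])
    patch <- arr[ix, iy, iz, , drop = FALSE]
    offset <- c(x0, y0, z0) - pad_lo
    pred <- predictor$fn(patch, offset)
    pred <- array(pred, dim = ps)
    if (any(pred < -1e-9) || any(pred > 1 + 1e-9))
      abort("predictor output outside [0, 1]", class = "periseg_contract_error")
    acc[ix, iy, iz] <- acc[ix, iy, iz] + pred
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  stopifnot(all(cnt > 0L))
  pm <- acc / cnt
  pm <- pm[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
           pad_lo[3] + seq_len(d[3]), drop = FALSE]
  probability_map(pmin(pmax(pm, 0), 1), ref$spacing, ref$origin)
}

flip_seqs <- function(seqs, axis) {
  out <- lapply(unclass(seqs), function(v) {
    v$values <- flip_array(v$values, axis)
    v
  })
  sequence_set(out)
}

flip_array <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

rot90_xy <- function(a, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(a)
  for (i in seq_len(k)) {
    perm <- if (length(dim(a)) == 3) c(2, 1, 3) else c(2, 1, 3, 4)
    a <- aperm(a, perm)
    a <- flip_array(a, 1)
  }
  a
}

rot_seqs <- function(seqs, k) {
  out <- lapply(unclass(seqs), function(v) {
    v$values <- rot90_xy(v$values, k)
    v$spacing <- v$spacing[c(2, 1, 3)]
    v
  })
  sequence_set(out)
}

gamma_seqs <- function(seqs, gamma) {
  out <- lapply(unclass(seqs), function(v) {
    x <- v$values
    rng <- range(x)
    if (diff(rng) > 0) {
      u <- (x - rng[1]) / diff(rng)
      v$values <- rng[1] + diff(rng) * u^gamma
    }
    v
  })
  sequence_set(out)
}

#' Test-time-augmented prediction
#'
#' Runs one sliding-window pass on the identity input plus one pass per
#' enabled transform (axis flip, axial 90-degree rotation, gamma contrast),
#' inverts the geometric transforms on the predicted maps, and averages.
#' Transform parameters are sampled reproducibly from the config seed.
#'
#' @inheritParams sliding_window_predict
#' @return A `probability_map`.
#' @export
tta_predict <- function(seqs, predictor, cfg) {
  stopifnot(inherits(cfg, "inference_config"))
  if (!cfg$tta_enabled)
    abort("tta_predict called with tta_enabled = FALSE",
          class = "periseg_parameter_error")
  rng <- local({
    set.seed(cfg$seed)
    list(flip_axis = sample(1:3, 1),
         rot_k = sample(1:3, 1),
         gamma = stats::runif(1, 0.7, 1.5))
  })
  maps <- list(sliding_window_predict(seqs, predictor, cfg))
  for (tr in cfg$tta_transforms) {
    if (tr == "flip") {
      pm <- sliding_window_predict(flip_seqs(seqs, rng$flip_axis), predictor, cfg)
      pm$values <- flip_array(pm$values, rng$flip_axis)
    } else if (tr == "rotation") {
      pm <- sliding_window_predict(rot_seqs(seqs, rng$rot_k), predictor, cfg)
      pm$values <- rot90_xy(pm$values, -rng$rot_k)
      pm$spacing <- seqs[[1]]$spacing
    } else if (tr == "gamma") {
      pm <- sliding_window_predict(gamma_seqs(seqs, rng$gamma), predictor, cfg)
    }
    pm$origin <- seqs[[1]]$origin
    maps <- c(maps, list(pm))
  }
  ensemble_probability(maps, mode = "average")
}

#' Ensemble probability maps
#'
#' Combines one to five probability maps voxel-wise: `"average"` takes the
#' mean probability, `"amax"` the maximum.
#'
#' @param maps List of `probability_map` objects on one grid.
#' @param mode `"average"` or `"amax"`.
#' @return A `probability_map`.
#' @export
ensemble_probability <- function(maps, mode = c("average", "amax")) {
  mode <- match.arg(mode)
  if (!is.list(maps) || length(maps) < 1 || length(maps) > 5)
    abort("`maps` must hold 1 to 5 probability maps",
          class = "periseg_parameter_error")
  for (m in maps) stopifnot(inherits(m, "probability_map"))
  if (length(maps) > 1)
    for (m in maps[-1]) check_same_grid(maps[[1]], m, "probability maps")
  out <- maps[[1]]
  if (length(maps) == 1) return(out)
  vals <- lapply(maps, `[[`, "values")
  out$values <- if (mode == "average") Reduce(`+`, vals) / length(vals)
                else Reduce(pmax, vals)
  out
}

#' Two-step probability-map postprocessing
#'
#' Step 1: probabilities outside the brain mask are set to zero. Step 2: the
#' map is binarised at `bin_threshold`; connected components (26-connectivity)
#' whose physical volume falls below the policy's minimum (0.05 ml by
#' default) or which do not appear on at least two consecutive axial slices
#' have their probabilities zeroed. Surviving probabilities are unchanged,
#' so the operation is idempotent.
#'
#' @param pm A `probability_map`.
#' @param brain A `binary_mask` of the brain on the same grid.
#' @param policy A `threshold_policy`.
#' @param bin_threshold Binarisation threshold in (0, 1].
#' @return A cleaned `probability_map`.
#' @export
postprocess_probability <- function(pm, brain, policy = threshold_policy(),
                                    bin_threshold = 0.5) {
  stopifnot(inherits(pm, "probability_map"), inherits(brain, "binary_mask"))
  check_same_grid(pm, brain, "probability map and brain mask")
  if (!is.numeric(bin_threshold) || bin_threshold <= 0 || bin_threshold > 1)
    abort("`bin_threshold` must lie in (0, 1]",
          class = "periseg_parameter_error")
  v <- pm$values
  v[!brain$values] <- 0

  bin <- binary_mask(v >= bin_threshold, pm$spacing, pm$origin)
  cc <- connected_components(bin, connectivity = 26)
  if (cc$n > 0) {
    voxel_ml <- prod(pm$spacing) / 1000
    for (i in seq_len(cc$n)) {
      comp <- cc$labels == i
      vol_ml <- sum(comp) * voxel_ml
      nslices <- sum(apply(comp, 3, any))
      if (vol_ml < policy$postprocess_min_volume_ml || nslices < 2)
        v[comp] <- 0
    }
  }
  out <- pm
  out$values <- v
  out
}
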