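#' @useDynLib periseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort
#' @importFrom tibble tibble as_tibble
NULL

STRUCTURE_LABELS <- c("TC", "NETC", "SNFH", "ET", "CAVITY", "WT", "BRAIN")
SEQUENCE_LABELS <- c("t1c", "t1w", "flair", "t2w", "t1d")

new_grid_obj <- function(values, spacing, origin, class) {
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = c(class, "volume_grid")
  )
}

#' 3D scalar volume on a physical grid
#'
#' The elementary imaging container: a 3D array of intensities together with
#' per-axis voxel spacing (mm) and the physical coordinate of voxel (1,1,1).
#' The third array axis is the axial direction by convention.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, physical position of the first voxel (mm).
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    abort("`values` must be a 3D array", class = "periseg_format_error")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 positive finite numbers",
          class = "periseg_format_error")
  if (any(!is.finite(values)))
    abort("`values` must be finite", class = "periseg_format_error")
  storage.mode(values) <- "double"
  new_grid_obj(values, spacing, origin, character(0))
}

#' Binary structure mask on a physical grid
#'
#' @param values 3D array coercible to logical (values in \{0, 1\}).
#' @inheritParams volume_grid
#' @return A `binary_mask` object (subclass of `volume_grid`).
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    abort("`values` must be a 3D array", class = "periseg_format_error")
  if (is.numeric(values) && !all(values %in% c(0, 1)))
    abort("mask values must be 0/1", class = "periseg_format_error")
  v <- array(as.logical(values), dim = dim(values))
  if (any(is.na(v)))
    abort("mask values must be 0/1", class = "periseg_format_error")
  new_grid_obj(v, spacing, origin, "binary_mask")
}

#' Voxel-wise probability map on a physical grid
#'
#' @param values 3D numeric array with entries in \[0, 1\].
#' @inheritParams volume_grid
#' @return A `probability_map` object (subclass of `volume_grid`).
#' @export
probability_map <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    abort("`values` must be a 3D array", class = "periseg_format_error")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    abort("probabilities must lie in [0, 1]", class = "periseg_format_error")
  storage.mode(values) <- "double"
  new_grid_obj(values, spacing, origin, "probability_map")
}

#' @export
print.volume_grid <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s> %s voxels @ %s mm\n", kind,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

grid_compatible <- function(a, b, tol = 1e-4) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!grid_compatible(a, b))
    abort(paste0(what, " are not on the same grid"),
          class = "periseg_alignment_error")
  invisible(TRUE)
}

#' Named set of co-registered MR sequences
#'
#' Holds one `volume_grid` per MR sequence label. Valid labels are
#' `t1c`, `t1w`, `flair`, `t2w` and the derived difference channel `t1d`
#' (which requires both `t1c` and `t1w` to be present).
#'
#' @param ... Named `volume_grid` objects, or a single named list.
#' @return A `sequence_set`.
#' @export
sequence_set <- function(...) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) &&
      !inherits(vols[[1]], "volume_grid")) vols <- vols[[1]]
  nms <- names(vols)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    abort("sequences must be uniquely named", class = "periseg_input_error")
  bad <- setdiff(nms, SEQUENCE_LABELS)
  if (length(bad))
    abort(paste("unknown sequence label(s):", paste(bad, collapse = ", ")),
          class = "periseg_input_error")
  if ("t1d" %in% nms && !all(c("t1c", "t1w") %in% nms))
    abort("t1d requires both t1c and t1w", class = "periseg_input_error")
  for (v in vols) stopifnot(inherits(v, "volume_grid"))
  if (length(vols) > 1)
    for (v in vols[-1]) check_same_grid(vols[[1]], v, "sequences")
  structure(vols, class = "sequence_set")
}

#' Named set of binary structure masks for one timepoint
#'
#' Valid labels: `TC` (tumor core), `NETC` (non-enhancing tumor core),
#' `SNFH` (surrounding non-enhancing FLAIR hyperintensity), `ET`
#' (postoperative enhancing residual tissue), `CAVITY` (resection cavity),
#' `WT` (whole tumor) and `BRAIN`.
#'
#' @param ... Named `binary_mask` objects, or a single named list.
#' @return A `structure_set`.
#' @export
structure_set <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) &&
      !inherits(masks[[1]], "volume_grid")) masks <- masks[[1]]
  nms <- names(masks)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    abort("structures must be uniquely named", class = "periseg_input_error")
  bad <- setdiff(nms, STRUCTURE_LABELS)
  if (length(bad))
    abort(paste("unknown structure label(s):", paste(bad, collapse = ", ")),
          class = "periseg_input_error")
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  if (length(masks) > 1)
    for (m in masks[-1]) check_same_grid(masks[[1]], m, "structures")
  structure(masks, class = "structure_set")
}

#' Perioperative patient study
#'
#' Bundles preoperative and/or postoperative timepoints, each a pair of a
#' `sequence_set` and a `structure_set`, plus the contrast-enhancement flag
#' that steers refinement and reporting.
#'
#' @param patient_id Character scalar.
#' @param preoperative,postoperative Lists with elements `sequences`
#'   (a `sequence_set` or NULL) and `structures` (a `structure_set`), or NULL.
#' @param contrast_enhancing Logical; is the tumor contrast-enhancing?
#' @return A `patient_study`.
#' @export
patient_study <- function(patient_id, preoperative = NULL,
                          postoperative = NULL, contrast_enhancing = TRUE) {
  if (is.null(preoperative) && is.null(postoperative))
    abort("at least one timepoint is required", class = "periseg_input_error")
  tp <- list()
  for (nm in c("preoperative", "postoperative")) {
    x <- get(nm)
    if (is.null(x)) next
    stopifnot(is.list(x), "structures" %in% names(x))
    tp[[nm]] <- x
  }
  structure(list(patient_id = as.character(patient_id), timepoints = tp,
                 contrast_enhancing = isTRUE(contrast_enhancing)),
            class = "patient_study")
}

#' Operating thresholds for detection, postprocessing and reporting
#'
#' Central policy object holding every cut-off the pipeline applies:
#' per-structure positivity cut-off volumes (ml) deciding whether a structure
#' counts as present in a scan, the minimum component volume kept by
#' probability postprocessing, per-structure minimum component sizes (voxels)
#' for object-wise evaluation, the patient-wise true-positive Dice threshold
#' (percent), and the residual-volume bounds of the surgical-outcome
#' categories.
#'
#' @param positivity_cutoff_ml Named numeric: minimum structure volume (ml)
#'   for a sample to count as positive. Defaults: ET 0.175, NETC 0.05,
#'   CAVITY 0.1, TC 0.1.
#' @param postprocess_min_volume_ml Minimum connected-component volume (ml)
#'   surviving probability-map postprocessing. Default 0.05.
#' @param objectwise_min_voxels Named numeric: minimum component size in
#'   voxels for object-wise metrics (default 75; NETC 50).
#' @param patientwise_tp_dice_pct Dice overlap (percent) that a positive
#'   prediction must exceed against the ground truth to count as a
#'   true positive. Default 0.1.
#' @param complete_max_ml Residual volume (ml) strictly below which a
#'   resection is "complete". Default 0.175 (the ET detectability cut-off).
#' @param near_total_max_ml Residual volume (ml) up to which a resection is
#'   "near total". Default 1.0.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(positivity_cutoff_ml = c(ET = 0.175, NETC = 0.05,
                                                      CAVITY = 0.1, TC = 0.1),
                             postprocess_min_volume_ml = 0.05,
                             objectwise_min_voxels = c(default = 75, NETC = 50),
                             patientwise_tp_dice_pct = 0.1,
                             complete_max_ml = 0.175,
                             near_total_max_ml = 1.0) {
  vals <- c(positivity_cutoff_ml, postprocess_min_volume_ml,
            objectwise_min_voxels, patientwise_tp_dice_pct,
            complete_max_ml, near_total_max_ml)
  if (any(vals < 0)) abort("policy values must be >= 0",
                           class = "periseg_parameter_error")
  if (complete_max_ml > near_total_max_ml)
    abort("complete_max_ml must not exceed near_total_max_ml",
          class = "periseg_parameter_error")
  structure(list(positivity_cutoff_ml = positivity_cutoff_ml,
                 postprocess_min_volume_ml = postprocess_min_volume_ml,
                 objectwise_min_voxels = objectwise_min_voxels,
                 patientwise_tp_dice_pct = patientwise_tp_dice_pct,
                 complete_max_ml = complete_max_ml,
                 near_total_max_ml = near_total_max_ml),
            class = "threshold_policy")
}

positivity_cutoff <- function(policy, structure) {
  cut <- policy$positivity_cutoff_ml
  if (!structure %in% names(cut))
    abort(paste("no positivity cut-off for structure", structure),
          class = "periseg_parameter_error")
  unname(cut[[structure]])
}

min_component_voxels <- function(policy, structure) {
  mv <- policy$objectwise_min_voxels
  if (structure %in% names(mv)) return(unname(mv[[structure]]))
  unname(mv[["default"]])
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as One of "volume", "mask", "probability" — the container to build.
#' @return A `volume_grid`, `binary_mask` or `probability_map`.
#' @export
read_volume <- function(path, as = c("volume", "mask", "probability")) {
  as <- match.arg(as)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(paste("cannot read", path),
                                            class = "periseg_format_error"))
  d <- dim(img)
  if (length(d) != 3L)
    abort(sprintf("expected a 3D image, got %d dimensions", length(d)),
          class = "periseg_format_error")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(sp <= 0))
    abort("non-positive voxel spacing in header", class = "periseg_format_error")
  orig <- tryCatch(as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img)),
                   error = function(e) c(0, 0, 0))
  vals <- array(as.numeric(img), dim = d)
  switch(as,
         volume = volume_grid(vals, sp, orig),
         mask = binary_mask(vals != 0, sp, orig),
         probability = probability_map(vals, sp, orig))
}

#' Write a volume, mask or probability map to NIfTI
#'
#' Masks are written as unsigned 8-bit, probability maps as float32.
#'
#' @param x A `volume_grid`, `binary_mask` or `probability_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "volume_grid"))
  vals <- x$values
  dt <- "float"
  if (inherits(x, "binary_mask")) {
    vals <- array(as.integer(vals), dim = dim(vals))
    dt <- "uint8"
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
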