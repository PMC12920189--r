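#' Phantom generation parameters
#'
#' Geometry, intensity and noise settings of the perioperative phantom
#' generator. Structures are spheres/ellipsoids with controllable volumes:
#' preoperatively an enhancing tumor core with a necrotic interior and a
#' surrounding FLAIR-hyperintense halo; postoperatively a resection cavity
#' with fragmented rim residual tissue and a shrunken halo.
#'
#' @param grid_shape Integer length-3 voxel grid (default 96^3).
#' @param spacing_mm Isotropic voxel spacing (default 1 mm).
#' @param brain_axes_mm Brain ellipsoid semi-axes in mm.
#' @param tc_volume_ml Length-2 range of preoperative tumor-core volume (ml).
#' @param necrosis_fraction Fraction of the tumor core that is necrotic
#'   (NETC); 0 gives a fully enhancing core.
#' @param snfh_margin_mm Halo thickness around the tumor core (mm).
#' @param cavity_volume_ml Range of postoperative cavity volume (ml).
#' @param fragment_count Integer range of residual (ET) fragments.
#' @param fragment_volume_ml Range of per-fragment volume (ml); may straddle
#'   the 0.175 ml detectability cut-off by design.
#' @param intensity_means Named list per sequence of tissue means
#'   (brain, rim, netc, snfh, cavity).
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(96, 96, 96), spacing_mm = 1,
                           brain_axes_mm = c(40, 44, 36),
                           tc_volume_ml = c(20, 40),
                           necrosis_fraction = 0.3,
                           snfh_margin_mm = 8,
                           cavity_volume_ml = c(12, 28),
                           fragment_count = c(1, 3),
                           fragment_volume_ml = c(0.05, 0.8),
                           intensity_means = list(
                             t1c = c(brain = 600, rim = 1000, netc = 350,
                                     snfh = 550, cavity = 150),
                             t1w = c(brain = 600, rim = 650, netc = 400,
                                     snfh = 550, cavity = 150),
                             flair = c(brain = 400, rim = 500, netc = 450,
                                       snfh = 800, cavity = 100),
                             t2w = c(brain = 500, rim = 550, netc = 700,
                                     snfh = 750, cavity = 900)),
                           noise_sd = 15) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8), spacing_mm > 0,
            necrosis_fraction >= 0, necrosis_fraction < 1,
            all(tc_volume_ml >= 0), all(cavity_volume_ml >= 0),
            all(fragment_volume_ml >= 0), noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 brain_axes_mm = brain_axes_mm, tc_volume_ml = tc_volume_ml,
                 necrosis_fraction = necrosis_fraction,
                 snfh_margin_mm = snfh_margin_mm,
                 cavity_volume_ml = cavity_volume_ml,
                 fragment_count = as.integer(fragment_count),
                 fragment_volume_ml = fragment_volume_ml,
                 intensity_means = intensity_means, noise_sd = noise_sd),
            class = "phantom_params")
}

squared_distance_field <- function(grid_shape, spacing, center_vox) {
  ax <- ((seq_len(grid_shape[1]) - center_vox[1]) * spacing[1])^2
  ay <- ((seq_len(grid_shape[2]) - center_vox[2]) * spacing[2])^2
  az <- ((seq_len(grid_shape[3]) - center_vox[3]) * spacing[3])^2
  outer(outer(ax, ay, `+`), az, `+`)
}

#' Single-component mask of an exact target volume
#'
#' Builds a quasi-spherical 26-connected mask with exactly
#' `round(volume_ml * 1000 / voxel_volume)` voxels by taking the voxels
#' nearest to the centre (ties broken by array order), so the realized
#' volume equals the request to within half a voxel.
#'
#' @param volume_ml Target volume in ml.
#' @param grid_shape Integer length-3 grid.
#' @param spacing Voxel spacing (mm), isotropic or per-axis.
#' @param center Voxel coordinate of the centre (defaults to the grid
#'   centre).
#' @return A `binary_mask`.
#' @export
synth_component_mask <- function(volume_ml, grid_shape = c(64, 64, 64),
                                 spacing = c(1, 1, 1),
                                 center = (grid_shape + 1) / 2) {
  spacing <- rep(spacing, length.out = 3)
  k <- round(volume_ml * 1000 / prod(spacing))
  v <- array(FALSE, dim = grid_shape)
  if (k > 0) {
    d2 <- squared_distance_field(grid_shape, spacing, center)
    ord <- order(as.vector(d2))[seq_len(min(k, length(d2)))]
    v[ord] <- TRUE
  }
  binary_mask(v, spacing)
}

ellipsoid_mask <- function(grid_shape, spacing, center_vox, semi_axes_mm) {
  ax <- ((seq_len(grid_shape[1]) - center_vox[1]) * spacing[1] / semi_axes_mm[1])^2
  ay <- ((seq_len(grid_shape[2]) - center_vox[2]) * spacing[2] / semi_axes_mm[2])^2
  az <- ((seq_len(grid_shape[3]) - center_vox[3]) * spacing[3] / semi_axes_mm[3])^2
  binary_mask(outer(outer(ax, ay, `+`), az, `+`) <= 1, spacing)
}

exact_sphere <- function(volume_ml, grid_shape, spacing, center) {
  synth_component_mask(volume_ml, grid_shape, spacing, center)
}

render_sequences <- function(structs, means, noise_sd, spacing, postop) {
  brain <- structs$BRAIN$values
  out <- list()
  for (seqname in names(means)) {
    mu <- means[[seqname]]
    v <- array(0, dim = dim(brain))
    v[brain] <- mu[["brain"]]
    if (!postop) {
      rim <- structs$TC$values & !structs$NETC$values
      v[structs$SNFH$values] <- mu[["snfh"]]
      v[rim] <- mu[["rim"]]
      v[structs$NETC$values] <- mu[["netc"]]
    } else {
      v[structs$SNFH$values] <- mu[["snfh"]]
      v[structs$CAVITY$values] <- mu[["cavity"]]
      v[structs$ET$values] <- mu[["rim"]]
    }
    if (noise_sd > 0) {
      n_in <- sum(brain)
      v[brain] <- pmax(v[brain] + stats::rnorm(n_in, 0, noise_sd), 1)
    }
    out[[seqname]] <- volume_grid(v, spacing)
  }
  sequence_set(out)
}

#' Generate one synthetic perioperative patient
#'
#' Builds a two-timepoint study on an isotropic grid: preoperatively a
#' spherical tumor core (enhancing rim around a necrotic NETC interior)
#' surrounded by an SNFH halo inside an ellipsoidal brain; postoperatively a
#' CSF-like resection cavity in place of the core, residual enhancing
#' fragments along the cavity margin, and a shrunken halo. Ground-truth
#' masks satisfy the refinement invariants by construction. Sequences are
#' piecewise-constant intensities plus Gaussian noise; the background
#' outside the brain is exactly zero. Fully reproducible per seed.
#'
#' @param params A `phantom_params`.
#' @param patient_id Identifier string.
#' @param seed Integer seed.
#' @param negative Generate a postoperative timepoint without residual
#'   tumor (ET absent/empty).
#' @param timepoints Which timepoints to generate.
#' @return A `patient_study`.
#' @export
generate_patient <- function(params = phantom_params(), patient_id = "p001",
                             seed = 1L, negative = FALSE,
                             timepoints = c("preoperative", "postoperative")) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(seed)
  gs <- params$grid_shape
  sp <- rep(params$spacing_mm, 3)
  center <- (gs + 1) / 2
  brain <- ellipsoid_mask(gs, sp, center, params$brain_axes_mm)
  brain_ml <- mask_volume_ml(brain)

  tc_ml <- stats::runif(1, params$tc_volume_ml[1], params$tc_volume_ml[2])
  if (tc_ml >= brain_ml)
    abort("requested tumor volume exceeds the brain volume",
          class = "periseg_parameter_error")
  tc_r <- (3 * tc_ml * 1000 / (4 * pi))^(1 / 3)
  max_off <- pmax(0, (params$brain_axes_mm - tc_r - params$snfh_margin_mm) / 2)
  tumor_center <- center + stats::runif(3, -1, 1) * max_off / sp

  tc <- exact_sphere(tc_ml, gs, sp, tumor_center)
  netc <- exact_sphere(tc_ml * params$necrosis_fraction, gs, sp, tumor_center)
  d2 <- squared_distance_field(gs, sp, tumor_center)
  halo <- binary_mask(d2 <= (tc_r + params$snfh_margin_mm)^2 & !tc$values, sp)
  halo$values <- halo$values & brain$values
  tc$values <- tc$values & brain$values
  netc$values <- netc$values & tc$values

  study <- list()
  if ("preoperative" %in% timepoints) {
    pre_structs <- structure_set(list(TC = tc, NETC = netc, SNFH = halo,
                                      BRAIN = brain))
    pre_seqs <- render_sequences(pre_structs, params$intensity_means,
                                 params$noise_sd, sp, postop = FALSE)
    study$preoperative <- list(sequences = pre_seqs, structures = pre_structs)
  }

  if ("postoperative" %in% timepoints) {
    cav_ml <- min(stats::runif(1, params$cavity_volume_ml[1],
                               params$cavity_volume_ml[2]), 0.95 * tc_ml)
    cavity <- exact_sphere(cav_ml, gs, sp, tumor_center)
    cavity$values <- cavity$values & brain$values
    cav_r <- (3 * cav_ml * 1000 / (4 * pi))^(1 / 3)

    et <- binary_mask(array(FALSE, dim = gs), sp)
    if (!negative) {
      nfrag <- sample(seq(params$fragment_count[1], params$fragment_count[2]), 1)
      for (i in seq_len(nfrag)) {
        frag_ml <- stats::runif(1, params$fragment_volume_ml[1],
                                params$fragment_volume_ml[2])
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        frag_r <- (3 * frag_ml * 1000 / (4 * pi))^(1 / 3)
        fc <- tumor_center + dir * (cav_r + frag_r) / sp
        fc <- pmin(pmax(fc, 2), gs - 1)
        frag <- exact_sphere(frag_ml, gs, sp, fc)
        et$values <- et$values | frag$values
      }
      et$values <- et$values & !cavity$values & brain$values
    }

    post_halo <- binary_mask(
      d2 <= (cav_r + 0.6 * params$snfh_margin_mm)^2, sp)
    post_halo$values <- post_halo$values & brain$values &
      !cavity$values & !et$values
    post_structs <- structure_set(list(ET = et, CAVITY = cavity,
                                       SNFH = post_halo, BRAIN = brain))
    post_seqs <- render_sequences(post_structs, params$intensity_means,
                                  params$noise_sd, sp, postop = TRUE)
    study$postoperative <- list(sequences = post_seqs,
                                structures = post_structs)
  }

  patient_study(patient_id,
                preoperative = study$preoperative,
                postoperative = study$postoperative,
                contrast_enhancing = TRUE)
}

#' Controlled corruption of a ground-truth mask
#'
#' Test harness for the evaluation framework: applies morphological and
#' topological corruption whose magnitude scales with `severity` (0 = exact
#' identity). Available operations: metric-ball `dilate`/`erode` (radius up
#' to 3 mm), `translate` (shift up to 4 voxels), `drop_component` (each
#' component dropped with probability `severity`) and `add_false_component`
#' (spurious blob with probability `severity`). Deterministic per seed.
#'
#' @param gt A `binary_mask`.
#' @param severity Corruption severity in \[0, 1\].
#' @param operations Subset of the operations above.
#' @param seed Integer seed.
#' @return A corrupted `binary_mask`.
#' @export
perturb_mask <- function(gt, severity,
                         operations = c("dilate", "translate"),
                         seed = 1L) {
  stopifnot(inherits(gt, "binary_mask"), severity >= 0, severity <= 1)
  valid <- c("dilate", "erode", "translate", "drop_component",
             "add_false_component")
  bad <- setdiff(operations, valid)
  if (length(bad))
    abort(paste("unknown operation(s):", paste(bad, collapse = ", ")),
          class = "periseg_parameter_error")
  if (severity == 0) return(gt)
  set.seed(seed)
  out <- gt
  for (op in operations) {
    if (op == "dilate") {
      out <- dilate_mask(out, severity * 3)
    } else if (op == "erode") {
      out <- erode_mask(out, severity * 3)
    } else if (op == "translate") {
      shift <- round(severity * 4 * sample(c(-1, 1), 3, replace = TRUE) *
                       stats::runif(3, 0.5, 1))
      out$values <- shift_array(out$values, shift)
    } else if (op == "drop_component") {
      cc <- connected_components(out)
      if (cc$n > 0) {
        drop <- which(stats::runif(cc$n) < severity)
        if (length(drop) == cc$n && cc$n > 1) drop <- drop[-1]
        for (i in drop) out$values[cc$labels == i] <- FALSE
      }
    } else if (op == "add_false_component") {
      if (stats::runif(1) < severity) {
        gs <- dim(out$values)
        fc <- stats::runif(3, 0.2, 0.8) * gs
        blob <- exact_sphere(0.1 + severity * 0.5, gs, out$spacing, fc)
        out$values <- out$values | blob$values
      }
    }
  }
  out
}

shift_array <- function(a, shift) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) {
      src[[ax]] <- seq_len(d[ax] - s)
      dst[[ax]] <- seq_len(d[ax] - s) + s
    } else {
      src[[ax]] <- seq_len(d[ax] + s) - s
      dst[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

gaussian_blur3 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(a)
  conv_axis <- function(x, axis) {
    n <- d[axis]
    band <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1, pmin(n, i + seq(-r, r)))
      for (t in seq_along(j)) band[i, j[t]] <- band[i, j[t]] + k[t]
    }
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- band %*% matrix(xp, dp[1], dp[2] * dp[3])
    aperm(array(m, dp), order(perm))
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  a
}

#' Oracle patch predictor built from ground truth
#'
#' Returns a `patch_predictor` whose output is the indicator of a chosen
#' structure (optionally Gaussian-blurred and corrupted by clamped Gaussian
#' noise), restricted to each requested patch. With `blur = noise = 0` the
#' assembled sliding-window map thresholded at 0.5 reproduces the structure
#' mask exactly. The probability field is precomputed once, so predictions
#' are deterministic.
#'
#' @param structures A `structure_set` on the inference grid.
#' @param structure Which structure the predictor segments.
#' @param blur Gaussian blur sigma in voxels (0 = none).
#' @param noise Gaussian noise sd on the probability scale (0 = none).
#' @param seed Integer seed for the noise field.
#' @param patch_shape Declared patch shape (default 64^3: phantom-scale).
#' @param channels Declared input channels.
#' @return A `patch_predictor`.
#' @export
make_oracle_predictor <- function(structures, structure = "ET", blur = 0,
                                  noise = 0, seed = 1L,
                                  patch_shape = c(64, 64, 64),
                                  channels = c("t1c", "t1w")) {
  stopifnot(inherits(structures, "structure_set"))
  if (!structure %in% names(structures))
    abort(paste("structure", structure, "not present"),
          class = "periseg_parameter_error")
  field <- array(as.numeric(structures[[structure]]$values),
                 dim = dim(structures[[structure]]$values))
  if (blur > 0) field <- gaussian_blur3(field, blur)
  if (noise > 0) {
    set.seed(seed)
    field <- field + array(stats::rnorm(length(field), 0, noise),
                           dim = dim(field))
  }
  field <- pmin(pmax(field, 0), 1)
  fd <- dim(field)
  fn <- function(patch, offset) {
    ps <- dim(patch)[1:3]
    out <- array(0, dim = ps)
    lo <- pmax(offset + 1L, 1L)           # 1-based source start
    hi <- pmin(offset + ps, fd)
    if (all(lo <= hi)) {
      dst_lo <- lo - offset
      dst_hi <- hi - offset
      out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
        field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    }
    out
  }
  patch_predictor(fn, channels = channels, patch_shape = patch_shape)
}

#' Generate a synthetic cohort with cross-validation folds
#'
#' Patients are assigned whole to folds (no patient straddles folds); fold
#' sizes differ by at most one. A configurable fraction of patients is
#' negative: their postoperative timepoint has no residual tumor.
#'
#' @param n_patients Number of patients (>= `fold_count`).
#' @param params A `phantom_params`.
#' @param fold_count Number of folds (default 5).
#' @param negative_fraction Fraction of negative patients; exactly
#'   `round(negative_fraction * n_patients)` are negative.
#' @param seed Integer seed.
#' @return Tibble: `patient_id`, `fold`, `negative`, `study` (list column of
#'   `patient_study`).
#' @export
generate_cohort <- function(n_patients, params = phantom_params(),
                            fold_count = 5, negative_fraction = 0.2,
                            seed = 1L) {
  if (n_patients < fold_count)
    abort("need at least one patient per fold",
          class = "periseg_parameter_error")
  set.seed(seed)
  n_neg <- round(negative_fraction * n_patients)
  neg <- rep(FALSE, n_patients)
  if (n_neg > 0) neg[sample(n_patients, n_neg)] <- TRUE
  folds <- sample(rep(seq_len(fold_count), length.out = n_patients))
  seeds <- sample.int(.Machine$integer.max, n_patients)
  studies <- lapply(seq_len(n_patients), function(i)
    generate_patient(params, patient_id = sprintf("p%03d", i),
                     seed = seeds[i], negative = neg[i]))
  tibble::tibble(patient_id = sprintf("p%03d", seq_len(n_patients)),
                 fold = folds, negative = neg, study = studies)
}
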