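test_that("NIfTI round-trip preserves values, spacing and mask binarity", {
  set.seed(11)
  m <- binary_mask(array(runif(1000) < 0.3, dim = c(10, 10, 10)),
                   spacing = c(1, 1, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(m, path)
  back <- read_volume(path, as = "mask")
  expect_identical(back$values, m$values)
  expect_equal(back$spacing, m$spacing, tolerance = 1e-4)

  v <- volume_grid(array(rnorm(8 * 9 * 10), dim = c(8, 9, 10)),
                   spacing = c(0.5, 1, 2))
  path2 <- tempfile(fileext = ".nii.gz")
  write_volume(v, path2)
  back2 <- read_volume(path2)
  expect_equal(back2$values, v$values, tolerance = 1e-6)
  expect_equal(back2$spacing, v$spacing, tolerance = 1e-4)
})

test_that("phantom volume written at 1 mm reports an isotropic header", {
  st <- generate_patient(small_params(), seed = 5,
                         timepoints = "preoperative")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(st$timepoints$preoperative$sequences$t1c, path)
  # independent reader: oro.nifti, not the RNifti path used by the package
  hdr <- oro.nifti::readNIfTI(path)
  expect_equal(unname(oro.nifti::pixdim(hdr)[2:4]), c(1, 1, 1))
})

test_that("reading a non-3D image is a format error", {
  arr4 <- array(0, dim = c(4, 4, 4, 2))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), path)
  expect_error(read_volume(path), class = "periseg_format_error")
  suppressWarnings(
    expect_error(read_volume(tempfile(fileext = ".nii")),
                 class = "periseg_format_error"))
})

test_that("container invariants are enforced", {
  expect_error(volume_grid(array(0, c(3, 3, 3)), spacing = c(1, -1, 1)),
               class = "periseg_format_error")
  expect_error(binary_mask(array(2, c(3, 3, 3))),
               class = "periseg_format_error")
  expect_error(probability_map(array(1.2, c(3, 3, 3))),
               class = "periseg_format_error")
  expect_error(sequence_set(t1d = volume_grid(array(0, c(3, 3, 3)))),
               class = "periseg_input_error")
})

test_that("resampling halves/doubles shapes per the spacing ratio", {
  v <- volume_grid(array(rnorm(50^3), dim = c(50, 50, 50)),
                   spacing = c(2, 2, 2))
  out <- resample_isotropic(v, target_mm = 1)
  expect_equal(dim(out$values), c(100, 100, 100))
  expect_equal(out$spacing, c(1, 1, 1))

  same <- resample_isotropic(out, target_mm = 1)
  expect_equal(same$values, out$values)
  expect_error(resample_isotropic(v, target_mm = 0),
               class = "periseg_parameter_error")
})

test_that("trilinear resampling reproduces a linear ramp analytically", {
  # f(x_phys) = 3 + 2 * x_phys sampled at 2 mm; centre-aligned resampling to
  # 1 mm must reproduce the ramp exactly away from the clamped borders
  nx <- 20
  xphys <- ((seq_len(nx)) - 0.5) * 2
  ramp <- array(rep(3 + 2 * xphys, times = 6 * 6), dim = c(nx, 6, 6))
  v <- volume_grid(ramp, spacing = c(2, 2, 2))
  out <- resample_isotropic(v, target_mm = 1)
  xout <- ((seq_len(dim(out$values)[1])) - 0.5) * 1
  interior <- xout > 1 & xout < max(xphys)
  expect_lt(max(abs(out$values[interior, 3, 3] - (3 + 2 * xout[interior]))),
            1e-6)
})

test_that("mask resampling stays binary and roughly volume-preserving", {
  m <- cube_mask(c(40, 40, 40), c(10, 10, 10), c(20, 20, 20),
                 spacing = c(2, 2, 2))
  out <- resample_isotropic(m, target_mm = 1)
  expect_s3_class(out, "binary_mask")
  expect_true(is.logical(out$values))
  round_trip <- resample_isotropic(out, target_mm = 2)
  expect_lt(abs(mask_volume_ml(round_trip) - mask_volume_ml(m)) /
              mask_volume_ml(m), 0.02)
})

test_that("tight_crop finds the exact bounding box", {
  v <- array(0, dim = c(40, 40, 40))
  v[6:25, 6:25, 6:25] <- 1
  cr <- tight_crop(volume_grid(v))
  expect_equal(unname(cr$region),
               matrix(c(6, 25, 6, 25, 6, 25), nrow = 3, byrow = TRUE))
  expect_equal(dim(cr$volume$values), c(20, 20, 20))

  full <- volume_grid(array(1, dim = c(5, 5, 5)))
  cr2 <- tight_crop(full)
  expect_equal(dim(cr2$volume$values), c(5, 5, 5))

  expect_error(tight_crop(volume_grid(array(0, c(4, 4, 4)))),
               class = "periseg_empty_error")
})

test_that("tight_crop equals an exhaustive bounding-box scan on sparse volumes", {
  set.seed(21)
  for (i in 1:100) {
    v <- array(0, dim = c(15, 15, 15))
    k <- sample(1:10, 1)
    v[sample(length(v), k)] <- runif(k, 0.5, 2)
    cr <- tight_crop(volume_grid(v))
    idx <- which(v > 0, arr.ind = TRUE)
    expect_equal(unname(cr$region),
                 unname(t(apply(idx, 2, range))))
  }
})

test_that("uncrop inverts tight_crop", {
  set.seed(22)
  v <- array(0, dim = c(20, 20, 20))
  v[5:12, 8:15, 3:9] <- runif(8 * 8 * 7)
  vol <- volume_grid(v)
  cr <- tight_crop(vol)
  back <- uncrop(cr$volume, cr$region, dim(v))
  expect_equal(back$values, v)
})

test_that("channel subtraction preserves negatives and checks grids", {
  a <- volume_grid(array(5, c(4, 4, 4)))
  b <- volume_grid(array(7, c(4, 4, 4)))
  expect_equal(subtract_channel(a, b)$values, array(-2, c(4, 4, 4)))
  expect_equal(subtract_channel(a, a)$values, array(0, c(4, 4, 4)))
  bb <- volume_grid(array(0, c(5, 4, 4)))
  expect_error(subtract_channel(a, bb), class = "periseg_alignment_error")
})

test_that("t1d channel highlights the enhancing rim", {
  st <- generate_patient(small_params(), seed = 9,
                         timepoints = "preoperative")
  seqs <- add_t1d(st$timepoints$preoperative$sequences)
  pre <- st$timepoints$preoperative$structures
  rim <- pre$TC$values & !pre$NETC$values
  p <- small_params()
  expected <- p$intensity_means$t1c[["rim"]] - p$intensity_means$t1w[["rim"]]
  expect_lt(abs(mean(seqs$t1d$values[rim]) - expected), 5 * p$noise_sd)
  expect_error(add_t1d(sequence_set(t1c = seqs$t1c)),
               class = "periseg_input_error")
})

test_that("clipping maps an extreme outlier to the 99.5th percentile", {
  set.seed(31)
  vals <- c(rnorm(999, 100, 10), 1e6)
  v <- volume_grid(array(vals, dim = c(10, 10, 10)))
  out <- clip_and_normalize(v, unit_variance = FALSE)
  # oracle: clip to the empirical [0th, 99.5th] percentiles, subtract the mean
  p <- unname(quantile(vals, c(0, 0.995), type = 7))
  oracle <- pmin(pmax(vals, p[1]), p[2])
  oracle <- oracle - mean(oracle)
  expect_equal(as.vector(out$values), oracle, tolerance = 1e-8)
  expect_equal(max(out$values) - min(out$values), p[2] - p[1],
               tolerance = 1e-8)
})

test_that("normalisation zeroes the nonzero-voxel mean and keeps zeros zero", {
  v <- array(0, dim = c(3, 3, 3))
  v[1:3] <- c(2, 4, 6)
  out <- clip_and_normalize(volume_grid(v))
  expect_lt(abs(mean(out$values[1:3])), 1e-9)   # originally-nonzero voxels
  expect_equal(sd(out$values[1:3]), 1, tolerance = 1e-9)  # unit variance
  expect_true(all(out$values[-(1:3)] == 0))

  zeros <- clip_and_normalize(volume_grid(array(0, c(4, 4, 4))))
  expect_true(all(zeros$values == 0))

  # constant nonzero foreground: mean-subtracted, scaling skipped with warning
  const <- array(0, dim = c(3, 3, 3)); const[1:5] <- 7
  expect_warning(out2 <- clip_and_normalize(volume_grid(const)),
                 "zero variance")
  expect_true(all(out2$values == 0))
})

test_that("nonzero-mean-zero invariant holds on random volumes", {
  set.seed(41)
  for (i in 1:20) {
    v <- array(0, dim = c(12, 12, 12))
    n <- sample(50:800, 1)
    v[sample(length(v), n)] <- rlnorm(n, 4, 1)
    out <- clip_and_normalize(volume_grid(v))
    nz <- v != 0
    expect_lt(abs(mean(out$values[nz])), 1e-6)
    expect_true(all(out$values[!nz] == 0))
  }
})

test_that("mask volume is the voxel count times voxel volume", {
  m <- cube_mask(c(20, 20, 20), c(1, 1, 1), c(10, 10, 10))
  expect_equal(mask_volume_ml(m), 1.0)
  expect_equal(mask_volume_ml(binary_mask(array(FALSE, c(4, 4, 4)))), 0)
  m2 <- cube_mask(c(20, 20, 20), c(1, 1, 1), c(7, 10, 5),
                  spacing = c(0.5, 1, 2))
  expect_equal(mask_volume_ml(m2), 7 * 10 * 5 * 1 / 1000)
  # 350 voxels at 1 mm: 0.35 ml, above the 0.175 ml residual-tumor cut-off
  m3 <- synth_component_mask(0.35, c(20, 20, 20))
  expect_equal(mask_volume_ml(m3), 0.35)
  expect_gt(mask_volume_ml(m3), threshold_policy()$positivity_cutoff_ml[["ET"]])
})

test_that("mask volume is additive over disjoint masks", {
  a <- cube_mask(c(30, 30, 30), c(1, 1, 1), c(5, 5, 5))
  b <- cube_mask(c(30, 30, 30), c(20, 20, 20), c(6, 6, 6))
  both <- binary_mask(a$values | b$values)
  expect_equal(mask_volume_ml(both), mask_volume_ml(a) + mask_volume_ml(b))
})
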