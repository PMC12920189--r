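test_that("threshold sweep produces nested masks at k/10", {
  set.seed(81)
  pm <- probability_map(array(runif(16^3), c(16, 16, 16)))
  sw <- threshold_sweep(pm)
  expect_equal(sw$threshold, (1:10) / 10)
  for (k in 1:9)
    expect_true(all(!sw$mask[[k + 1]]$values | sw$mask[[k]]$values))

  flat <- threshold_sweep(probability_map(array(0.55, c(8, 8, 8))))
  n_on <- vapply(flat$mask, function(m) sum(m$values), integer(1))
  expect_equal(n_on > 0, flat$threshold <= 0.55)
  expect_error(threshold_sweep(pm, n = 1), class = "periseg_parameter_error")
})

test_that("patient-wise outcomes follow the volume cut-off and Dice rule", {
  d <- c(30, 30, 30)
  et_035 <- synth_component_mask(0.35, d)
  expect_equal(patientwise_outcome(et_035, et_035, "ET"), "TP")

  empty <- binary_mask(array(FALSE, d))
  expect_equal(patientwise_outcome(empty, empty, "ET"), "TN")
  expect_equal(patientwise_outcome(empty, et_035, "ET"), "FP")
  expect_equal(patientwise_outcome(et_035, empty, "ET"), "FN")

  # both positive but fully disjoint (Dice 0): still a miss
  a <- synth_component_mask(1, d, center = c(8, 8, 8))
  b <- synth_component_mask(1, d, center = c(24, 24, 24))
  expect_false(any(a$values & b$values))
  expect_equal(patientwise_outcome(a, b, "ET"), "FN")

  # sub-cutoff volumes are negative regardless of overlap
  tiny <- synth_component_mask(0.1, d)
  expect_equal(patientwise_outcome(tiny, tiny, "ET"), "TN")
  # the same volume is positive for NETC (0.05 ml cut-off)
  expect_equal(patientwise_outcome(tiny, tiny, "NETC"), "TP")

  expect_error(patientwise_outcome(a, b, "XX"),
               class = "periseg_parameter_error")
})

test_that("classification metrics match direct arithmetic", {
  perfect <- classification_metrics(c(TP = 10, FN = 0, FP = 0, TN = 10))
  expect_equal(unlist(perfect), c(recall = 100, precision = 100,
                                  specificity = 100, bacc = 100))
  m <- classification_metrics(c(TP = 8, FN = 2, TN = 3, FP = 7))
  expect_equal(m$recall, 80)
  expect_equal(m$specificity, 30)
  expect_equal(m$bacc, 55)
  degenerate <- classification_metrics(c(TP = 0, FN = 0, TN = 5, FP = 2))
  expect_true(is.na(degenerate$recall))
  expect_false(is.na(degenerate$specificity))
})

test_that("voxel-wise metrics agree with closed forms and brute force", {
  a <- cube_mask(c(30, 30, 30), c(5, 5, 5), c(10, 10, 10))
  expect_equal(unlist(voxelwise_metrics(a, a)),
               c(dice = 100, recall = 100, precision = 100, hd95 = 0))

  # two 10-cubes overlapping in a 5x10x10 slab: Dice 50%
  b <- cube_mask(c(30, 30, 30), c(10, 5, 5), c(10, 10, 10))
  vw <- voxelwise_metrics(a, b)
  expect_equal(vw$dice, 50)
  expect_equal(vw$recall, 50)
  expect_equal(vw$precision, 50)

  # two single voxels 3 mm apart: HD95 = 3 mm
  p <- binary_mask(array(FALSE, c(12, 12, 12)))
  q <- binary_mask(array(FALSE, c(12, 12, 12)))
  p$values[4, 6, 6] <- TRUE
  q$values[7, 6, 6] <- TRUE
  expect_equal(voxelwise_metrics(p, q)$hd95, 3)

  e <- binary_mask(array(FALSE, c(12, 12, 12)))
  expect_equal(voxelwise_metrics(e, p)$dice, 0)
  expect_true(is.na(voxelwise_metrics(e, p)$hd95))
  expect_equal(voxelwise_metrics(e, e)$dice, 100)
  expect_equal(voxelwise_metrics(e, e)$hd95, 0)
})

test_that("dice is symmetric and bounded on random mask pairs", {
  set.seed(91)
  for (i in 1:25) {
    a <- binary_mask(array(runif(10^3) < 0.2, c(10, 10, 10)))
    b <- binary_mask(array(runif(10^3) < 0.2, c(10, 10, 10)))
    ab <- voxelwise_metrics(a, b)
    ba <- voxelwise_metrics(b, a)
    expect_equal(ab$dice, ba$dice)
    expect_true(ab$dice >= 0 && ab$dice <= 100)
    if (!is.na(ab$hd95)) expect_equal(ab$hd95, ba$hd95)
  }
})

test_that("HD95 equals brute-force all-pairs percentile on small masks", {
  set.seed(92)
  for (i in 1:30) {
    sp <- sample(list(c(1, 1, 1), c(1, 1.5, 2)), 1)[[1]]
    a <- binary_mask(array(runif(9^3) < 0.15, c(9, 9, 9)), spacing = sp)
    b <- binary_mask(array(runif(9^3) < 0.15, c(9, 9, 9)), spacing = sp)
    if (!sum(a$values) || !sum(b$values)) next
    expect_equal(voxelwise_metrics(a, b)$hd95, brute_hd95(a, b),
                 tolerance = 1e-6)
  }
})

pairing_dice_matrix <- function(gt_cc, pred_cc) {
  ov <- matrix(0, gt_cc$n, pred_cc$n)
  for (i in seq_len(gt_cc$n)) for (j in seq_len(pred_cc$n))
    ov[i, j] <- sum(gt_cc$labels == i & pred_cc$labels == j)
  2 * ov / outer(gt_cc$sizes, pred_cc$sizes, `+`)
}

test_that("component pairing is optimal where greedy best-first fails", {
  # pred1 overlaps both gt components strongly; pred2 overlaps gt1 weakly.
  # greedy takes the single best pair (gt1,pred1) and strands gt2 at zero;
  # the optimum is (gt1,pred2) + (gt2,pred1)
  d <- c(64, 12, 5)
  gt <- binary_mask(array(FALSE, d))
  gt$values[1:30, 1:10, ] <- TRUE        # gt1
  gt$values[33:62, 1:10, ] <- TRUE       # gt2
  pred <- binary_mask(array(FALSE, d))
  pred$values[1:62, 1:8, ] <- TRUE       # pred1: spans both gt components
  pred$values[1:30, 10, ] <- TRUE        # pred2: thin strip over gt1 only
  gt_cc <- connected_components(gt)
  pred_cc <- connected_components(pred)
  expect_equal(gt_cc$n, 2L)
  expect_equal(pred_cc$n, 2L)

  dice <- pairing_dice_matrix(gt_cc, pred_cc)
  greedy_total <- max(dice)              # greedy's first pick blocks the rest
  optimum <- brute_best_assignment(dice)
  expect_gt(optimum, greedy_total + 0.05)

  m <- pair_components(gt_cc, pred_cc)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(sum(m$pairs$dice) / 100, optimum, tolerance = 1e-12)
})

test_that("pairing equals the exhaustive optimum on random mask configurations", {
  set.seed(95)
  d <- c(36, 36, 12)
  for (trial in 1:25) {
    gt <- binary_mask(array(FALSE, d))
    pred <- binary_mask(array(FALSE, d))
    for (k in seq_len(sample(1:4, 1))) {
      c0 <- c(runif(2, 5, 31), runif(1, 3, 9))
      gt$values <- gt$values |
        synth_component_mask(runif(1, 0.05, 0.3), d, center = c0)$values
    }
    for (k in seq_len(sample(1:4, 1))) {
      c0 <- c(runif(2, 5, 31), runif(1, 3, 9))
      pred$values <- pred$values |
        synth_component_mask(runif(1, 0.05, 0.3), d, center = c0)$values
    }
    gt_cc <- connected_components(gt)
    pred_cc <- connected_components(pred)
    if (gt_cc$n == 0 || pred_cc$n == 0) next
    m <- pair_components(gt_cc, pred_cc)
    dice <- pairing_dice_matrix(gt_cc, pred_cc)
    expect_equal(sum(m$pairs$dice) / 100, brute_best_assignment(dice),
                 tolerance = 1e-9)
    if (nrow(m$pairs))
      expect_true(all(dice[as.matrix(m$pairs[, c("gt", "pred")])] > 0))
  }
})

test_that("object-wise metrics aggregate matched and unmatched components", {
  d <- c(50, 30, 20)
  gt <- binary_mask(array(FALSE, d))
  gt$values[2:11, 2:11, 2:6] <- TRUE       # 500 voxels, detected exactly
  gt$values[30:39, 2:11, 2:6] <- TRUE      # 500 voxels, missed
  pred <- binary_mask(array(FALSE, d))
  pred$values[2:11, 2:11, 2:6] <- TRUE
  ow <- objectwise_metrics(gt, pred, "ET")
  expect_equal(ow$dice, 50)       # (100 + 0) / 2
  expect_equal(ow$recall, 50)
  expect_equal(ow$precision, 100) # the only prediction is perfect
  expect_equal(ow$hd95, 0)        # matched pairs only

  # single matched pair: reduces to voxel-wise values of that pair
  solo_gt <- binary_mask(array(FALSE, d)); solo_gt$values[2:11, 2:11, 2:6] <- TRUE
  solo_pr <- binary_mask(array(FALSE, d)); solo_pr$values[4:13, 2:11, 2:6] <- TRUE
  ow2 <- objectwise_metrics(solo_gt, solo_pr, "ET")
  vw2 <- voxelwise_metrics(solo_gt, solo_pr)
  expect_equal(ow2$dice, vw2$dice)
  expect_equal(ow2$hd95, vw2$hd95)
})

test_that("size filtering shields HD95 from distant small false positives", {
  d <- c(60, 30, 20)
  gt <- binary_mask(array(FALSE, d))
  gt$values[2:11, 2:11, 2:6] <- TRUE
  pred_clean <- binary_mask(gt$values)
  pred_frag <- binary_mask(gt$values)
  pred_frag$values[52:55, 25:28, 15:18] <- TRUE   # 64 voxels < 75 minimum
  ow_clean <- objectwise_metrics(gt, pred_clean, "ET")
  ow_frag <- objectwise_metrics(gt, pred_frag, "ET")
  expect_equal(ow_frag$hd95, ow_clean$hd95)
  expect_equal(ow_frag$dice, ow_clean$dice)

  # NETC keeps 60-voxel components (50-voxel minimum), ET does not
  small <- binary_mask(array(FALSE, d))
  small$values[2:5, 2:6, 2:4] <- TRUE   # 60 voxels
  expect_equal(objectwise_metrics(small, small, "NETC")$dice, 100)
  expect_true(is.na(objectwise_metrics(small, small, "ET")$dice))
})

test_that("pooled estimates equal concatenated-sample statistics", {
  folds <- tibble::tibble(fold_id = c(1, 2), n = c(2, 2),
                          metric = "dice", mean = c(0.5, 1.0), sd = c(0, 0))
  pooled <- pooled_estimates(folds)
  expect_equal(pooled$mean, 0.75)
  expect_equal(pooled$sd, sd(c(0.5, 0.5, 1, 1)))

  # identical folds pool to the fold values
  same <- tibble::tibble(fold_id = 1:3, n = 5, metric = "dice",
                         mean = 70, sd = 4)
  pooled_same <- pooled_estimates(same)
  expect_equal(pooled_same$mean, 70)

  set.seed(101)
  for (i in 1:5) {
    values <- split(rnorm(60, 50, 20), rep(1:5, length.out = 60))
    folds <- purrr::imap_dfr(values, function(v, k)
      tibble::tibble(fold_id = k, n = length(v), metric = "m",
                     mean = mean(v), sd = sd(v)))
    pooled <- pooled_estimates(folds)
    expect_equal(pooled$mean, mean(unlist(values)), tolerance = 1e-9)
    expect_equal(pooled$sd, sd(unlist(values)), tolerance = 1e-9)
  }
})

test_that("best-threshold selection maximises Dice with ties upward", {
  records <- tibble::tibble(
    threshold = rep(c(0.4, 0.5, 0.6), each = 2),
    dice = c(80, 90, 90, 80, 60, 60),
    gt_positive = TRUE)
  expect_equal(select_best_threshold(records), 0.5)   # tie 85 at 0.4 and 0.5

  single <- tibble::tibble(threshold = 0.3, dice = 10, gt_positive = TRUE)
  expect_equal(select_best_threshold(single), 0.3)

  negatives <- tibble::tibble(threshold = 0.3, dice = 10, gt_positive = FALSE)
  expect_error(select_best_threshold(negatives),
               class = "periseg_selection_error")
})

test_that("sensitivity analysis reproduces hand-tallied counts and monotone TP", {
  set.seed(111)
  n <- 20
  records <- tibble::tibble(
    gt_positive = rep(c(TRUE, FALSE), c(14, 6)),
    pred_positive = c(rep(TRUE, 12), FALSE, FALSE, rep(TRUE, 2), rep(FALSE, 4)),
    dice = c(runif(12, 0, 100), 0, 0, 0, 0, 0, 0, 0, 0))
  tab <- sensitivity_analysis(records)
  for (k in seq_len(nrow(tab))) {
    t <- tab$dice_threshold_pct[k]
    expect_equal(tab$TP[k],
                 sum(records$gt_positive & records$pred_positive &
                       records$dice > t))
    expect_equal(tab$FP[k], 2)
    expect_equal(tab$TN[k], 4)
    expect_equal(tab$TP[k] + tab$FN[k], 14)
  }
  expect_true(all(diff(tab$TP) <= 0))
  expect_equal(tab$dice_threshold_pct, c(0.1, 10, 25, 50, 75))
})

test_that("evaluate_sample produces one record per threshold with outcomes", {
  st <- generate_patient(small_params(), seed = 22)
  gt <- st$timepoints$postoperative$structures$ET
  pm <- probability_map(array(as.numeric(gt$values), dim(gt$values)))
  recs <- evaluate_sample(gt, pm, "ET", objectwise = FALSE)
  expect_equal(nrow(recs), 10)
  expect_true(all(recs$dice == 100))
  expect_true(all(recs$hd95 == 0))
  expect_true(all(recs$outcome == "TP"))
})
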