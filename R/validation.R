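#' Binarize a probability map at equally spaced thresholds
#'
#' Thresholds are `k/n` for `k = 1..n` (ten by default, i.e. 0.1 to 1.0);
#' each mask is `pm >= t`, so masks are nested with increasing threshold.
#'
#' @param pm A `probability_map`.
#' @param n Number of thresholds (>= 2). Default 10.
#' @return A tibble with columns `threshold` and `mask` (list of
#'   `binary_mask`).
#' @export
threshold_sweep <- function(pm, n = 10) {
  stopifnot(inherits(pm, "probability_map"))
  if (!is.numeric(n) || n < 2)
    abort("`n` must be >= 2", class = "periseg_parameter_error")
  thresholds <- seq_len(n) / n
  masks <- lapply(thresholds, function(t)
    binary_mask(pm$values >= t, pm$spacing, pm$origin))
  tibble::tibble(threshold = thresholds, mask = masks)
}

#' Voxel-wise overlap and surface-distance metrics
#'
#' Dice, recall and precision on the percent scale, and the 95th-percentile
#' Hausdorff distance (HD95) in mm — the maximum of the two directed 95th
#' percentile surface-to-surface distances. When both masks are empty the
#' agreement is perfect (Dice 100, HD95 0); when exactly one is empty Dice
#' is 0 and HD95 undefined (`NA`).
#'
#' @param gt,pred `binary_mask` objects on one grid.
#' @return One-row tibble: `dice`, `recall`, `precision` (percent), `hd95`
#'   (mm).
#' @export
voxelwise_metrics <- function(gt, pred) {
  stopifnot(inherits(gt, "binary_mask"), inherits(pred, "binary_mask"))
  check_same_grid(gt, pred, "masks")
  ng <- sum(gt$values); np <- sum(pred$values)
  if (ng == 0 && np == 0)
    return(tibble::tibble(dice = 100, recall = 100, precision = 100, hd95 = 0))
  ov <- sum(gt$values & pred$values)
  dice <- 100 * 2 * ov / (ng + np)
  recall <- if (ng > 0) 100 * ov / ng else NA_real_
  precision <- if (np > 0) 100 * ov / np else NA_real_
  hd95 <- if (ng == 0 || np == 0) NA_real_ else hd95_mm(gt, pred)
  tibble::tibble(dice = dice, recall = recall, precision = precision,
                 hd95 = hd95)
}

hd95_mm <- function(gt, pred, q = 0.95) {
  sg <- mask_surface(gt)
  sp <- mask_surface(pred)
  dt_pred <- distance_transform(sp)
  dt_gt <- distance_transform(sg)
  d_g2p <- dt_pred[sg$values]
  d_p2g <- dt_gt[sp$values]
  max(stats::quantile(d_g2p, q, names = FALSE, type = 7),
      stats::quantile(d_p2g, q, names = FALSE, type = 7))
}

#' Patient-wise detection outcome for one sample
#'
#' A side (ground truth or prediction) is positive when its structure volume
#' reaches the per-structure cut-off. Both positive with a Dice overlap
#' above the policy's patient-wise threshold (0.1% by default) is a true
#' positive; both positive without sufficient overlap — or ground truth
#' positive with a negative prediction — is a false negative; prediction
#' positive alone is a false positive; both negative is a true negative.
#'
#' @param gt,pred `binary_mask` objects on one grid.
#' @param structure Structure label with a policy cut-off (e.g. `"ET"`).
#' @param policy A `threshold_policy`.
#' @param dice_pct Optional precomputed Dice (percent) to avoid recomputation.
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
patientwise_outcome <- function(gt, pred, structure,
                                policy = threshold_policy(),
                                dice_pct = NULL) {
  cut <- positivity_cutoff(policy, structure)
  gt_pos <- mask_volume_ml(gt) >= cut
  pred_pos <- mask_volume_ml(pred) >= cut
  if (!gt_pos && !pred_pos) return("TN")
  if (!gt_pos && pred_pos) return("FP")
  if (gt_pos && !pred_pos) return("FN")
  if (is.null(dice_pct)) {
    ov <- sum(gt$values & pred$values)
    dice_pct <- 100 * 2 * ov / (sum(gt$values) + sum(pred$values))
  }
  if (dice_pct > policy$patientwise_tp_dice_pct) "TP" else "FN"
}

#' Patient-wise classification metrics from outcome counts
#'
#' @param counts Named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble: `recall`, `precision`, `specificity`, `bacc`
#'   (percent; `NA` where the denominator is zero).
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  recall <- frac(tp, tp + fn)
  precision <- frac(tp, tp + fp)
  specificity <- frac(tn, tn + fp)
  bacc <- if (is.na(recall) || is.na(specificity)) NA_real_
          else (recall + specificity) / 2
  tibble::tibble(recall = recall, precision = precision,
                 specificity = specificity, bacc = bacc)
}

overlap_table <- function(gt_labels, pred_labels, n_gt, n_pred) {
  both <- gt_labels > 0L & pred_labels > 0L
  ov <- matrix(0, nrow = n_gt, ncol = n_pred)
  if (any(both)) {
    tab <- table(gt = gt_labels[both], pred = pred_labels[both])
    ov[cbind(as.integer(rownames(tab))[row(tab)],
             as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
  }
  ov
}

#' Optimal one-to-one component pairing
#'
#' Matches ground-truth to predicted connected components with the Hungarian
#' algorithm, minimising total `1 - Dice` over assigned pairs. Pairs with no
#' voxel overlap are dissolved after assignment, so only genuinely
#' overlapping components are matched.
#'
#' @param gt_cc,pred_cc Component labelings from [connected_components()]
#'   (already size-filtered).
#' @return A list: `pairs` (tibble `gt`, `pred`, `dice` in percent),
#'   `unmatched_gt`, `unmatched_pred` (integer component indices).
#' @export
pair_components <- function(gt_cc, pred_cc) {
  n_gt <- gt_cc$n; n_pred <- pred_cc$n
  empty <- tibble::tibble(gt = integer(0), pred = integer(0),
                          dice = numeric(0))
  if (n_gt == 0 || n_pred == 0)
    return(list(pairs = empty, unmatched_gt = seq_len(n_gt),
                unmatched_pred = seq_len(n_pred)))
  ov <- overlap_table(gt_cc$labels, pred_cc$labels, n_gt, n_pred)
  dice <- 2 * ov / outer(gt_cc$sizes, pred_cc$sizes, `+`)
  cost <- 1 - dice
  if (n_gt <= n_pred) {
    sol <- clue::solve_LSAP(cost)
    assign <- cbind(gt = seq_len(n_gt), pred = as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(cost))
    assign <- cbind(gt = as.integer(sol), pred = seq_len(n_pred))
  }
  keep <- ov[assign] > 0
  pairs <- tibble::tibble(gt = assign[keep, "gt"],
                          pred = assign[keep, "pred"],
                          dice = 100 * dice[assign[keep, , drop = FALSE]])
  list(pairs = pairs,
       unmatched_gt = setdiff(seq_len(n_gt), pairs$gt),
       unmatched_pred = setdiff(seq_len(n_pred), pairs$pred))
}

component_mask <- function(cc, i, template) {
  out <- template
  out$values <- cc$labels == i
  out
}

#' Object-wise (lesion-wise) metrics
#'
#' Extracts 26-connected components from both masks, discards components
#' below the per-structure minimum size (75 voxels by default, 50 for NETC),
#' pairs them optimally ([pair_components()]), computes voxel-wise metrics
#' per matched pair, and aggregates: every unmatched ground-truth component
#' contributes 0 to Dice and recall, every unmatched predicted component 0
#' to Dice and precision; HD95 is averaged over matched pairs only.
#'
#' @param gt,pred `binary_mask` objects on one grid.
#' @param structure Structure label (selects the minimum component size).
#' @param policy A `threshold_policy`.
#' @return One-row tibble: `dice`, `recall`, `precision` (percent), `hd95`
#'   (mm), `n_pairs`, `n_gt`, `n_pred`. All-`NA` metrics when neither side
#'   has a surviving component.
#' @export
objectwise_metrics <- function(gt, pred, structure = "ET",
                               policy = threshold_policy()) {
  check_same_grid(gt, pred, "masks")
  minvox <- min_component_voxels(policy, structure)
  gt_cc <- connected_components(gt, min_voxels = minvox)
  pred_cc <- connected_components(pred, min_voxels = minvox)
  if (gt_cc$n == 0 && pred_cc$n == 0)
    return(tibble::tibble(dice = NA_real_, recall = NA_real_,
                          precision = NA_real_, hd95 = NA_real_,
                          n_pairs = 0L, n_gt = 0L, n_pred = 0L))
  m <- pair_components(gt_cc, pred_cc)
  per_pair <- purrr::map2_dfr(m$pairs$gt, m$pairs$pred, function(i, j) {
    voxelwise_metrics(component_mask(gt_cc, i, gt),
                      component_mask(pred_cc, j, pred))
  })
  dice_vals <- c(per_pair$dice, rep(0, length(m$unmatched_gt)),
                 rep(0, length(m$unmatched_pred)))
  recall_vals <- c(per_pair$recall, rep(0, length(m$unmatched_gt)))
  precision_vals <- c(per_pair$precision, rep(0, length(m$unmatched_pred)))
  tibble::tibble(
    dice = mean(dice_vals),
    recall = if (gt_cc$n > 0) mean(recall_vals) else NA_real_,
    precision = if (pred_cc$n > 0) mean(precision_vals) else NA_real_,
    hd95 = if (nrow(per_pair)) mean(per_pair$hd95) else NA_real_,
    n_pairs = nrow(m$pairs), n_gt = gt_cc$n, n_pred = pred_cc$n)
}

#' Pooled mean and standard deviation across folds
#'
#' Combines per-fold summary statistics into the exact sample statistics of
#' the concatenated per-sample values: pooled mean is the size-weighted mean
#' of fold means; pooled variance adds within-fold and between-fold
#' contributions over `sum(n) - 1` degrees of freedom.
#'
#' @param folds Tibble with columns `fold_id`, `n`, `metric`, `mean`, `sd`.
#' @return Tibble per metric: `metric`, `n`, `mean`, `sd` (`sd` is `NA`
#'   when fewer than two samples are pooled).
#' @export
pooled_estimates <- function(folds) {
  stopifnot(all(c("n", "metric", "mean", "sd") %in% names(folds)))
  stopifnot(all(folds$n >= 1))
  folds |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      pooled_mean = sum(.data$n * .data$mean) / sum(.data$n),
      pooled_sd = {
        N <- sum(.data$n)
        if (N < 2) NA_real_ else {
          within <- sum((.data$n - 1) * .data$sd^2)
          between <- sum(.data$n * (.data$mean - pooled_mean)^2)
          sqrt((within + between) / (N - 1))
        }
      },
      n = sum(.data$n), .groups = "drop") |>
    dplyr::select("metric", "n", mean = "pooled_mean", sd = "pooled_sd")
}

#' Fold-level summary of per-sample metric records
#'
#' @param records Tibble with columns `fold`, plus metric columns.
#' @param metrics Metric column names to summarise.
#' @return Tibble `fold_id`, `n`, `metric`, `mean`, `sd` (NA values dropped
#'   per metric).
#' @export
fold_stats <- function(records, metrics = c("dice", "recall", "precision", "hd95")) {
  records |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(fold_id = .data$fold, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::mutate(sd = dplyr::coalesce(.data$sd, 0))
}

#' Select the best binarization threshold
#'
#' Returns the sweep threshold maximising mean voxel-wise Dice over positive
#' samples (ties broken toward the higher threshold).
#'
#' @param records Tibble with columns `threshold`, `dice`, `gt_positive`.
#' @return The selected threshold (scalar).
#' @export
select_best_threshold <- function(records) {
  stopifnot(all(c("threshold", "dice", "gt_positive") %in% names(records)))
  pos <- dplyr::filter(records, .data$gt_positive)
  if (!nrow(pos))
    abort("no positive samples to select a threshold on",
          class = "periseg_selection_error")
  summ <- pos |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(mean_dice = mean(.data$dice, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_dice), dplyr::desc(.data$threshold))
  summ$threshold[[1]]
}

#' Detection-threshold sensitivity analysis
#'
#' Recomputes patient-wise outcomes over a cohort while sweeping the
#' true-positive Dice threshold (defaults: 0.1, 10, 25, 50, 75 percent).
#' Volume-based positivity of each side is fixed, so TN and FP counts are
#' unchanged across thresholds; TP counts are non-increasing.
#'
#' @param records Tibble with per-sample columns `gt_positive`,
#'   `pred_positive` (logical) and `dice` (percent).
#' @param dice_thresholds Dice thresholds in percent.
#' @return A `periseg_sensitivity` tibble: one row per threshold with
#'   outcome counts and classification metrics.
#' @export
sensitivity_analysis <- function(records,
                                 dice_thresholds = c(0.1, 10, 25, 50, 75)) {
  stopifnot(all(c("gt_positive", "pred_positive", "dice") %in% names(records)))
  rows <- purrr::map_dfr(dice_thresholds, function(t) {
    tp <- sum(records$gt_positive & records$pred_positive & records$dice > t)
    fn <- sum(records$gt_positive) - tp
    fp <- sum(!records$gt_positive & records$pred_positive)
    tn <- sum(!records$gt_positive & !records$pred_positive)
    dplyr::bind_cols(
      tibble::tibble(dice_threshold_pct = t, TP = tp, FP = fp, TN = tn, FN = fn),
      classification_metrics(c(TP = tp, FP = fp, TN = tn, FN = fn)))
  })
  class(rows) <- c("periseg_sensitivity", class(rows))
  rows
}

#' Evaluate one sample across a threshold sweep
#'
#' Runs the full multi-level evaluation of a predicted probability map
#' against its ground truth: for each sweep threshold, the patient-wise
#' outcome, voxel-wise metrics, and (optionally) object-wise metrics.
#'
#' @param gt A `binary_mask` ground truth.
#' @param pm A `probability_map` prediction.
#' @param structure Structure label.
#' @param policy A `threshold_policy`.
#' @param n_thresholds Sweep cardinality (default 10).
#' @param objectwise Compute object-wise metrics too (default TRUE).
#' @param sample_id,fold Identifiers carried into the output.
#' @return A tibble of metric records, one row per threshold.
#' @export
evaluate_sample <- function(gt, pm, structure = "ET",
                            policy = threshold_policy(), n_thresholds = 10,
                            objectwise = TRUE, sample_id = "sample",
                            fold = 1L) {
  sweep <- threshold_sweep(pm, n_thresholds)
  cut <- positivity_cutoff(policy, structure)
  gt_vol <- mask_volume_ml(gt)
  purrr::pmap_dfr(sweep, function(threshold, mask) {
    vw <- voxelwise_metrics(gt, mask)
    pred_vol <- mask_volume_ml(mask)
    outcome <- patientwise_outcome(gt, mask, structure, policy,
                                   dice_pct = vw$dice)
    base <- tibble::tibble(sample_id = sample_id, structure = structure,
                           fold = fold, threshold = threshold,
                           gt_volume_ml = gt_vol, pred_volume_ml = pred_vol,
                           gt_positive = gt_vol >= cut,
                           pred_positive = pred_vol >= cut,
                           outcome = outcome)
    out <- dplyr::bind_cols(base, vw)
    if (objectwise) {
      ow <- objectwise_metrics(gt, mask, structure, policy)
      names(ow) <- paste0("obj_", names(ow))
      out <- dplyr::bind_cols(out, ow)
    }
    out
  })
}
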