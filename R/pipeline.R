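#' Write a synthetic cohort to a directory tree
#'
#' Lays out `patient/timepoint/` NIfTI files (sequences and ground-truth
#' structure masks) plus a `manifest.csv` that downstream stages consume.
#' The manifest also carries the fold label, the negative flag and the
#' contrast-enhancement class (the classifier contract: class labels are
#' manifest-provided).
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
simulate_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    study <- cohort$study[[i]]
    pid <- cohort$patient_id[[i]]
    for (tp in names(study$timepoints)) {
      tpdir <- file.path(dir, pid, tp)
      dir.create(tpdir, recursive = TRUE, showWarnings = FALSE)
      seqs <- study$timepoints[[tp]]$sequences
      for (nm in names(seqs))
        write_volume(seqs[[nm]], file.path(tpdir, paste0(nm, ".nii.gz")))
      structs <- study$timepoints[[tp]]$structures
      for (nm in names(structs))
        write_volume(structs[[nm]],
                     file.path(tpdir, paste0("gt_", nm, ".nii.gz")))
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = pid, timepoint = tp, fold = cohort$fold[[i]],
        negative = cohort$negative[[i]],
        contrast_enhancing = study$contrast_enhancing,
        sequences = paste(names(seqs), collapse = ";"),
        structures = paste(names(structs), collapse = ";"),
        path = file.path(pid, tp))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a cohort from a directory tree
#'
#' Reads back the `manifest.csv` layout written by [simulate_cohort_dir()].
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return Tibble `patient_id`, `fold`, `negative`, `study`.
#' @export
read_cohort_dir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  split_rows <- split(manifest, manifest$patient_id)
  studies <- lapply(split_rows, function(rows) {
    tps <- list()
    for (k in seq_len(nrow(rows))) {
      tpdir <- file.path(dir, rows$path[k])
      seqs <- strsplit(rows$sequences[k], ";")[[1]]
      structs <- strsplit(rows$structures[k], ";")[[1]]
      ss <- sequence_set(stats::setNames(lapply(seqs, function(nm)
        read_volume(file.path(tpdir, paste0(nm, ".nii.gz")))), seqs))
      st <- structure_set(stats::setNames(lapply(structs, function(nm)
        read_volume(file.path(tpdir, paste0("gt_", nm, ".nii.gz")),
                    as = "mask")), structs))
      tps[[rows$timepoint[k]]] <- list(sequences = ss, structures = st)
    }
    patient_study(rows$patient_id[1], preoperative = tps$preoperative,
                  postoperative = tps$postoperative,
                  contrast_enhancing = isTRUE(rows$contrast_enhancing[1]))
  })
  first <- manifest[!duplicated(manifest$patient_id), ]
  ord <- order(first$patient_id)
  tibble::tibble(patient_id = first$patient_id[ord],
                 fold = first$fold[ord], negative = first$negative[ord],
                 study = unname(studies[first$patient_id[ord]]))
}

segment_timepoint <- function(study, timepoint, structures_to_segment, cfg,
                              policy, blur, noise, seed, bin_threshold) {
  tp <- study$timepoints[[timepoint]]
  gt <- tp$structures
  brain <- gt$BRAIN
  preds <- list()
  for (nm in structures_to_segment) {
    if (!nm %in% names(gt)) next
    pred <- make_oracle_predictor(gt, structure = nm, blur = blur,
                                  noise = noise, seed = seed,
                                  patch_shape = cfg$patch_shape %||% c(64, 64, 64),
                                  channels = intersect(names(tp$sequences),
                                                       c("t1c", "t1w")))
    pm <- if (cfg$tta_enabled) tta_predict(tp$sequences, pred, cfg)
          else sliding_window_predict(tp$sequences, pred, cfg)
    if (!is.null(brain))
      pm <- postprocess_probability(pm, brain, policy, bin_threshold)
    preds[[nm]] <- pm
  }
  preds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full demonstration pipeline
#'
#' Orchestrates simulate -> preprocess -> segment (oracle predictor) ->
#' postprocess -> refine -> report -> validate on a synthetic cohort,
#' writing every artifact under `out_dir`: the cohort tree, refined
#' predicted masks, per-patient JSON and Markdown reports, validation CSVs
#' and a structured run log. Identical config and seed produce
#' byte-identical reports.
#'
#' @param out_dir Output directory.
#' @param n_patients Cohort size (default 5).
#' @param seed Integer seed for all randomness.
#' @param params A `phantom_params`.
#' @param policy A `threshold_policy`.
#' @param cfg An `inference_config`; patch shape defaults to 64^3 at
#'   phantom scale.
#' @param structure Structure evaluated by the validation stage.
#' @param blur,noise Oracle-predictor degradation (0 = exact oracle).
#' @param bin_threshold Binarization threshold for predicted masks.
#' @param validate Run the validation stage (default TRUE).
#' @return Invisibly, a list with `reports` (list of `periseg_report`),
#'   `records` (validation tibble or NULL), and `log` (tibble).
#' @export
run_pipeline <- function(out_dir, n_patients = 5, seed = 1L,
                         params = phantom_params(),
                         policy = threshold_policy(),
                         cfg = inference_config(patch_shape = c(64, 64, 64)),
                         structure = "ET", blur = 0, noise = 0,
                         bin_threshold = 0.5, validate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(stage, patient, detail = "") {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage,
                                              patient = patient,
                                              detail = detail)
  }

  cohort <- generate_cohort(n_patients, params, fold_count = min(5, n_patients),
                            seed = seed)
  simulate_cohort_dir(cohort, file.path(out_dir, "cohort"))
  stage("simulate", "all", sprintf("%d patients", n_patients))

  dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
  reports <- list()
  records <- list()
  seeds <- local({ set.seed(seed); sample.int(2^30, n_patients) })

  for (i in seq_len(nrow(cohort))) {
    study <- cohort$study[[i]]
    pid <- cohort$patient_id[[i]]

    # preprocessing (resample, crop, t1d, clip, normalise) per timepoint
    for (tp in names(study$timepoints)) {
      pp <- preprocess_sequences(study$timepoints[[tp]]$sequences)
      stage("preprocess", pid,
            sprintf("%s: crop [%s]", tp,
                    paste(apply(pp$region, 1, paste, collapse = "-"),
                          collapse = ",")))
    }

    refined <- list()
    for (tp in names(study$timepoints)) {
      to_seg <- if (tp == "preoperative") c("TC", "NETC", "SNFH")
                else c("ET", "CAVITY", "SNFH")
      pms <- segment_timepoint(study, tp, to_seg, cfg, policy, blur, noise,
                               seed = seeds[i], bin_threshold = bin_threshold)
      stage("segment", pid, sprintf("%s: %s", tp,
                                    paste(names(pms), collapse = ",")))
      masks <- lapply(pms, function(pm)
        binary_mask(pm$values >= bin_threshold, pm$spacing, pm$origin))
      masks$BRAIN <- study$timepoints[[tp]]$structures$BRAIN
      ref <- refine_structures(structure_set(masks), timepoint = tp,
                               contrast_enhancing = study$contrast_enhancing)
      refined[[tp]] <- ref$structures
      stage("refine", pid,
            sprintf("%s: removed %d voxels", tp,
                    sum(ref$log$voxels_removed)))
      if (tp == "postoperative" && validate && structure %in% names(pms)) {
        records[[length(records) + 1]] <- evaluate_sample(
          study$timepoints[[tp]]$structures[[structure]], pms[[structure]],
          structure = structure, policy = policy, sample_id = pid,
          fold = cohort$fold[[i]], objectwise = FALSE)
      }
    }

    pred_study <- patient_study(
      pid,
      preoperative = if ("preoperative" %in% names(refined))
        list(sequences = NULL, structures = refined$preoperative),
      postoperative = if ("postoperative" %in% names(refined))
        list(sequences = NULL, structures = refined$postoperative),
      contrast_enhancing = study$contrast_enhancing)
    rep <- build_report(pred_study, policy)
    report_to_json(rep, file.path(out_dir, "reports", paste0(pid, ".json")))
    writeLines(report_to_markdown(rep),
               file.path(out_dir, "reports", paste0(pid, ".md")))
    reports[[pid]] <- rep
    stage("report", pid, rep$surgical$resection_category %||% "no surgical section")
  }

  recs <- NULL
  if (validate && length(records)) {
    recs <- dplyr::bind_rows(records)
    dir.create(file.path(out_dir, "validation"), showWarnings = FALSE)
    utils::write.csv(recs, file.path(out_dir, "validation", "records.csv"),
                     row.names = FALSE)
    best <- select_best_threshold(recs)
    at_best <- dplyr::filter(recs, .data$threshold == best)
    fs <- fold_stats(at_best)
    utils::write.csv(fs, file.path(out_dir, "validation", "folds.csv"),
                     row.names = FALSE)
    utils::write.csv(pooled_estimates(fs),
                     file.path(out_dir, "validation", "pooled.csv"),
                     row.names = FALSE)
    utils::write.csv(sensitivity_analysis(at_best),
                     file.path(out_dir, "validation", "sensitivity.csv"),
                     row.names = FALSE)
    stage("validate", "all", sprintf("best threshold %.1f", best))
  }

  logtb <- dplyr::bind_rows(log)
  utils::write.csv(logtb, file.path(out_dir, "run_log.csv"),
                   row.names = FALSE)
  invisible(list(reports = reports, records = recs, log = logtb))
}

#' Evaluate a cohort against predictions
#'
#' Runs the threshold-sweep evaluation of one structure over every patient
#' owning the requested timepoint. When `predictions` is NULL the ground
#' truth is used as its own (perfect) probability map — the oracle-identity
#' configuration.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param structure Structure label.
#' @param timepoint Timepoint to evaluate.
#' @param policy A `threshold_policy`.
#' @param predictions Optional named list (by patient id) of
#'   `probability_map` predictions.
#' @param n_thresholds Sweep cardinality.
#' @param objectwise Compute object-wise metrics (slower).
#' @return Tibble of metric records (one row per patient x threshold).
#' @export
evaluate_cohort <- function(cohort, structure = "ET",
                            timepoint = "postoperative",
                            policy = threshold_policy(), predictions = NULL,
                            n_thresholds = 10, objectwise = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    study <- cohort$study[[i]]
    if (!timepoint %in% names(study$timepoints)) next
    gt <- study$timepoints[[timepoint]]$structures[[structure]]
    if (is.null(gt)) next
    pid <- cohort$patient_id[[i]]
    pm <- if (!is.null(predictions)) predictions[[pid]]
          else probability_map(array(as.numeric(gt$values),
                                     dim = dim(gt$values)),
                               gt$spacing, gt$origin)
    rows[[length(rows) + 1]] <- evaluate_sample(
      gt, pm, structure = structure, policy = policy,
      n_thresholds = n_thresholds, objectwise = objectwise,
      sample_id = pid, fold = cohort$fold[[i]])
  }
  dplyr::bind_rows(rows)
}
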