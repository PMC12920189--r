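#' Volumetric and planimetric features of one structure
#'
#' Computes the standardized per-structure report features: physical volume
#' (ml), diameter characteristics on the axial slice of maximal in-slice
#' lesion area — long and short axis of the best-fit (moment-matched)
#' ellipse, Feret (maximal caliper) diameter and area-equivalent diameter,
#' all in mm — the tumor-to-brain volume ratio in percent, and the
#' 26-connected component count. An empty mask yields all-zero features.
#'
#' @param mask A `binary_mask` of the structure.
#' @param brain A `binary_mask` of the brain, same grid.
#' @return One-row tibble: `volume_ml`, `long_axis_mm`, `short_axis_mm`,
#'   `feret_mm`, `equivalent_diameter_mm`, `tumor_to_brain_ratio_pct`,
#'   `component_count`.
#' @export
compute_features <- function(mask, brain) {
  stopifnot(inherits(mask, "binary_mask"), inherits(brain, "binary_mask"))
  check_same_grid(mask, brain, "mask and brain")
  if (!any(brain$values))
    abort("brain mask is empty", class = "periseg_parameter_error")
  if (!any(mask$values))
    return(tibble::tibble(volume_ml = 0, long_axis_mm = 0, short_axis_mm = 0,
                          feret_mm = 0, equivalent_diameter_mm = 0,
                          tumor_to_brain_ratio_pct = 0, component_count = 0L))
  vol <- mask_volume_ml(mask)
  ratio <- 100 * vol / mask_volume_ml(brain)
  ncomp <- connected_components(mask)$n

  slice_areas <- apply(mask$values, 3, sum)
  zi <- which.max(slice_areas)
  slab <- mask$values[, , zi]
  px <- mask$spacing[1:2]
  coords <- which(slab, arr.ind = TRUE)
  xy <- cbind(coords[, 1] * px[1], coords[, 2] * px[2])
  area <- nrow(xy) * prod(px)
  eqd <- 2 * sqrt(area / pi)

  # Feret: max pairwise distance among convex-hull points of pixel centres
  if (nrow(xy) == 1) {
    feret <- 0
    long_axis <- short_axis <- 0
  } else {
    hull <- xy[grDevices::chull(xy), , drop = FALSE]
    dd <- as.matrix(stats::dist(hull))
    feret <- max(dd)
    cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    long_axis <- 4 * sqrt(ev[1])
    short_axis <- 4 * sqrt(ev[2])
  }

  tibble::tibble(volume_ml = vol, long_axis_mm = long_axis,
                 short_axis_mm = short_axis, feret_mm = feret,
                 equivalent_diameter_mm = eqd,
                 tumor_to_brain_ratio_pct = ratio,
                 component_count = as.integer(ncomp))
}

#' Post-surgical volumetric evolution (extent of resection)
#'
#' `100 * (pre - post) / pre` percent: the relative volume change from the
#' preoperative to the postoperative timepoint. Equals the extent of
#' resection when the structure is the tumor. Negative values indicate
#' growth; a zero preoperative volume makes the quantity undefined and
#' returns `NA` (not an error).
#'
#' @param pre_ml,post_ml Structure volumes (ml) at each timepoint.
#' @return Percent change, or `NA_real_` when `pre_ml` is 0.
#' @export
volumetric_evolution <- function(pre_ml, post_ml) {
  stopifnot(pre_ml >= 0, post_ml >= 0)
  if (pre_ml == 0) return(NA_real_)
  if (post_ml == 0) return(100)
  100 * (pre_ml - post_ml) / pre_ml
}

#' Surgical outcome category from residual tumor volume
#'
#' Maps the postoperative residual volume to the RANO-style surgical
#' assessment: `complete` below `complete_max_ml` (default: the 0.175 ml
#' residual-tumor detectability cut-off), `near total` up to
#' `near_total_max_ml` (default 1 ml), otherwise `subtotal`. The thresholds
#' live in the policy, never in the code.
#'
#' @param residual_ml Residual volume in ml (>= 0).
#' @param policy A `threshold_policy`.
#' @return One of `"complete"`, `"near total"`, `"subtotal"`.
#' @export
classify_resection <- function(residual_ml, policy = threshold_policy()) {
  if (!is.numeric(residual_ml) || residual_ml < 0)
    abort("`residual_ml` must be >= 0", class = "periseg_parameter_error")
  if (residual_ml < policy$complete_max_ml) "complete"
  else if (residual_ml <= policy$near_total_max_ml) "near total"
  else "subtotal"
}

#' Build the standardized perioperative report
#'
#' Assembles per-timepoint features for every segmented structure, the
#' volumetric evolution of each structure present at both timepoints, and —
#' when both timepoints exist — the surgical assessment from the
#' postoperative residual: ET for contrast-enhancing tumors, SNFH (the
#' whole-tumor proxy) otherwise.
#'
#' @param study A `patient_study` with refined structure sets.
#' @param policy A `threshold_policy`.
#' @return A `periseg_report`: list with `patient_id`, `features` (tibble),
#'   `evolution` (tibble), `surgical` (list or NULL), `policy`, `warnings`.
#' @export
build_report <- function(study, policy = threshold_policy()) {
  stopifnot(inherits(study, "patient_study"))
  if (!length(study$timepoints))
    abort("study has no timepoints", class = "periseg_input_error")

  feats <- list()
  warnings <- character(0)
  for (tp in names(study$timepoints)) {
    ss <- study$timepoints[[tp]]$structures
    brain <- ss$BRAIN
    if (is.null(brain)) {
      warnings <- c(warnings, paste0(tp, ": no brain mask; ratios unavailable"))
      next
    }
    for (nm in setdiff(names(ss), "BRAIN")) {
      f <- compute_features(ss[[nm]], brain)
      feats[[length(feats) + 1]] <-
        dplyr::bind_cols(tibble::tibble(timepoint = tp, structure = nm), f)
    }
  }
  features <- if (length(feats)) dplyr::bind_rows(feats) else
    tibble::tibble(timepoint = character(0), structure = character(0))

  evolution <- tibble::tibble(structure = character(0),
                              pre_ml = numeric(0), post_ml = numeric(0),
                              evolution_pct = numeric(0))
  surgical <- NULL
  if (all(c("preoperative", "postoperative") %in% names(study$timepoints))) {
    pre <- study$timepoints$preoperative$structures
    post <- study$timepoints$postoperative$structures
    common <- intersect(setdiff(names(pre), "BRAIN"),
                        setdiff(names(post), "BRAIN"))
    # tumor evolution pairs a preoperative structure with its postoperative
    # counterpart even when labels differ (TC before vs ET after surgery)
    pairs <- tibble::tibble(structure = common, pre_label = common,
                            post_label = common)
    if (study$contrast_enhancing && !is.null(pre$TC) && !is.null(post$ET) &&
        !"ET" %in% names(pre))
      pairs <- dplyr::bind_rows(pairs,
                                tibble::tibble(structure = "tumor",
                                               pre_label = "TC",
                                               post_label = "ET"))
    evolution <- purrr::pmap_dfr(pairs, function(structure, pre_label, post_label) {
      pre_ml <- mask_volume_ml(pre[[pre_label]])
      post_ml <- mask_volume_ml(post[[post_label]])
      tibble::tibble(structure = structure, pre_ml = pre_ml, post_ml = post_ml,
                     evolution_pct = volumetric_evolution(pre_ml, post_ml))
    })

    residual_label <- if (study$contrast_enhancing) "ET" else "SNFH"
    res_mask <- post[[residual_label]]
    if (!is.null(res_mask)) {
      residual_ml <- mask_volume_ml(res_mask)
      surgical <- list(
        residual_structure = residual_label,
        residual_ml = residual_ml,
        resection_category = classify_resection(residual_ml, policy),
        extent_of_resection_pct = {
          eor_row <- if (study$contrast_enhancing)
            dplyr::filter(evolution, .data$structure %in% c("tumor", "ET"))
          else dplyr::filter(evolution, .data$structure == "SNFH")
          if (nrow(eor_row)) eor_row$evolution_pct[[1]] else NA_real_
        },
        thresholds = list(complete_max_ml = policy$complete_max_ml,
                          near_total_max_ml = policy$near_total_max_ml))
    }
  }

  structure(list(patient_id = study$patient_id,
                 contrast_enhancing = study$contrast_enhancing,
                 features = features, evolution = evolution,
                 surgical = surgical,
                 location_features = "unavailable (atlas registration out of scope)",
                 policy = unclass(policy), warnings = warnings),
            class = "periseg_report")
}

sort_named_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    if (!is.null(names(x)) && all(names(x) != ""))
      x <- x[order(names(x))]
    lapply(x, sort_named_deep)
  } else x
}

#' Serialize a report to deterministic JSON
#'
#' Keys are sorted and floats written at fixed precision so identical inputs
#' produce byte-identical files.
#'
#' @param report A `periseg_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "periseg_report"))
  payload <- sort_named_deep(unclass(report))
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = 6, na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Read back a serialized report
#'
#' @param path JSON path written by [report_to_json()].
#' @return A `periseg_report`.
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  x$features <- tibble::as_tibble(x$features)
  x$evolution <- tibble::as_tibble(x$evolution)
  structure(x, class = "periseg_report")
}

#' Render a report as Markdown
#'
#' @param report A `periseg_report`.
#' @return Character vector of Markdown lines.
#' @export
report_to_markdown <- function(report) {
  stopifnot(inherits(report, "periseg_report"))
  lines <- c(sprintf("# Perioperative report — patient %s", report$patient_id),
             sprintf("Tumor type: %s",
                     if (isTRUE(report$contrast_enhancing)) "contrast-enhancing"
                     else "non-contrast-enhancing"),
             "", "## Structure features")
  f <- report$features
  if (nrow(f)) {
    lines <- c(lines,
               "| timepoint | structure | volume (ml) | long axis (mm) | short axis (mm) | Feret (mm) | eq. diameter (mm) | tumor/brain (%) | components |",
               "|---|---|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.1f | %.1f | %.1f | %.1f | %.2f | %d |",
                       f$timepoint, f$structure, f$volume_ml, f$long_axis_mm,
                       f$short_axis_mm, f$feret_mm, f$equivalent_diameter_mm,
                       f$tumor_to_brain_ratio_pct, f$component_count))
  }
  if (nrow(report$evolution)) {
    e <- report$evolution
    lines <- c(lines, "", "## Volumetric evolution",
               "| structure | pre (ml) | post (ml) | evolution (%) |",
               "|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %s |", e$structure, e$pre_ml,
                       e$post_ml, ifelse(is.na(e$evolution_pct), "n/a",
                                         sprintf("%.1f", e$evolution_pct))))
  }
  if (!is.null(report$surgical)) {
    s <- report$surgical
    lines <- c(lines, "", "## Surgical assessment",
               sprintf("- Residual %s volume: %.3f ml", s$residual_structure,
                       s$residual_ml),
               sprintf("- Extent of resection: %s",
                       if (is.na(s$extent_of_resection_pct)) "n/a"
                       else sprintf("%.1f%%", s$extent_of_resection_pct)),
               sprintf("- Category: **%s** (complete < %.3f ml, near total <= %.3f ml)",
                       s$resection_category, s$thresholds$complete_max_ml,
                       s$thresholds$near_total_max_ml))
  }
  if (length(report$warnings))
    lines <- c(lines, "", "## Warnings",
               paste0("- ", report$warnings))
  lines
}

#' @export
print.periseg_report <- function(x, ...) {
  cat(report_to_markdown(x), sep = "\n")
  invisible(x)
}
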