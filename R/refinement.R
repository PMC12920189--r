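#' Cross-structure mask refinement
#'
#' Enforces global anatomical consistency between independently segmented
#' structures of one timepoint.
#'
#' Contrast-enhancing tumors, preoperatively: the tumor core (TC) is the
#' reference and is left unchanged; NETC is restricted to the voxels it
#' shares with TC; TC is subtracted from SNFH; the whole tumor (WT) is the
#' disjoint union of TC and the refined SNFH. Postoperatively: the enhancing
#' residual tissue (ET) is the reference; the cavity and ET are subtracted
#' from SNFH. Non-contrast-enhancing tumors: SNFH serves as the whole tumor
#' mask; postoperatively the cavity is subtracted from SNFH first.
#'
#' Absent structures are skipped silently; every output is restricted to the
#' brain mask when one is present; the brain mask itself is never modified.
#' ET/CAVITY overlaps are not resolved (no rule exists) but are flagged.
#'
#' @param structures A `structure_set`.
#' @param timepoint `"preoperative"` or `"postoperative"`.
#' @param contrast_enhancing Logical.
#' @return A list: `structures` (refined `structure_set`), `log` (tibble of
#'   voxels removed per rule), `warnings` (character).
#' @export
refine_structures <- function(structures,
                              timepoint = c("preoperative", "postoperative"),
                              contrast_enhancing = TRUE) {
  stopifnot(inherits(structures, "structure_set"))
  timepoint <- match.arg(timepoint)
  s <- unclass(structures)
  log <- list()
  warnings <- character(0)
  note <- function(rule, removed) {
    log[[length(log) + 1]] <<- tibble::tibble(rule = rule,
                                              voxels_removed = as.integer(removed))
  }
  and_not <- function(a, b) a$values & !b$values

  if (contrast_enhancing && timepoint == "preoperative") {
    if (is.null(s$TC))
      abort("preoperative refinement of a contrast-enhancing tumor requires TC",
            class = "periseg_input_error")
    if (!is.null(s$NETC)) {
      before <- sum(s$NETC$values)
      s$NETC$values <- s$NETC$values & s$TC$values
      note("NETC_outside_TC", before - sum(s$NETC$values))
    }
    if (!is.null(s$SNFH)) {
      before <- sum(s$SNFH$values)
      s$SNFH$values <- and_not(s$SNFH, s$TC)
      note("SNFH_minus_TC", before - sum(s$SNFH$values))
    }
    wt <- s$TC
    if (!is.null(s$SNFH)) wt$values <- wt$values | s$SNFH$values
    s$WT <- wt
  } else if (contrast_enhancing && timepoint == "postoperative") {
    if (is.null(s$ET))
      abort("postoperative refinement of a contrast-enhancing tumor requires ET",
            class = "periseg_input_error")
    if (!is.null(s$SNFH)) {
      rem <- s$ET$values
      if (!is.null(s$CAVITY)) rem <- rem | s$CAVITY$values
      before <- sum(s$SNFH$values)
      s$SNFH$values <- s$SNFH$values & !rem
      note("SNFH_minus_cavity_ET", before - sum(s$SNFH$values))
    }
    if (!is.null(s$CAVITY) && any(s$ET$values & s$CAVITY$values))
      warnings <- c(warnings, "ET and CAVITY overlap; left untouched")
  } else {
    # non-contrast-enhancing: SNFH is the whole tumor
    if (is.null(s$SNFH))
      abort("refinement of a non-contrast-enhancing tumor requires SNFH",
            class = "periseg_input_error")
    if (timepoint == "postoperative" && !is.null(s$CAVITY)) {
      before <- sum(s$SNFH$values)
      s$SNFH$values <- and_not(s$SNFH, s$CAVITY)
      note("SNFH_minus_cavity", before - sum(s$SNFH$values))
    }
    s$WT <- s$SNFH
  }

  if (!is.null(s$BRAIN)) {
    for (nm in setdiff(names(s), "BRAIN")) {
      before <- sum(s[[nm]]$values)
      s[[nm]]$values <- s[[nm]]$values & s$BRAIN$values
      removed <- before - sum(s[[nm]]$values)
      if (removed > 0) note(paste0(nm, "_outside_brain"), removed)
    }
  }

  list(structures = structure_set(s),
       log = if (length(log)) dplyr::bind_rows(log)
             else tibble::tibble(rule = character(0),
                                 voxels_removed = integer(0)),
       warnings = warnings)
}
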