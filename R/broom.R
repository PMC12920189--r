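#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a perioperative report
#'
#' One row per timepoint and structure with the full feature set.
#'
#' @param x A `periseg_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.periseg_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(patient_id = x$patient_id), x$features)
}

#' One-row summary of a perioperative report
#'
#' @param x A `periseg_report`.
#' @param ... Unused.
#' @return A tibble with the surgical headline numbers.
#' @export
glance.periseg_report <- function(x, ...) {
  s <- x$surgical
  tibble::tibble(
    patient_id = x$patient_id,
    contrast_enhancing = x$contrast_enhancing,
    n_structures = length(unique(x$features$structure)),
    residual_ml = if (is.null(s)) NA_real_ else s$residual_ml,
    extent_of_resection_pct = if (is.null(s)) NA_real_
                              else s$extent_of_resection_pct,
    resection_category = if (is.null(s)) NA_character_
                         else s$resection_category)
}

#' Tidy a sensitivity analysis
#'
#' @param x A `periseg_sensitivity` tibble.
#' @param ... Unused.
#' @return A plain tibble (one row per Dice threshold).
#' @export
tidy.periseg_sensitivity <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
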