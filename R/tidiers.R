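# broom-style accessors and ggplot2 autoplot methods for the result
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an annotation table into candidate-level rows
#'
#' @param x An `ms_annotations` tibble.
#' @param ... Unused.
#' @return A tibble with one row per (spectrum, candidate) pair.
#' @export
tidy.ms_annotations <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), "spectrum_id", "rt_min",
                       "precursor_mz", "confidence", "candidates")
  tidyr::unnest(out, "candidates")
}

#' One-row summary of an annotation table
#'
#' @param x An `ms_annotations` tibble.
#' @param ... Unused.
#' @return A tibble with spectrum counts per confidence level.
#' @export
glance.ms_annotations <- function(x, ...) {
  tibble::tibble(
    n_spectra = nrow(x),
    n_identified_reference = sum(x$confidence == "identified_reference"),
    n_library_matched = sum(x$confidence == "library_matched"),
    n_class_characterized = sum(x$confidence == "class_characterized"),
    n_unknown = sum(x$confidence == "unknown"),
    n_classes = dplyr::n_distinct(x$class[!is.na(x$class)])
  )
}

#' Tidy a DDA run into its trigger log
#'
#' @param x A `dda_run`.
#' @param ... Unused.
#' @return The trigger-log tibble.
#' @export
tidy.dda_run <- function(x, ...) x$trigger_log

#' One-row summary of a DDA run
#'
#' @param x A `dda_run`.
#' @param ... Unused.
#' @return A tibble with component, scan and spectrum counts.
#' @export
glance.dda_run <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$mixture),
    n_ms1_scans = if (nrow(x$trigger_log) > 0L) max(x$trigger_log$scan) else 0L,
    n_ms2_spectra = nrow(x$spectra),
    n_triggered_components = dplyr::n_distinct(x$spectra$source_id),
    n_knockout_windows = if (is.null(x$windows)) 0L else nrow(x$windows)
  )
}

#' Tidy recovery metrics into the per-decile recall table
#'
#' @param x A `recovery_metrics` object.
#' @param ... Unused.
#' @return The per-abundance-decile recall tibble.
#' @export
tidy.recovery_metrics <- function(x, ...) x$decile_recall

#' One-row summary of recovery metrics
#'
#' @param x A `recovery_metrics` object.
#' @param ... Unused.
#' @return A tibble with counts, precision and recall.
#' @export
glance.recovery_metrics <- function(x, ...) {
  tibble::tibble(
    n_ground_truth = x$n_ground_truth,
    n_triggered = x$n_triggered,
    n_annotated_correct = x$n_annotated_correct,
    precision = x$precision,
    precision_defined = x$precision_defined,
    recall = x$recall
  )
}
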