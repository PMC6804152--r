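# Depth-first neutral-loss chain search. Glycosides dissociate by shedding
# sugar and acyl units one at a time, so the MS2 peak list contains a
# "ladder" from the precursor down to the aglycone; this module enumerates
# every maximal chain of registry losses that is supported by observed
# peaks.

#' Annotation engine configuration
#'
#' @param ppm_precursor Precursor match tolerance in ppm (default 10).
#' @param ppm_fragment Fragment match tolerance in ppm (default 10).
#' @param diag_tol_da Absolute tolerance for diagnostic ions in Da (default
#'   0.02); diagnostics are tabulated at 2 decimal places so an absolute
#'   window is the appropriate match rule.
#' @param max_depth Maximum loss-chain depth (default 8).
#' @param min_intensity Minimum fragment intensity in counts (default 5).
#' @param rt_window_min Retention-time window for reference-standard
#'   matching in minutes (default 0.2).
#' @param score_threshold Minimum candidate score for the
#'   `library_matched` confidence level (default 0.3).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(ppm_precursor = 10, ppm_fragment = 10,
                              diag_tol_da = 0.02, max_depth = 8,
                              min_intensity = 5, rt_window_min = 0.2,
                              score_threshold = 0.3) {
  stopifnot(ppm_precursor > 0, ppm_fragment > 0, diag_tol_da > 0,
            max_depth >= 1, min_intensity >= 0, rt_window_min > 0,
            score_threshold > 0)
  structure(list(
    ppm_precursor = ppm_precursor, ppm_fragment = ppm_fragment,
    diag_tol_da = diag_tol_da, max_depth = as.integer(max_depth),
    min_intensity = min_intensity, rt_window_min = rt_window_min,
    score_threshold = score_threshold
  ), class = "annotation_config")
}

# Accept a peaks data frame or a one-row spectra tibble.
as_peaks <- function(spectrum) {
  if (is.data.frame(spectrum) && "peaks" %in% names(spectrum)) {
    stopifnot(nrow(spectrum) == 1L)
    return(spectrum$peaks[[1]])
  }
  normalize_peaks(spectrum)
}

# Best observed peak for a theoretical m/z, or NA. Diagnostic matching uses
# an absolute window, ladder matching a ppm window.
match_peak <- function(peaks, target, ppm = NULL, abs_tol = NULL,
                       min_intensity = 0) {
  if (nrow(peaks) == 0L) return(NA_real_)
  ok <- peaks$intensity >= min_intensity
  d <- abs(peaks$mz - target)
  ok <- ok & if (!is.null(abs_tol)) d <= abs_tol else {
    abs(ppm_error(peaks$mz, target)) <= ppm
  }
  if (!any(ok)) return(NA_real_)
  cand <- peaks$mz[ok]
  cand[which.min(abs(cand - target))]
}

#' Find all maximal neutral-loss chains in a spectrum
#'
#' Depth-first search over the loss vocabulary starting from `start_mz`
#' (usually the deprotonated-molecule node). Each step subtracts one
#' registry loss from the current theoretical node and must land, within
#' the fragment ppm tolerance, on an observed peak at or above the minimum
#' intensity; chained node values stay theoretical so errors do not
#' accumulate. Only maximal (non-extendable) chains are returned, in
#' lexicographic order of their loss-name sequences. A chain cut off by
#' the depth limit is flagged `truncated`, not an error.
#'
#' @param spectrum A one-row spectra tibble or a peaks data frame.
#' @param start_mz Starting m/z of the chain (precursor-derived node).
#' @param losses Loss vocabulary tibble (default [neutral_losses()]).
#' @param config An [annotation_config()].
#' @return A tibble with one row per maximal chain: `losses` and `node_mz`
#'   list-columns (nodes include the start), `matched_mz` (observed peak
#'   per step), `ppm` (signed error per step), `terminal_mz`, `depth`,
#'   `truncated`.
#' @examples
#' peaks <- tibble::tibble(
#'   mz = c(475.3793, 637.4321, 769.4744, 931.5272),
#'   intensity = rep(100, 4))
#' find_loss_paths(peaks, 931.5272)
#' @export
find_loss_paths <- function(spectrum, start_mz, losses = neutral_losses(),
                            config = annotation_config()) {
  peaks <- as_peaks(spectrum)
  losses <- losses[order(losses$name), ]
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  recurse <- function(node, loss_names, nodes, matched, ppms, depth) {
    ext <- list()
    for (i in seq_len(nrow(losses))) {
      target <- node - losses$mass[i]
      if (target <= 0) next
      hit <- match_peak(peaks, target, ppm = config$ppm_fragment,
                        min_intensity = config$min_intensity)
      if (!is.na(hit)) {
        ext[[length(ext) + 1L]] <- list(name = losses$name[i], target = target,
                                        hit = hit)
      }
    }
    if (length(ext) == 0L || depth >= config$max_depth) {
      acc$rows[[length(acc$rows) + 1L]] <- tibble::tibble(
        losses = list(loss_names), node_mz = list(nodes),
        matched_mz = list(matched), ppm = list(ppms),
        terminal_mz = node, depth = depth,
        truncated = length(ext) > 0L && depth >= config$max_depth
      )
      return(invisible(NULL))
    }
    for (e in ext) {
      recurse(e$target, c(loss_names, e$name), c(nodes, e$target),
              c(matched, e$hit), c(ppms, ppm_error(e$hit, e$target)),
              depth + 1L)
    }
  }
  recurse(start_mz, character(0), start_mz, NA_real_, NA_real_, 0L)
  dplyr::bind_rows(acc$rows)
}

# Loss-name sequence as a single comparable string.
path_key <- function(losses) {
  vapply(losses, paste, character(1), collapse = ";")
}
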