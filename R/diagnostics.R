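# Diagnostic-ion classing, acylation detection and glycan-composition
# inference: the rule layer that turns a peak list plus loss chains into a
# structural reading (which sapogenin core, how many malonyls, which
# sugars).

#' Classify the sapogenin core from diagnostic product ions
#'
#' Negative-mode saponin fragmentation terminates in deprotonated sapogenin
#' ions; this matches the observed peaks against the diagnostic table of
#' [diagnostic_ions()] at an absolute tolerance. A label is eligible only
#' when its primary sapogenin ion is present (the side-chain-loss ion is
#' corroboration); the OA-GlurA call additionally requires at least one of
#' the decarboxylation pair. Among eligible labels the one with the most
#' matched diagnostics wins; an unresolved tie returns `"none"` with the
#' tied candidates listed. Positive mode returns `"none"` by design (the
#' saponin rules are negative-mode only).
#'
#' @param spectrum A one-row spectra tibble or peaks data frame.
#' @param polarity `"negative"` or `"positive"`; defaults to the spectrum's
#'   own polarity when available.
#' @param config An [annotation_config()].
#' @return A list of class `sapogenin_call`: `label`, `matched` (tibble of
#'   matched diagnostic rows with observed m/z and intensity), `candidates`
#'   (labels tied when `label == "none"`, otherwise empty).
#' @export
classify_sapogenin <- function(spectrum, polarity = NULL,
                               config = annotation_config()) {
  if (is.null(polarity) && is.data.frame(spectrum) &&
      "polarity" %in% names(spectrum)) {
    polarity <- spectrum$polarity[[1]]
  }
  polarity <- match.arg(polarity, c("negative", "positive"))
  empty_call <- structure(
    list(label = "none",
         matched = tibble::tibble(label = character(), mz = numeric(),
                                  kind = character(), observed_mz = numeric(),
                                  intensity = numeric()),
         candidates = character(0)),
    class = "sapogenin_call")
  if (polarity == "positive") return(empty_call)
  peaks <- as_peaks(spectrum)
  diag <- diagnostic_ions()
  hits <- purrr::map_dbl(diag$mz, function(m) {
    match_peak(peaks, m, abs_tol = config$diag_tol_da,
               min_intensity = config$min_intensity)
  })
  diag$observed_mz <- hits
  diag$intensity <- purrr::map2_dbl(hits, seq_along(hits), function(h, i) {
    if (is.na(h)) NA_real_ else peaks$intensity[which.min(abs(peaks$mz - h))]
  })
  matched <- diag[!is.na(diag$observed_mz), ]
  if (nrow(matched) == 0L) return(empty_call)
  per_label <- dplyr::group_by(matched, .data$label)
  per_label <- dplyr::summarise(
    per_label,
    n_matched = dplyr::n(),
    has_primary = any(.data$kind == "primary"),
    has_corr = any(.data$kind == "corroboration"),
    .groups = "drop")
  eligible <- per_label$has_primary &
    !(per_label$label == "OA_GlurA" & !per_label$has_corr)
  per_label <- per_label[eligible, ]
  if (nrow(per_label) == 0L) return(empty_call)
  best <- per_label[per_label$n_matched == max(per_label$n_matched), ]
  if (nrow(best) > 1L) {
    out <- empty_call
    out$matched <- matched
    out$candidates <- sort(best$label)
    return(out)
  }
  structure(list(label = best$label,
                 matched = matched[matched$label == best$label, ],
                 candidates = character(0)),
            class = "sapogenin_call")
}

#' @export
print.sapogenin_call <- function(x, ...) {
  cat("<sapogenin_call> label:", x$label)
  if (length(x$candidates) > 0L) {
    cat(" (tied:", paste(x$candidates, collapse = ", "), ")")
  }
  cat("\n")
  if (nrow(x$matched) > 0L) print(x$matched)
  invisible(x)
}

#' Detect malonyl substitution from CO2 / C3H2O3 neutral losses
#'
#' Malonylated saponins shed CO2 and the whole malonyl group (C3H2O3) from
#' the deprotonated molecule. A peak at the node minus one CO2 or one
#' malonyl indicates a single malonyl; a peak at the node minus two of
#' either indicates dimalonylation (which does not require the
#' single-malonyl evidence to also be present).
#'
#' @param spectrum A one-row spectra tibble or peaks data frame.
#' @param precursor_node_mz The deprotonated-molecule node m/z.
#' @param config An [annotation_config()].
#' @return Integer malonyl count: 0, 1 or 2.
#' @export
detect_malonyl <- function(spectrum, precursor_node_mz,
                           config = annotation_config()) {
  peaks <- as_peaks(spectrum)
  co2 <- loss_mass("CO2")
  mal <- loss_mass("malonyl")
  seen <- function(target) {
    !is.na(match_peak(peaks, target, abs_tol = config$diag_tol_da,
                      min_intensity = config$min_intensity))
  }
  if (seen(precursor_node_mz - 2 * co2) || seen(precursor_node_mz - 2 * mal)) {
    return(2L)
  }
  if (seen(precursor_node_mz - co2) || seen(precursor_node_mz - mal)) {
    return(1L)
  }
  0L
}

#' Infer the glycan composition from loss chains and the sapogenin call
#'
#' Chooses the loss chain that terminates at (or, failing that, nearest
#' above) a diagnostic ion of the called sapogenin, and reads the sugar
#' multiset off that chain. Ties are broken by longer chain, then more
#' sugar-typed losses, then lexicographic loss-name sequence, so the
#' result is deterministic.
#'
#' @param paths A chain tibble from [find_loss_paths()].
#' @param sapogenin A `sapogenin_call` from [classify_sapogenin()].
#' @param config An [annotation_config()].
#' @return A list: `sugars` (named integer multiset over sugar losses),
#'   `terminal_resolved` (`TRUE` when the chosen chain ends on a sapogenin
#'   diagnostic), `terminal_mz`, and `path` (the chosen chain row, or
#'   `NULL` when no chains were given).
#' @export
infer_glycan_composition <- function(paths, sapogenin,
                                     config = annotation_config()) {
  if (is.null(paths) || nrow(paths) == 0L) {
    return(list(sugars = integer(0), terminal_resolved = FALSE,
                terminal_mz = NA_real_, path = NULL))
  }
  diag <- diagnostic_ions()
  sap_mz <- if (sapogenin$label != "none") {
    diag$mz[diag$label == sapogenin$label]
  } else numeric(0)
  resolved <- rep(FALSE, nrow(paths))
  if (length(sap_mz) > 0L) {
    resolved <- purrr::map_lgl(paths$terminal_mz, function(t) {
      any(abs(t - sap_mz) <= config$diag_tol_da)
    })
  }
  if (any(resolved)) {
    pool <- paths[resolved, ]
    is_resolved <- TRUE
  } else if (length(sap_mz) > 0L) {
    # nearest terminal above the primary sapogenin ion
    primary <- diag$mz[diag$label == sapogenin$label & diag$kind == "primary"][1]
    above <- paths$terminal_mz >= primary - config$diag_tol_da
    pool <- if (any(above)) paths[above, ] else paths
    if (any(above)) {
      pool <- pool[abs(pool$terminal_mz - primary) ==
                     min(abs(pool$terminal_mz - primary)), ]
    }
    is_resolved <- FALSE
  } else {
    pool <- paths
    is_resolved <- FALSE
  }
  sugar_names <- neutral_losses(role = "sugar")$name
  n_sugar <- purrr::map_int(pool$losses, ~ sum(.x %in% sugar_names))
  ord <- order(-pool$depth, -n_sugar, path_key(pool$losses))
  chosen <- pool[ord[1], ]
  chain <- chosen$losses[[1]]
  sugar_chain <- chain[chain %in% sugar_names]
  sugars <- if (length(sugar_chain) > 0L) {
    tab <- table(sugar_chain)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(sugars = sugars, terminal_resolved = is_resolved,
       terminal_mz = chosen$terminal_mz, path = chosen)
}
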