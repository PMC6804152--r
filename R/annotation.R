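# Candidate generation, theoretical fragment ladders, scoring and the
# per-spectrum annotation pipeline.

base_adduct_for <- function(polarity) {
  if (polarity == "negative") "[M-H]-" else "[M+H]+"
}

#' Generate adduct hypotheses for a precursor m/z
#'
#' Tries every registry adduct of the spectrum's polarity against the
#' library: a (record, adduct) pair is a hypothesis when the theoretical
#' adduct m/z of the record matches the precursor within the precursor ppm
#' tolerance. Results are sorted by absolute ppm error, then record id,
#' then adduct name.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param polarity `"negative"` or `"positive"`.
#' @param library A compound library tibble.
#' @param config An [annotation_config()].
#' @return A tibble of hypotheses with record fields, `adduct`,
#'   `theoretical_mz` and `ppm`.
#' @export
hypothesize_adducts <- function(precursor_mz, polarity, library,
                                config = annotation_config()) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  adds <- adducts(polarity)
  hyps <- purrr::map(adds$name, function(a) {
    th <- mz_from_adduct(library$neutral_mass, a)
    ppm <- ppm_error(precursor_mz, th)
    hit <- abs(ppm) <= config$ppm_precursor
    if (!any(hit)) return(NULL)
    out <- library[hit, ]
    out$adduct <- a
    out$theoretical_mz <- th[hit]
    out$ppm <- ppm[hit]
    out
  })
  out <- dplyr::bind_rows(hyps)
  if (nrow(out) == 0L) {
    out <- dplyr::mutate(library[0, ], adduct = character(0),
                         theoretical_mz = numeric(0), ppm = numeric(0))
  }
  dplyr::arrange(out, abs(.data$ppm), .data$id, .data$adduct)
}

# Canonical sugar-loss order when a record gives a composition but no
# explicit sequence: expanded multiset sorted by loss name.
canonical_sugar_sequence <- function(comp) {
  comp <- comp[order(names(comp))]
  rep(names(comp), comp)
}

#' Theoretical fragment set of a library record
#'
#' Builds the rule-derived fragment list shared by the acquisition
#' simulator and the candidate scorer: the adduct precursor, the
#' (de)protonated-molecule node when the precursor is a different adduct,
#' acyl losses (CO2/whole-malonyl for malonylated records, sequential
#' acetyl losses), the cumulative glycosidic loss ladder (an explicit
#' per-record loss sequence when curated, otherwise the canonical sugar
#' order), diagnostic sapogenin ions in negative mode, and the
#' positive-mode class rules (methyl radical/H2O/CO chain for abietane
#' diterpenoids, CH4/CH3OH/CO/CH3 eliminations from the isoflavone
#' aglycone node).
#'
#' @param record A one-row library tibble.
#' @param polarity `"negative"` or `"positive"`.
#' @param adduct Adduct name for the precursor; defaults to the
#'   (de)protonated molecule for the polarity.
#' @return A tibble with `mz`, `label`, `kind` (`precursor`, `base`,
#'   `acyl`, `ladder`, `diagnostic`, `class`), deduplicated on m/z. An
#'   attribute `derivable` is `FALSE` when the record supports no rule
#'   beyond the precursor.
#' @export
theoretical_fragments <- function(record, polarity = "negative",
                                  adduct = NULL) {
  stopifnot(nrow(record) == 1L)
  polarity <- match.arg(polarity, c("negative", "positive"))
  if (is.null(adduct)) adduct <- base_adduct_for(polarity)
  mass <- record$neutral_mass
  base_add <- base_adduct_for(polarity)
  precursor <- mz_from_adduct(mass, adduct)
  base <- mz_from_adduct(mass, base_add)
  rows <- list(tibble::tibble(mz = precursor, label = adduct, kind = "precursor"))
  if (!identical(adduct, base_add)) {
    rows <- c(rows, list(tibble::tibble(mz = base, label = base_add, kind = "base")))
  }
  n_mal <- record$malonyl
  n_ac <- record$acetyl
  node <- base
  if (n_mal > 0L) {
    co2 <- loss_mass("CO2"); mal <- loss_mass("malonyl")
    acyl <- c(base - co2, base - mal)
    if (n_mal >= 2L) acyl <- c(acyl, base - 2 * co2, base - 2 * mal)
    rows <- c(rows, list(tibble::tibble(
      mz = acyl, label = rep(c("-CO2", "-malonyl"), length.out = length(acyl)),
      kind = "acyl")))
    node <- base - n_mal * mal
  }
  if (n_ac > 0L) {
    ac <- loss_mass("acetyl")
    steps <- node - cumsum(rep(ac, n_ac))
    rows <- c(rows, list(tibble::tibble(
      mz = steps, label = sprintf("-%dacetyl", seq_len(n_ac)), kind = "acyl")))
    node <- node - n_ac * ac
  }
  seq_str <- record$loss_sequence
  comp <- parse_sugar_composition(record$sugar_composition)
  chain <- if (!is.na(seq_str) && nzchar(seq_str)) {
    strsplit(seq_str, ";", fixed = TRUE)[[1]]
  } else if (length(comp) > 0L) {
    canonical_sugar_sequence(comp)
  } else character(0)
  aglycone_node <- node
  if (length(chain) > 0L) {
    steps <- node - cumsum(loss_mass(chain))
    rows <- c(rows, list(tibble::tibble(
      mz = steps,
      label = paste0("-", vapply(seq_along(chain), function(k) {
        paste(chain[seq_len(k)], collapse = "-")
      }, character(1))),
      kind = "ladder")))
    aglycone_node <- steps[length(steps)]
  }
  agl <- record$aglycone
  if (polarity == "negative" && !is.na(agl) && nzchar(agl)) {
    diag <- diagnostic_ions()
    labels <- agl
    if (agl == "OA" && "GlurA" %in% names(comp)) labels <- c("OA", "OA_GlurA")
    d <- diag[diag$label %in% labels, ]
    if (nrow(d) > 0L) {
      rows <- c(rows, list(tibble::tibble(
        mz = d$mz, label = paste0(d$label, "_", d$kind), kind = "diagnostic")))
    }
  }
  if (polarity == "positive" && record$class == "tanshinone") {
    chain_cls <- c("CH3", "H2O", "CO")
    steps <- base - cumsum(loss_mass(chain_cls))
    rows <- c(rows, list(tibble::tibble(
      mz = steps, label = paste0("-", c("CH3", "CH3-H2O", "CH3-H2O-CO")),
      kind = "class")))
  }
  if (polarity == "positive" && record$class == "flavonoid") {
    single <- c("CH4", "CH3OH", "CO", "CH3")
    rows <- c(rows, list(tibble::tibble(
      mz = aglycone_node - loss_mass(single),
      label = paste0("-", single), kind = "class")))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[out$mz > 0, ]
  # collapse nodes that coincide (e.g. the full sugar ladder terminus and
  # the deprotonated sapogenin diagnostic)
  keep <- !duplicated(round(out$mz, 3))
  out <- out[keep, ]
  attr(out, "derivable") <- any(out$kind %in% c("ladder", "diagnostic", "class", "acyl"))
  out
}

#' Score a candidate record against a spectrum
#'
#' The score is the matched fraction of the record's theoretical fragment
#' set (everything in [theoretical_fragments()] except the precursor
#' node): ladder and acyl nodes are matched at the fragment ppm tolerance,
#' diagnostic ions at the absolute diagnostic tolerance. A record with no
#' derivable fragments, or a spectrum matching none of them, falls back to
#' the precursor-only floor of 0.1.
#'
#' @param record A one-row library tibble.
#' @param spectrum A one-row spectra tibble or peaks data frame.
#' @param adduct Adduct name of the precursor hypothesis.
#' @param config An [annotation_config()].
#' @return A list: `score` in `[0.1, 1]`, `matched` and `total` fragment
#'   counts.
#' @export
score_candidate <- function(record, spectrum, adduct,
                            config = annotation_config()) {
  polarity <- if (is.data.frame(spectrum) && "polarity" %in% names(spectrum)) {
    spectrum$polarity[[1]]
  } else "negative"
  peaks <- as_peaks(spectrum)
  th <- theoretical_fragments(record, polarity, adduct)
  frag <- th[th$kind != "precursor", ]
  if (nrow(frag) == 0L) {
    return(list(score = 0.1, matched = 0L, total = 0L))
  }
  hit <- purrr::map2_lgl(frag$mz, frag$kind, function(m, k) {
    if (k == "diagnostic") {
      !is.na(match_peak(peaks, m, abs_tol = config$diag_tol_da,
                        min_intensity = config$min_intensity))
    } else {
      !is.na(match_peak(peaks, m, ppm = config$ppm_fragment,
                        min_intensity = config$min_intensity))
    }
  })
  list(score = max(sum(hit) / nrow(frag), 0.1),
       matched = sum(hit), total = nrow(frag))
}

.CONFIDENCE_LEVELS <- c("identified_reference", "library_matched",
                        "class_characterized", "unknown")

sapogenin_class_hint <- function(label) {
  switch(label,
         PPT = , PPD = , OA = , OA_GlurA = "ginsenoside",
         cycloastragenol = , soyasapogenol = "astragaloside",
         NA_character_)
}

#' Annotate a single spectrum against a compound library
#'
#' Runs the full characterization pipeline: adduct hypothesis generation,
#' neutral-loss chain search from the (de)protonated-molecule node,
#' diagnostic sapogenin classing, malonyl detection, glycan-composition
#' inference, then candidate scoring and ranking (score descending,
#' absolute ppm ascending, id ascending; isomeric candidates are all
#' retained). Confidence is `identified_reference` when a
#' reference-standard candidate matches mass, retention time (within the
#' configured window) and at least one fragment; `library_matched` when
#' the top candidate scores at or above the score threshold;
#' `class_characterized` when no library candidate qualifies but class
#' diagnostics fired; otherwise `unknown`.
#'
#' @param spectrum A one-row spectra tibble.
#' @param library A compound library tibble.
#' @param config An [annotation_config()].
#' @return A one-row annotation tibble (see [annotate_spectra()]).
#' @export
annotate_spectrum <- function(spectrum, library,
                              config = annotation_config()) {
  stopifnot(nrow(spectrum) == 1L)
  polarity <- spectrum$polarity[[1]]
  precursor <- spectrum$precursor_mz[[1]]
  base_add <- base_adduct_for(polarity)
  hyps <- hypothesize_adducts(precursor, polarity, library, config)

  # chain search starts from the (de)protonated node; when the precursor is
  # an FA/acetate adduct the adduct loss is the implied first step
  node0 <- if (nrow(hyps) > 0L) {
    mz_from_adduct(hyps$neutral_mass[1], base_add)
  } else {
    precursor
  }
  paths <- find_loss_paths(spectrum, node0, config = config)
  sap <- classify_sapogenin(spectrum, polarity, config)
  mal <- if (polarity == "negative") {
    detect_malonyl(spectrum, node0, config)
  } else 0L
  glycan <- infer_glycan_composition(paths, sap, config)

  candidates <- NULL
  if (nrow(hyps) > 0L) {
    scored <- purrr::map(seq_len(nrow(hyps)), function(i) {
      s <- score_candidate(hyps[i, ], spectrum, hyps$adduct[i], config)
      rt_ok <- !is.na(spectrum$rt_min[[1]]) && !is.na(hyps$expected_rt[i]) &&
        abs(spectrum$rt_min[[1]] - hyps$expected_rt[i]) <= config$rt_window_min
      tibble::tibble(
        id = hyps$id[i], name = hyps$name[i], class = hyps$class[i],
        subclass = hyps$subclass[i], formula = hyps$formula[i],
        adduct = hyps$adduct[i], neutral_mass = hyps$neutral_mass[i],
        ppm = hyps$ppm[i], score = s$score, matched = s$matched,
        total = s$total, reference_standard = hyps$reference_standard[i],
        rt_match = rt_ok)
    })
    candidates <- dplyr::bind_rows(scored)
    candidates <- dplyr::arrange(candidates, dplyr::desc(.data$score),
                                 abs(.data$ppm), .data$id)
  } else {
    candidates <- tibble::tibble(
      id = character(), name = character(), class = character(),
      subclass = character(), formula = character(), adduct = character(),
      neutral_mass = numeric(), ppm = numeric(), score = numeric(),
      matched = integer(), total = integer(),
      reference_standard = logical(), rt_match = logical())
  }

  ref_hit <- candidates$reference_standard & candidates$rt_match &
    candidates$matched >= 1L
  confidence <- if (any(ref_hit)) {
    "identified_reference"
  } else if (nrow(candidates) > 0L &&
             candidates$score[1] >= config$score_threshold) {
    "library_matched"
  } else if (sap$label != "none" || mal > 0L) {
    "class_characterized"
  } else {
    "unknown"
  }

  top <- if (nrow(candidates) > 0L) candidates[1, ] else NULL
  class_call <- if (!is.null(top) &&
                    confidence %in% c("identified_reference", "library_matched")) {
    top$class
  } else if (sap$label != "none") {
    sapogenin_class_hint(sap$label)
  } else {
    NA_character_
  }
  tied_top <- if (!is.null(top)) {
    candidates[candidates$score == top$score, ]
  } else candidates

  tibble::tibble(
    spectrum_id = spectrum$spectrum_id[[1]],
    rt_min = spectrum$rt_min[[1]],
    precursor_mz = precursor,
    polarity = polarity,
    adduct = if (!is.null(top)) top$adduct else base_add,
    neutral_mass = if (!is.null(top)) top$neutral_mass else {
      neutral_mass_from_mz(precursor, base_add)
    },
    formula = if (!is.null(top)) top$formula else NA_character_,
    class = class_call,
    subclass = if (!is.null(top) && !is.na(class_call) &&
                   identical(class_call, top$class)) top$subclass
               else if (sap$label != "none") sap$label
               else NA_character_,
    top_id = if (!is.null(top)) top$id else NA_character_,
    candidate_names = paste(tied_top$name, collapse = "; "),
    score = if (!is.null(top)) top$score else NA_real_,
    ppm_error = if (!is.null(top)) top$ppm else NA_real_,
    matched_fragments = if (!is.null(top)) top$matched else 0L,
    sapogenin = sap$label,
    malonyl_count = mal,
    sugar_composition = format_sugar_composition(glycan$sugars),
    glycan_resolved = glycan$terminal_resolved,
    confidence = confidence,
    candidates = list(candidates)
  )
}

empty_annotation_tbl <- function() {
  tibble::tibble(
    spectrum_id = character(), rt_min = numeric(), precursor_mz = numeric(),
    polarity = character(), adduct = character(), neutral_mass = numeric(),
    formula = character(), class = character(), subclass = character(),
    top_id = character(), candidate_names = character(), score = numeric(),
    ppm_error = numeric(), matched_fragments = integer(),
    sapogenin = character(), malonyl_count = integer(),
    sugar_composition = character(), glycan_resolved = logical(),
    confidence = character(), candidates = list()
  )
}

#' Annotate a set of spectra
#'
#' Applies [annotate_spectrum()] to every row of a spectra tibble.
#'
#' @param spectra A spectra tibble (e.g. from [read_mgf()] or
#'   [simulate_dda()]).
#' @param library A compound library tibble.
#' @param config An [annotation_config()].
#' @return An annotation tibble of class `ms_annotations`, one row per
#'   spectrum, with per-candidate detail in the `candidates` list-column.
#' @examples
#' lib <- four_herb_library()
#' sp <- theoretical_spectrum(lib[lib$id == "noto_r1", ], "negative")
#' annotate_spectra(sp, lib)
#' @export
annotate_spectra <- function(spectra, library,
                             config = annotation_config()) {
  rows <- purrr::map(seq_len(nrow(spectra)), function(i) {
    annotate_spectrum(spectra[i, ], library, config)
  })
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    empty_annotation_tbl()
  }
  class(out) <- c("ms_annotations", class(out))
  out
}

#' Class distribution of annotated components
#'
#' Counts non-`unknown` annotations per compound class and converts to
#' percentages (rounded to 2 decimal places; the rounded shares sum to 100
#' within 0.1).
#'
#' @param results A data frame with `class` and `confidence` columns (an
#'   annotation tibble, or any tally of characterized components).
#' @return A tibble with `class`, `n`, `percent`, sorted by descending
#'   count.
#' @export
summarize_classes <- function(results) {
  if (nrow(results) == 0L) {
    return(tibble::tibble(class = character(), n = integer(),
                          percent = numeric()))
  }
  keep <- dplyr::filter(results, .data$confidence != "unknown",
                        !is.na(.data$class))
  if (nrow(keep) == 0L) {
    return(tibble::tibble(class = character(), n = integer(),
                          percent = numeric()))
  }
  out <- dplyr::count(keep, .data$class, sort = TRUE)
  dplyr::mutate(out, percent = round(100 * .data$n / sum(.data$n), 2))
}
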