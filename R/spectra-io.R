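# Spectrum container and exchange formats. A set of MS2 spectra is a
# tibble with one row per spectrum and a `peaks` list-column of
# tibble(mz, intensity), so acquisition metadata stay alongside the peak
# lists and the whole set pipes through dplyr verbs.

#' Construct a spectra tibble
#'
#' @param spectrum_id Character ids, unique per spectrum.
#' @param polarity `"negative"` or `"positive"` (recycled).
#' @param precursor_mz Precursor m/z values.
#' @param rt_min Retention times in minutes.
#' @param peaks List of data frames with columns `mz`, `intensity`; each is
#'   sorted ascending in m/z on construction.
#' @param precursor_intensity Optional precursor intensities.
#' @param ccs Optional collision cross sections (pass-through metadata).
#' @return A spectra tibble.
#' @export
spectra_tbl <- function(spectrum_id, polarity, precursor_mz, rt_min, peaks,
                        precursor_intensity = NA_real_, ccs = NA_real_) {
  stopifnot(all(polarity %in% c("negative", "positive")))
  peaks <- purrr::map(peaks, normalize_peaks)
  tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    polarity = polarity,
    precursor_mz = as.numeric(precursor_mz),
    rt_min = as.numeric(rt_min),
    precursor_intensity = as.numeric(precursor_intensity),
    ccs = as.numeric(ccs),
    peaks = peaks
  )
}

normalize_peaks <- function(p) {
  p <- tibble::as_tibble(p)
  stopifnot(all(c("mz", "intensity") %in% names(p)))
  p <- p[, c("mz", "intensity")]
  if (nrow(p) > 0L) {
    if (any(!is.finite(p$mz)) || any(!is.finite(p$intensity))) {
      stop("non-finite peak values", call. = FALSE)
    }
    if (any(p$mz <= 0) || any(p$intensity < 0)) {
      stop("peak m/z must be > 0 and intensity >= 0", call. = FALSE)
    }
    p <- p[order(p$mz), ]
  }
  p
}

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks: `PEPMASS` becomes the precursor
#' m/z (a second value, when present, the precursor intensity),
#' `RTINSECONDS` is converted to minutes, and the sign of `CHARGE` sets the
#' polarity (negative assumed when absent, the primary acquisition mode for
#' glycoside-rich extracts). Peaks are returned sorted ascending in m/z.
#'
#' @param path Path to an MGF file.
#' @return A spectra tibble (see [spectra_tbl()]).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  rows <- purrr::map(seq_along(begin), function(b) {
    block <- lines[(begin[b] + 1L):(end[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_header <- grepl("^[A-Z][A-Z0-9_]*=", block)
    headers <- block[is_header]
    keys <- sub("=.*$", "", headers)
    vals <- sub("^[^=]*=", "", headers)
    header <- stats::setNames(vals, keys)
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("MGF block %d has no PEPMASS", b), call. = FALSE)
    }
    pep <- strsplit(trimws(header[["PEPMASS"]]), "\\s+")[[1]]
    precursor_mz <- as.numeric(pep[1])
    precursor_intensity <- if (length(pep) > 1L) as.numeric(pep[2]) else NA_real_
    rt_min <- if ("RTINSECONDS" %in% keys) {
      as.numeric(header[["RTINSECONDS"]]) / 60
    } else NA_real_
    polarity <- if ("CHARGE" %in% keys) {
      if (grepl("-", header[["CHARGE"]], fixed = TRUE)) "negative" else "positive"
    } else "negative"
    ccs <- if ("CCS" %in% keys) as.numeric(header[["CCS"]]) else NA_real_
    peak_lines <- block[!is_header]
    fields <- strsplit(trimws(peak_lines), "\\s+")
    if (any(vapply(fields, length, integer(1)) < 2L)) {
      stop(sprintf("MGF block %d: peak line with fewer than two fields", b),
           call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1)))
    intensity <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
    if (anyNA(mz) || anyNA(intensity)) {
      stop(sprintf("MGF block %d: non-numeric peak line", b), call. = FALSE)
    }
    title <- if ("TITLE" %in% keys) header[["TITLE"]] else sprintf("spectrum_%d", b)
    spectra_tbl(title, polarity, precursor_mz, rt_min,
                list(tibble::tibble(mz = mz, intensity = intensity)),
                precursor_intensity, ccs)
  })
  dplyr::bind_rows(rows)
}

#' Write spectra to an MGF file
#'
#' @param spectra A spectra tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::map_chr(seq_len(nrow(spectra)), function(i) {
    s <- spectra[i, ]
    header <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$spectrum_id),
      if (!is.na(s$precursor_intensity)) {
        sprintf("PEPMASS=%.6f %.4f", s$precursor_mz, s$precursor_intensity)
      } else sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (!is.na(s$rt_min)) sprintf("RTINSECONDS=%.4f", s$rt_min * 60),
      paste0("CHARGE=1", if (s$polarity == "negative") "-" else "+"),
      if (!is.na(s$ccs)) sprintf("CCS=%.2f", s$ccs)
    )
    p <- s$peaks[[1]]
    peak_lines <- sprintf("%.6f %.4f", p$mz, p$intensity)
    paste(c(header, peak_lines, "END IONS"), collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Write the tabular annotation report
#'
#' Tab-separated report with one row per spectrum and the twelve columns
#' `spectrum_id`, `rt_min`, `precursor_mz`, `adduct`, `formula`,
#' `neutral_mass`, `class`, `subclass`, `candidate_names`, `confidence`,
#' `ppm_error`, `matched_fragments`; m/z and mass columns are printed at 4
#' decimal places.
#'
#' @param results An annotation tibble from [annotate_spectra()] (an empty
#'   tibble writes a header-only file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(results, path) {
  cols <- c("spectrum_id", "rt_min", "precursor_mz", "adduct", "formula",
            "neutral_mass", "class", "subclass", "candidate_names",
            "confidence", "ppm_error", "matched_fragments")
  if (nrow(results) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- dplyr::select(results, dplyr::all_of(cols))
  out <- dplyr::mutate(
    out,
    rt_min = sprintf("%.2f", .data$rt_min),
    precursor_mz = sprintf("%.4f", .data$precursor_mz),
    neutral_mass = ifelse(is.na(.data$neutral_mass), "",
                          sprintf("%.4f", .data$neutral_mass)),
    ppm_error = ifelse(is.na(.data$ppm_error), "",
                       sprintf("%.2f", .data$ppm_error))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
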