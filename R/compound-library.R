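# Compound library: validated tibble of library records, CSV/JSON I/O,
# the packaged four-herb fixture library, and accurate-mass queries.

.LIBRARY_CLASSES <- c("ginsenoside", "astragaloside", "phenolic_acid",
                      "tanshinone", "flavonoid", "iridoid", "phenylpropanoid",
                      "other")
.GINSENOSIDE_SUBCLASSES <- c("PPD", "PPT", "OA", "OT", "malonyl", "other")
.SOURCE_HERBS <- c("NRR", "SMRR", "AR", "SR", "unknown")
.REQUIRED_COLUMNS <- c("id", "name", "formula", "class")

#' Parse a sugar-composition string
#'
#' Compositions are written `"Glc:2;Pen:1"`: semicolon-separated
#' `sugar:count` pairs over the sugar losses of [neutral_losses()].
#'
#' @param x A single composition string (may be `NA` or empty).
#' @return A named integer vector of sugar counts (empty when none).
#' @export
parse_sugar_composition <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(integer(0))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*([A-Za-z]+)\\s*:\\s*([0-9]+)\\s*$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("malformed sugar composition '%s'", x), call. = FALSE)
  }
  sugars <- vapply(m, `[[`, character(1), 2)
  counts <- as.integer(vapply(m, `[[`, character(1), 3))
  known <- neutral_losses(role = "sugar")$name
  unknown <- setdiff(sugars, known)
  if (length(unknown) > 0L) {
    stop("unknown sugar(s) in composition: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(counts, sugars)
}

#' Serialize a sugar multiset back to its string form
#'
#' @param counts Named integer vector as returned by
#'   [parse_sugar_composition()].
#' @return A string like `"Glc:2;Pen:1"` (empty string for an empty multiset).
#' @export
format_sugar_composition <- function(counts) {
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) return("")
  counts <- counts[order(names(counts))]
  paste0(names(counts), ":", counts, collapse = ";")
}

# Fill optional columns with defaults and coerce types.
normalize_library_columns <- function(tbl) {
  defaults <- list(
    subclass = NA_character_, source_herb = "unknown", aglycone = NA_character_,
    sugar_composition = NA_character_, loss_sequence = NA_character_,
    malonyl = 0L, acetyl = 0L, expected_rt = NA_real_,
    reference_standard = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(tbl)) tbl[[col]] <- defaults[[col]]
  }
  tbl$malonyl <- as.integer(tidyr::replace_na(tbl$malonyl, 0L))
  tbl$acetyl <- as.integer(tidyr::replace_na(tbl$acetyl, 0L))
  tbl$reference_standard <- as.logical(tidyr::replace_na(tbl$reference_standard, FALSE))
  tbl$expected_rt <- as.numeric(tbl$expected_rt)
  tbl$source_herb <- tidyr::replace_na(as.character(tbl$source_herb), "unknown")
  tbl
}

#' Validate a compound-library tibble
#'
#' Checks the schema (id/name/formula/class present), the closed class and
#' source-herb vocabularies, ginsenoside subclasses, id uniqueness, formula
#' parseability (reported with the offending row number), and - when both a
#' sugar composition and an aglycone are given - that aglycone plus sugar
#' residues plus acyl groups reconcile with the molecular formula to 1e-3
#' Da. Adds a `neutral_mass` column.
#'
#' @param tbl A data frame of compound records.
#' @return The validated library as a tibble, with `neutral_mass` in Da.
#' @export
validate_library <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  missing <- setdiff(.REQUIRED_COLUMNS, names(tbl))
  if (length(missing) > 0L) {
    stop("library is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- normalize_library_columns(tbl)
  if (anyDuplicated(tbl$id)) {
    stop("duplicate record ids: ",
         paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(tbl$class), .LIBRARY_CLASSES)
  if (length(bad_class) > 0L) {
    stop("unknown compound class(es): ", paste(bad_class, collapse = ", "),
         "; allowed: ", paste(.LIBRARY_CLASSES, collapse = ", "), call. = FALSE)
  }
  bad_herb <- setdiff(unique(tbl$source_herb), .SOURCE_HERBS)
  if (length(bad_herb) > 0L) {
    stop("unknown source herb(s): ", paste(bad_herb, collapse = ", "),
         call. = FALSE)
  }
  gins <- tbl$class == "ginsenoside"
  bad_sub <- setdiff(unique(tbl$subclass[gins]), .GINSENOSIDE_SUBCLASSES)
  bad_sub <- bad_sub[!is.na(bad_sub)]
  if (length(bad_sub) > 0L) {
    stop("unknown ginsenoside subclass(es): ", paste(bad_sub, collapse = ", "),
         call. = FALSE)
  }
  tbl$neutral_mass <- vapply(seq_len(nrow(tbl)), function(i) {
    tryCatch(formula_mass(tbl$formula[i]), error = function(e) {
      stop(sprintf("row %d (id '%s'): %s", i, tbl$id[i], conditionMessage(e)),
           call. = FALSE)
    })
  }, numeric(1))
  # glycoside arithmetic: aglycone + dehydrated residues + acyls == formula
  sap <- sapogenins()
  for (i in seq_len(nrow(tbl))) {
    agl <- tbl$aglycone[i]
    comp <- parse_sugar_composition(tbl$sugar_composition[i])
    if (!is.na(agl) && nzchar(agl) && length(comp) > 0L) {
      if (!agl %in% sap$label) {
        stop(sprintf("row %d (id '%s'): unknown aglycone '%s'", i, tbl$id[i], agl),
             call. = FALSE)
      }
      expected <- sap$mass[sap$label == agl] +
        sum(loss_mass(names(comp)) * comp) +
        tbl$malonyl[i] * loss_mass("malonyl") +
        tbl$acetyl[i] * loss_mass("acetyl")
      if (abs(expected - tbl$neutral_mass[i]) > 1e-3) {
        stop(sprintf(
          "row %d (id '%s'): sugar composition + aglycone (%.4f Da) does not match formula %s (%.4f Da)",
          i, tbl$id[i], expected, tbl$formula[i], tbl$neutral_mass[i]),
          call. = FALSE)
      }
    }
  }
  tbl
}

#' Read a compound library from CSV or JSON
#'
#' The CSV dialect is UTF-8 with a header row; sugar compositions are
#' written `"Glc:2;Pen:1"`. A JSON file holding an array of records with
#' identical field names is accepted interchangeably.
#'
#' @param path Path to a `.csv` or `.json` library file.
#' @return A validated library tibble (see [validate_library()]).
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tbl <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    stop("unsupported library format '", ext, "' (use .csv or .json)",
         call. = FALSE)
  )
  validate_library(tbl)
}

#' Write a compound library to CSV or JSON
#'
#' @param library A library tibble.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return The input, invisibly.
#' @export
write_compound_library <- function(library, path) {
  out <- dplyr::select(library, -dplyr::any_of("neutral_mass"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::write_csv(out, path, progress = FALSE),
    json = jsonlite::write_json(out, path, digits = NA, pretty = TRUE, na = "null"),
    stop("unsupported library format '", ext, "'", call. = FALSE)
  )
  invisible(library)
}

#' Built-in four-herb reference library
#'
#' A 43-record library of compounds reported from a four-herb cardiovascular
#' formula combining notoginseng (NRR), danshen (SMRR), astragalus (AR) and
#' figwort (SR) roots: ginsenosides (PPT/PPD/OA and malonylated),
#' astragalosides and a soyasaponin, salvianolic acids, tanshinones,
#' isoflavones, iridoid glycosides and phenylpropanoids, plus two free
#' sapogenins. Formulas follow the published record for each compound (the
#' cryptotanshinone entry keeps its reported formula C19H12O3, which
#' differs from the common literature formula). Retention times are given
#' where published; for compounds known only from the knockout-window
#' listing they are synthetic placements inside the corresponding windows.
#'
#' @return A validated library tibble.
#' @examples
#' lib <- four_herb_library()
#' dplyr::count(lib, class)
#' @export
four_herb_library <- function() {
  path <- system.file("extdata", "four_herb_library.csv", package = "ladderms")
  read_compound_library(path)
}

#' Query library records by neutral mass
#'
#' Returns exactly the records whose neutral monoisotopic mass lies within
#' a closed ppm window of the query mass, sorted by absolute ppm error and
#' then id (so isomer ties are deterministic). Isomers are distinct records
#' and are never collapsed.
#'
#' @param library A library tibble.
#' @param mass Query neutral mass in Da.
#' @param tolerance_ppm Half-width of the closed match window (default 10).
#' @param class Optional class filter.
#' @return Matching records with a `ppm` column.
#' @examples
#' query_by_neutral_mass(four_herb_library(), 932.5345, 10)
#' @export
query_by_neutral_mass <- function(library, mass, tolerance_ppm = 10,
                                  class = NULL) {
  stopifnot(tolerance_ppm > 0, mass > 0)
  out <- library
  if (!is.null(class)) {
    out <- dplyr::filter(out, .data$class == .env$class)
  }
  out <- dplyr::mutate(out, ppm = ppm_error(.env$mass, .data$neutral_mass))
  # closed interval; tiny slack keeps exact-edge queries inside despite
  # floating-point rounding
  out <- dplyr::filter(out, abs(.data$ppm) <= .env$tolerance_ppm + 1e-9)
  dplyr::arrange(out, abs(.data$ppm), .data$id)
}
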