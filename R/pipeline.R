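# End-to-end orchestration: annotate an MGF against a library, or run the
# simulate -> annotate -> evaluate chain, writing the tabular reports and
# a JSON manifest that makes the run reproducible.

run_manifest <- function(inputs, config_list, out_dir, extra = list()) {
  digests <- purrr::map_chr(inputs, function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  })
  manifest <- c(list(
    tool = "ladderms",
    version = as.character(utils::packageVersion("ladderms")),
    inputs = as.list(digests),
    config = config_list
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Annotate an MGF file and write the report files
#'
#' Reads MS2 spectra from an MGF file, annotates them against a compound
#' library, and writes `annotations.tsv` (see [write_annotation_table()]),
#' `class_summary.tsv` and `manifest.json` into the output directory. An
#' empty MGF yields header-only outputs with a warning.
#'
#' @param mgf Path to the input MGF file.
#' @param library_path Path to a CSV/JSON library, or `NULL` to use the
#'   built-in [four_herb_library()].
#' @param out_dir Output directory (created if needed).
#' @param config An [annotation_config()].
#' @return The annotation tibble, invisibly.
#' @export
run_annotation <- function(mgf, library_path = NULL, out_dir,
                           config = annotation_config()) {
  library <- if (is.null(library_path)) four_herb_library() else {
    read_compound_library(library_path)
  }
  spectra <- read_mgf(mgf)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(spectra) == 0L) {
    warning("no spectra in ", mgf, "; writing empty outputs", call. = FALSE)
    results <- annotate_spectra(spectra_tbl(character(0), character(0),
                                            numeric(0), numeric(0), list()),
                                library, config)
  } else {
    results <- annotate_spectra(spectra, library, config)
  }
  write_annotation_table(results, file.path(out_dir, "annotations.tsv"))
  readr::write_tsv(summarize_classes(results),
                   file.path(out_dir, "class_summary.tsv"), progress = FALSE)
  run_manifest(list(mgf = mgf, library = library_path),
               unclass(config), out_dir,
               list(n_spectra = nrow(spectra), builtin_library = is.null(library_path)))
  invisible(results)
}

#' Simulate, annotate and evaluate a DDA run, writing all artifacts
#'
#' Runs the full chain on a random mixture drawn from the library (or a
#' supplied mixture), writes the acquired MS2 spectra as MGF, the
#' ground-truth manifest as JSON, the trigger log as CSV and a recovery
#' report as JSON. When knockout windows are given the report includes the
#' with/without-knockout comparison at the requested load factor.
#'
#' @param library_path Path to a CSV/JSON library, or `NULL` for the
#'   built-in library.
#' @param n_components Mixture size when drawing randomly (ignored when
#'   `mixture` is supplied).
#' @param seed Integer seed (mandatory).
#' @param windows Optional knockout windows tibble or path to a JSON list
#'   of `{start_min, end_min}` objects.
#' @param out_dir Output directory.
#' @param mixture Optional explicit mixture tibble; `NULL` draws one with
#'   [generate_mixture()].
#' @param dda_cfg A [dda_config()].
#' @param annotation_cfg An [annotation_config()].
#' @param load_factor Load factor for the knockout injection (default
#'   50/3).
#' @return A list with the run(s), annotations and recovery metrics,
#'   invisibly.
#' @export
run_simulation <- function(library_path = NULL, n_components = 20, seed,
                           windows = NULL, out_dir, mixture = NULL,
                           dda_cfg = dda_config(),
                           annotation_cfg = annotation_config(),
                           load_factor = 50 / 3) {
  if (missing(seed)) stop("seed is mandatory for simulation", call. = FALSE)
  library <- if (is.null(library_path)) four_herb_library() else {
    read_compound_library(library_path)
  }
  if (is.character(windows)) {
    windows <- tibble::as_tibble(jsonlite::fromJSON(windows))
  }
  windows <- validate_knockout_windows(windows)
  if (is.null(mixture)) {
    mixture <- generate_mixture(library, n_components, seed = seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  run <- simulate_dda(mixture, library, dda_cfg, windows = windows, seed = seed)
  ann <- annotate_spectra(run$spectra, library, annotation_cfg)
  rec <- evaluate_recovery(ann, run)
  write_mgf(run$spectra, file.path(out_dir, "acquired.mgf"))
  readr::write_csv(run$trigger_log, file.path(out_dir, "trigger_log.csv"),
                   progress = FALSE)
  jsonlite::write_json(mixture, file.path(out_dir, "ground_truth.json"),
                       digits = NA, pretty = TRUE)
  write_annotation_table(ann, file.path(out_dir, "annotations.tsv"))

  report <- list(
    n_ground_truth = rec$n_ground_truth, n_triggered = rec$n_triggered,
    n_annotated_correct = rec$n_annotated_correct,
    precision = rec$precision, recall = rec$recall
  )
  comparison <- NULL
  if (!is.null(windows) && nrow(windows) > 0L) {
    comparison <- run_knockout_comparison(
      mixture = mixture, library = library, windows = windows,
      config = dda_cfg, load_factor = load_factor, seed = seed,
      annotation_cfg = annotation_cfg)
    report$knockout_comparison <- list(
      baseline_correct = comparison$baseline$recovery$n_annotated_correct,
      knockout_correct = comparison$knockout$recovery$n_annotated_correct,
      gained = length(comparison$gained_ids),
      load_factor = load_factor
    )
  }
  jsonlite::write_json(report, file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_manifest(list(library = library_path), unclass(dda_cfg), out_dir,
               list(seed = seed, n_components = nrow(mixture),
                    knockout = !is.null(windows) && nrow(windows) > 0L))
  invisible(list(run = run, annotations = ann, recovery = rec,
                 comparison = comparison))
}
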