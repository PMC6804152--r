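# Synthetic acquisition: ground-truth mixtures with Gaussian elution,
# rule-derived MS2 spectra, top-N data-dependent triggering, and eluate
# "knockout" windows that divert chromatographic regions to waste.

#' DDA acquisition configuration
#'
#' Defaults follow a QTOF survey method for herbal extracts: MS1 at 0.3 s
#' per scan over m/z 80-1500, MS2 triggered for the five most intense
#' precursors above 1000 detector counts, each MS2 stopping when its TIC
#' budget (2000 counts) is met or after 1.5 s. Dynamic exclusion (6 s,
#' settable to 0) prevents re-triggering the same apex.
#'
#' @param top_n MS2 events per MS1 scan (default 5).
#' @param trigger_threshold Minimum precursor intensity in counts (1000).
#' @param ms2_stop_tic MS2 TIC stop criterion in counts (2000).
#' @param ms2_max_time_s MS2 time budget in seconds (1.5).
#' @param ms1_scan_time_s MS1 scan time in seconds (0.3).
#' @param mass_range Acquired m/z range (c(80, 1500)).
#' @param exclusion_s Dynamic exclusion window in seconds (6).
#' @return A list of class `dda_config`.
#' @export
dda_config <- function(top_n = 5, trigger_threshold = 1000,
                       ms2_stop_tic = 2000, ms2_max_time_s = 1.5,
                       ms1_scan_time_s = 0.3, mass_range = c(80, 1500),
                       exclusion_s = 6) {
  stopifnot(top_n >= 0, trigger_threshold > 0, ms2_stop_tic > 0,
            ms2_max_time_s > 0, ms1_scan_time_s > 0,
            length(mass_range) == 2L, mass_range[1] < mass_range[2],
            exclusion_s >= 0)
  structure(list(top_n = as.integer(top_n),
                 trigger_threshold = trigger_threshold,
                 ms2_stop_tic = ms2_stop_tic,
                 ms2_max_time_s = ms2_max_time_s,
                 ms1_scan_time_s = ms1_scan_time_s,
                 mass_range = mass_range, exclusion_s = exclusion_s),
            class = "dda_config")
}

#' Knockout window table
#'
#' Time windows whose eluate is diverted to waste: all MS1 signal inside a
#' window is zeroed, emulating the physical switching valve.
#'
#' @param start_min,end_min Numeric vectors of window bounds in minutes.
#' @return A tibble with `start_min`, `end_min`; windows must be
#'   non-overlapping with `0 <= start < end`.
#' @export
knockout_windows <- function(start_min, end_min) {
  stopifnot(length(start_min) == length(end_min))
  tbl <- tibble::tibble(start_min = as.numeric(start_min),
                        end_min = as.numeric(end_min))
  validate_knockout_windows(tbl)
}

validate_knockout_windows <- function(tbl) {
  if (is.null(tbl) || nrow(tbl) == 0L) return(tbl)
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("start_min", "end_min") %in% names(tbl)))
  if (any(tbl$start_min < 0) || any(tbl$end_min <= tbl$start_min)) {
    stop("knockout windows need 0 <= start < end", call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$start_min)
  if (nrow(tbl) > 1L &&
      any(tbl$start_min[-1] < tbl$end_min[-nrow(tbl)])) {
    stop("knockout windows may not overlap", call. = FALSE)
  }
  tbl
}

in_windows <- function(t, windows) {
  if (is.null(windows) || nrow(windows) == 0L) return(FALSE)
  any(t >= windows$start_min & t < windows$end_min)
}

#' Draw a random ground-truth mixture from a library
#'
#' Components get log-uniform abundances spanning the requested dynamic
#' range (herbal extracts span orders of magnitude in content) and uniform
#' retention times over the gradient; elution peaks are Gaussian with a
#' common width.
#'
#' @param library A compound library tibble.
#' @param n_components Number of components to draw (without replacement).
#' @param dynamic_range_log10 Log10 span of abundances (default 3).
#' @param seed Integer seed; the draw is reproducible.
#' @param rt_range Retention-time range in minutes (default c(0.5, 29.5)).
#' @param peak_sigma Gaussian elution sigma in minutes (default 0.05).
#' @param max_abundance Apex intensity of the most abundant component in
#'   detector counts (default 1e6).
#' @return A mixture tibble: `id`, `rt`, `abundance`, `sigma`.
#' @export
generate_mixture <- function(library, n_components, dynamic_range_log10 = 3,
                             seed, rt_range = c(0.5, 29.5),
                             peak_sigma = 0.05, max_abundance = 1e6) {
  stopifnot(dynamic_range_log10 >= 0, n_components >= 1)
  if (n_components > nrow(library)) {
    stop("n_components exceeds library size", call. = FALSE)
  }
  withr::local_seed(seed)
  ids <- sample(library$id, n_components)
  tibble::tibble(
    id = ids,
    rt = stats::runif(n_components, rt_range[1], rt_range[2]),
    abundance = max_abundance * 10^(-stats::runif(n_components, 0,
                                                  dynamic_range_log10)),
    sigma = peak_sigma
  )
}

# Per-kind base intensities of the rule-derived fragment profile.
.FRAGMENT_INTENSITY <- c(precursor = 1000, base = 900, acyl = 500,
                         ladder = 600, diagnostic = 300, class = 400)

#' Rule-derived MS2 spectrum of a library record
#'
#' Builds the theoretical fragment set of the record (see
#' [theoretical_fragments()]) with a fixed intensity profile (precursor
#' 1000 counts, ladder nodes decaying geometrically, diagnostics weaker),
#' optionally adds uniform noise peaks below 10% of the base intensity,
#' and restricts all peaks to the acquired mass range.
#'
#' @param record A one-row library tibble.
#' @param polarity `"negative"` or `"positive"`.
#' @param adduct Precursor adduct (default: (de)protonated molecule).
#' @param noise_peaks Number of random noise peaks (default 0).
#' @param seed Seed for the noise draw (required when `noise_peaks > 0`).
#' @param config A [dda_config()] providing the mass range.
#' @return A one-row spectra tibble with an extra `precursor_only` column
#'   flagging records with no derivable fragment rules.
#' @export
theoretical_spectrum <- function(record, polarity = "negative", adduct = NULL,
                                 noise_peaks = 0, seed = NULL,
                                 config = dda_config()) {
  stopifnot(nrow(record) == 1L)
  th <- theoretical_fragments(record, polarity, adduct)
  derivable <- attr(th, "derivable")
  intensity <- .FRAGMENT_INTENSITY[th$kind]
  ladder_idx <- which(th$kind == "ladder")
  if (length(ladder_idx) > 0L) {
    intensity[ladder_idx] <- .FRAGMENT_INTENSITY[["ladder"]] *
      0.85^(seq_along(ladder_idx) - 1)
  }
  peaks <- tibble::tibble(mz = th$mz, intensity = unname(intensity))
  if (noise_peaks > 0L) {
    if (is.null(seed)) stop("seed is required when noise_peaks > 0", call. = FALSE)
    withr::local_seed(seed)
    noise <- tibble::tibble(
      mz = stats::runif(noise_peaks, config$mass_range[1], config$mass_range[2]),
      intensity = stats::runif(noise_peaks, 0, 0.1 * max(peaks$intensity))
    )
    peaks <- dplyr::bind_rows(peaks, noise)
  }
  peaks <- dplyr::filter(peaks, .data$mz >= config$mass_range[1],
                         .data$mz <= config$mass_range[2])
  out <- spectra_tbl(record$id, polarity,
                     th$mz[th$kind == "precursor"],
                     record$expected_rt, list(peaks))
  out$precursor_only <- !derivable
  out
}

#' Simulate a DDA run over a ground-truth mixture
#'
#' MS1 intensity per component is its abundance scaled by a Gaussian
#' elution profile, zeroed while a knockout window is active. At each MS1
#' scan, the `top_n` components above the trigger threshold and outside
#' dynamic exclusion trigger MS2 acquisition of their rule-derived
#' spectrum; every trigger decision is logged. MS2 acquisition time
#' shortens for intense precursors (the TIC stop criterion), and elapsed
#' MS2 time delays subsequent MS1 scans, so acquisition-time competition
#' is part of the model.
#'
#' @param mixture A mixture tibble from [generate_mixture()] (columns
#'   `id`, `rt`, `abundance`, `sigma`).
#' @param library A compound library tibble containing every mixture id.
#' @param config A [dda_config()].
#' @param windows Optional knockout window tibble (see
#'   [knockout_windows()]).
#' @param polarity Acquisition polarity (default `"negative"`).
#' @param noise_peaks Noise peaks per MS2 spectrum (default 0).
#' @param seed Integer seed; the run is reproducible byte-for-byte.
#' @param load_factor Multiplies all abundances, expressing on-column load
#'   (concentration times injection volume) relative to the reference
#'   injection (default 1).
#' @return A list of class `dda_run`: `spectra` (acquired MS2 spectra with
#'   their `source_id`), `trigger_log`, `mixture` (with the load factor
#'   applied), `config`, `windows`, `polarity`, `seed`.
#' @export
simulate_dda <- function(mixture, library, config = dda_config(),
                         windows = NULL, polarity = "negative",
                         noise_peaks = 0, seed = 1, load_factor = 1) {
  windows <- validate_knockout_windows(windows)
  stopifnot(all(mixture$abundance > 0), all(mixture$sigma > 0))
  missing <- setdiff(mixture$id, library$id)
  if (length(missing) > 0L) {
    stop("mixture ids absent from library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  withr::local_seed(seed)
  mixture <- dplyr::mutate(mixture, abundance = .data$abundance * load_factor)
  recs <- library[match(mixture$id, library$id), ]
  precursor_mz <- mz_from_adduct(recs$neutral_mass, base_adduct_for(polarity))
  run_end <- max(mixture$rt + 4 * mixture$sigma)
  last_trigger <- stats::setNames(rep(-Inf, nrow(mixture)), mixture$id)

  spectra <- list(); log_rows <- list()
  t <- 0; scan <- 0L
  while (t <= run_end) {
    scan <- scan + 1L
    knocked <- in_windows(t, windows)
    raw <- mixture$abundance * exp(-((t - mixture$rt)^2) / (2 * mixture$sigma^2))
    signal <- if (knocked) rep(0, length(raw)) else raw
    eligible <- signal >= config$trigger_threshold &
      (t - last_trigger[mixture$id]) * 60 >= config$exclusion_s
    ord <- order(-signal, precursor_mz)
    picked <- ord[eligible[ord]][seq_len(min(config$top_n, sum(eligible)))]
    ms2_time <- 0
    for (i in picked) {
      ms2 <- theoretical_spectrum(recs[i, ], polarity,
                                  noise_peaks = noise_peaks,
                                  seed = if (noise_peaks > 0)
                                    sample.int(.Machine$integer.max, 1)
                                  else NULL,
                                  config = config)
      ms2$spectrum_id <- sprintf("scan%05d_%s", scan, mixture$id[i])
      ms2$rt_min <- t
      ms2$precursor_intensity <- signal[i]
      ms2$peaks[[1]]$intensity <- ms2$peaks[[1]]$intensity * signal[i] / 1000
      ms2$source_id <- mixture$id[i]
      spectra[[length(spectra) + 1L]] <- ms2
      last_trigger[mixture$id[i]] <- t
      ms2_time <- ms2_time +
        config$ms2_max_time_s * min(1, config$ms2_stop_tic / signal[i])
    }
    interesting <- raw >= config$trigger_threshold
    if (any(interesting)) {
      decision <- dplyr::case_when(
        seq_along(raw) %in% picked ~ "triggered",
        knocked ~ "knocked_out",
        !eligible ~ "excluded",
        TRUE ~ "outcompeted"
      )
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        scan = scan, time_min = t, id = mixture$id[interesting],
        precursor_mz = precursor_mz[interesting],
        intensity = signal[interesting],
        decision = decision[interesting]
      )
    }
    t <- t + (config$ms1_scan_time_s + ms2_time) / 60
  }
  structure(list(
    spectra = if (length(spectra) > 0L) dplyr::bind_rows(spectra) else {
      dplyr::mutate(spectra_tbl(character(0), character(0), numeric(0),
                                numeric(0), list()),
                    precursor_only = logical(0), source_id = character(0))
    },
    trigger_log = if (length(log_rows) > 0L) dplyr::bind_rows(log_rows) else {
      tibble::tibble(scan = integer(), time_min = numeric(), id = character(),
                     precursor_mz = numeric(), intensity = numeric(),
                     decision = character())
    },
    mixture = mixture, config = config, windows = windows,
    polarity = polarity, seed = seed
  ), class = "dda_run")
}

#' @export
print.dda_run <- function(x, ...) {
  cat(sprintf("<dda_run> %d components, %d MS2 spectra, %d knockout window(s)\n",
              nrow(x$mixture), nrow(x$spectra),
              if (is.null(x$windows)) 0L else nrow(x$windows)))
  invisible(x)
}

#' On-column load of an injection
#'
#' Load scales as concentration times injection volume, so a 10 mg/mL, 5
#' uL injection carries 16.7-fold the load of a 1 mg/mL, 3 uL one.
#'
#' @param concentration_mg_ml Sample concentration in mg/mL.
#' @param volume_ul Injection volume in uL.
#' @return On-column load in ug.
#' @examples
#' on_column_load(10, 5) / on_column_load(1, 3) # 16.7
#' @export
on_column_load <- function(concentration_mg_ml, volume_ul) {
  stopifnot(concentration_mg_ml > 0, volume_ul > 0)
  concentration_mg_ml * volume_ul
}
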