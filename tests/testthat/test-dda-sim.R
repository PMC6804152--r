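# mixture generation, theoretical spectra, DDA triggering, knockout,
# recovery metrics

lib <- four_herb_library()

test_that("mixture draws respect the dynamic range and seed", {
  m <- generate_mixture(lib, 10, 3, seed = 1)
  expect_equal(nrow(m), 10L)
  expect_lte(max(m$abundance) / min(m$abundance), 1000)
  expect_identical(m, generate_mixture(lib, 10, 3, seed = 1))
  # degenerate range: all abundances equal
  flat <- generate_mixture(lib, 10, 0, seed = 1)
  expect_equal(length(unique(flat$abundance)), 1L)
  expect_error(generate_mixture(lib, 1000, 3, seed = 1), "exceeds library")
})

test_that("theoretical spectra reproduce published fragment ladders", {
  salb <- theoretical_spectrum(lib_record(lib, "sal_b"), "negative")
  expect_true(all(c(717.146, 519.093, 321.040) %in%
                    round(salb$peaks[[1]]$mz, 3)))
  form <- theoretical_spectrum(lib_record(lib, "formononetin"), "positive")
  expect_true(all(c(269.081, 253.050, 237.055) %in%
                    round(form$peaks[[1]]$mz, 3)))
  expect_false(salb$precursor_only)
})

test_that("theoretical spectra are deterministic without noise and in-range", {
  a <- theoretical_spectrum(lib_record(lib, "ro"), "negative")
  b <- theoretical_spectrum(lib_record(lib, "ro"), "negative")
  expect_identical(a, b)
  noisy <- theoretical_spectrum(lib_record(lib, "ro"), "negative",
                                noise_peaks = 10, seed = 3)
  expect_equal(nrow(noisy$peaks[[1]]), nrow(a$peaks[[1]]) + 10)
  rng <- dda_config()$mass_range
  expect_true(all(noisy$peaks[[1]]$mz >= rng[1] &
                    noisy$peaks[[1]]$mz <= rng[2]))
  expect_error(theoretical_spectrum(lib_record(lib, "ro"), "negative",
                                    noise_peaks = 5), "seed")
  # a record with no fragment rules is flagged precursor-only
  tan_neg <- theoretical_spectrum(lib_record(lib, "tan_iia"), "negative")
  expect_true(tan_neg$precursor_only)
})

test_that("a lone component above threshold triggers at its apex", {
  mix <- tibble::tibble(id = "noto_r1", rt = 2.0, abundance = 5e4,
                        sigma = 0.05)
  run <- simulate_dda(mix, lib, seed = 1)
  expect_gt(nrow(run$spectra), 0L)
  trig <- dplyr::filter(run$trigger_log, decision == "triggered")
  expect_true(any(abs(trig$time_min - 2.0) < 0.1))
  # a knockout window over its elution silences it completely
  ko <- simulate_dda(mix, lib, windows = knockout_windows(1.5, 2.5), seed = 1)
  expect_equal(nrow(ko$spectra), 0L)
  expect_true(all(ko$trigger_log$decision == "knocked_out"))
})

test_that("top-N selection takes the most intense eligible precursors", {
  # six co-eluting components, one per intensity rank; top_n = 2
  ids <- c("noto_r1", "rg1", "rb1", "ro", "sal_b", "harpagoside")
  mix <- tibble::tibble(id = ids, rt = 5, abundance = c(6:1) * 1e4,
                        sigma = 0.5)
  cfg <- dda_config(top_n = 2, exclusion_s = 1e6)
  run <- simulate_dda(mix, lib, cfg, seed = 1)
  trig <- dplyr::filter(run$trigger_log, decision == "triggered")
  first_trigger <- dplyr::summarise(dplyr::group_by(trig, id),
                                    t = min(time_min), .groups = "drop")
  first_trigger <- first_trigger[match(ids, first_trigger$id), ]
  # more abundant components cross the threshold (and so trigger) earlier
  expect_true(all(diff(first_trigger$t) >= 0))
  # with a long exclusion the slots move down the abundance order
  expect_gt(dplyr::n_distinct(run$spectra$source_id), 2L)
})

test_that("dynamic exclusion suppresses immediate re-triggering", {
  mix <- tibble::tibble(id = "rb1", rt = 2, abundance = 1e6, sigma = 0.2)
  no_excl <- simulate_dda(mix, lib, dda_config(exclusion_s = 0), seed = 1)
  excl <- simulate_dda(mix, lib, dda_config(exclusion_s = 30), seed = 1)
  expect_gt(nrow(no_excl$spectra), nrow(excl$spectra))
})

test_that("top_n = 0 acquires no MS2 and recall is 0", {
  mix <- tibble::tibble(id = "rb1", rt = 2, abundance = 1e6, sigma = 0.1)
  run <- simulate_dda(mix, lib, dda_config(top_n = 0), seed = 1)
  expect_equal(nrow(run$spectra), 0L)
  ann <- annotate_spectra(run$spectra, lib)
  rec <- evaluate_recovery(ann, run)
  expect_equal(rec$recall, 0)
  expect_false(rec$precision_defined)
  expect_equal(rec$precision, 0)
})

test_that("the simulate-annotate-evaluate chain is seed-reproducible", {
  mix <- generate_mixture(lib, 8, 2, seed = 5, rt_range = c(1, 4))
  one <- function() {
    run <- simulate_dda(mix, lib, noise_peaks = 3, seed = 9)
    ann <- annotate_spectra(run$spectra, lib)
    evaluate_recovery(ann, run)
  }
  a <- one(); b <- one()
  expect_identical(glance(a), glance(b))
  expect_identical(a$correct_ids, b$correct_ids)
})

test_that("recovery metrics follow their definitions", {
  mix <- tibble::tibble(id = c("noto_r1", "sal_b"), rt = c(2, 3),
                        abundance = c(5e4, 5e4), sigma = 0.05)
  run <- simulate_dda(mix, lib, seed = 1)
  ann <- annotate_spectra(run$spectra, lib)
  rec <- evaluate_recovery(ann, run)
  expect_equal(rec$recall, 1)
  expect_equal(rec$precision, 1)
  expect_equal(rec$n_ground_truth, 2L)
  expect_true(all(rec$decile_recall$recall %in% c(0, 1)))
})

test_that("overlapping or inverted knockout windows are rejected", {
  expect_error(knockout_windows(c(1, 1.5), c(2, 2.5)), "overlap")
  expect_error(knockout_windows(2, 1), "start < end")
  expect_silent(knockout_windows(c(5.5, 6.2, 11, 13.8),
                                 c(5.8, 6.5, 11.5, 14.1)))
})

test_that("on-column load reproduces the published injection factor", {
  expect_equal(round(on_column_load(10, 5) / on_column_load(1, 3), 1), 16.7)
})

test_that("knockout of a dominant apex exposes shadowed minors", {
  cmp <- run_knockout_comparison(seed = 1)
  base_ids <- cmp$baseline$recovery$correct_ids
  ko_ids <- cmp$knockout$recovery$correct_ids
  expect_gt(length(ko_ids), length(base_ids))
  expect_gt(length(cmp$gained_ids), 0L)
  # the gained components are minors, not the knocked-out dominant
  expect_false("rb1" %in% cmp$gained_ids)
})

test_that("windows covering only the dominant apex never lose minors", {
  # time-separated construction: the window covers the dominant apex only,
  # minors elute later; the triggered minor set with knockout contains the
  # set without
  minors <- c("noto_r1", "sal_b", "harpagoside", "ast_iv")
  mix <- dplyr::bind_rows(
    tibble::tibble(id = "rb1", rt = 2.0, abundance = 5e5, sigma = 0.05),
    tibble::tibble(id = minors, rt = c(3.0, 3.2, 3.4, 3.6),
                   abundance = 5e3, sigma = 0.05))
  win <- knockout_windows(1.8, 2.2)
  base <- simulate_dda(mix, lib, seed = 1)
  ko <- simulate_dda(mix, lib, windows = win, seed = 1)
  base_minors <- intersect(unique(base$spectra$source_id), minors)
  ko_minors <- intersect(unique(ko$spectra$source_id), minors)
  expect_true(all(base_minors %in% ko_minors))
  expect_false("rb1" %in% unique(ko$spectra$source_id))
})
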