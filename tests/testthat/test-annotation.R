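# adduct hypotheses, candidate scoring, full per-spectrum annotation

lib <- four_herb_library()

test_that("adduct hypotheses cover deprotonated and formate precursors", {
  fa <- hypothesize_adducts(977.5327, "negative", lib)
  expect_true(any(fa$id == "noto_r1" & fa$adduct == "[M+HCOO]-"))
  deprot <- hypothesize_adducts(931.527, "negative", lib)
  expect_true(any(deprot$id == "noto_r1" & deprot$adduct == "[M-H]-"))
  # polarity gate: same m/z finds nothing in positive mode
  expect_equal(nrow(hypothesize_adducts(931.527, "positive", lib)), 0L)
})

test_that("theoretical fragments reproduce published non-saponin ladders", {
  salb <- theoretical_fragments(lib_record(lib, "sal_b"), "negative")
  expect_equal(round(sort(salb$mz[salb$kind != "precursor"]), 3),
               c(321.040, 519.093))
  expect_equal(round(salb$mz[salb$kind == "precursor"], 2), 717.15)
  form <- theoretical_fragments(lib_record(lib, "formononetin"), "positive")
  expect_true(all(round(c(269.081, 253.050, 237.055), 3) %in%
                    round(form$mz, 3)))
  tan <- theoretical_fragments(lib_record(lib, "tan_iia"), "positive")
  expect_equal(round(tan$mz[tan$kind == "precursor"], 2), 295.13)
})

test_that("scoring rewards the true ladder and floors at precursor-only", {
  sp <- theoretical_spectrum(lib_record(lib, "noto_r1"), "negative")
  true_score <- score_candidate(lib_record(lib, "noto_r1"), sp, "[M-H]-")
  expect_equal(true_score$score, 1.0)
  # a PPD record of equal nominal mass scores strictly lower
  wrong <- lib_record(lib, "rd")
  wrong_score <- score_candidate(wrong, sp, "[M-H]-")
  expect_lt(wrong_score$score, true_score$score)
  # empty MS2 falls to the 0.1 floor
  empty <- make_spectrum(numeric(0), precursor_mz = 931.5272)
  expect_equal(score_candidate(lib_record(lib, "noto_r1"), empty,
                               "[M-H]-")$score, 0.1)
})

test_that("adding a matching theoretical fragment never lowers the score", {
  rec <- lib_record(lib, "noto_r1")
  th <- theoretical_fragments(rec, "negative")
  frag_mz <- th$mz[th$kind != "precursor"]
  peaks <- make_peaks(frag_mz[1])
  prev <- score_candidate(rec, peaks, "[M-H]-")$score
  for (k in seq_along(frag_mz)[-1]) {
    cur <- score_candidate(rec, make_peaks(frag_mz[1:k]), "[M-H]-")$score
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 1.0)
})

test_that("a reference-standard match with rt and fragments is identified", {
  sp <- theoretical_spectrum(lib_record(lib, "noto_r1"), "negative")
  sp$rt_min <- 5.74
  res <- annotate_spectrum(sp, lib)
  expect_identical(res$confidence, "identified_reference")
  expect_identical(res$top_id, "noto_r1")
  expect_identical(res$sapogenin, "PPT")
  expect_identical(res$sugar_composition, "Glc:2;Pen:1")
  # same spectrum without a matching rt drops to library_matched
  sp$rt_min <- 20
  expect_identical(annotate_spectrum(sp, lib)$confidence, "library_matched")
})

test_that("isomeric candidates are all reported, tied at identical score", {
  # an OA saponin one pentose heavier than the Glc2-GlurA core compound
  sp <- theoretical_spectrum(lib_record(lib, "stip_r2"), "negative")
  res <- annotate_spectrum(sp, lib)
  expect_identical(res$top_id, "stip_r2")
  expect_identical(res$sapogenin, "OA_GlurA")
  # the seven-way isomer family ties exactly
  sp59 <- theoretical_spectrum(lib_record(lib, "re1"), "negative")
  res59 <- annotate_spectrum(sp59, lib)
  cands <- res59$candidates[[1]]
  top <- cands[cands$score == cands$score[1], ]
  expect_gte(nrow(top), 7)
  expect_true(all(c("re1", "re2", "re3", "noto_r3", "noto_r6", "noto_m",
                    "chik_lm4") %in% top$id))
  expect_match(res59$candidate_names, "; ")
})

test_that("random noise annotates as unknown", {
  sp <- make_spectrum(c(101.3, 222.2, 333.3), precursor_mz = 645.21)
  res <- annotate_spectrum(sp, lib)
  expect_identical(res$confidence, "unknown")
  expect_true(is.na(res$top_id))
})

test_that("sapogenin diagnostics without a library hit give a class call", {
  # PPD diagnostics at a mass absent from the library
  sp <- make_spectrum(c(459.383, 375.290), precursor_mz = 1500.9)
  res <- annotate_spectrum(sp, lib)
  expect_identical(res$confidence, "class_characterized")
  expect_identical(res$class, "ginsenoside")
})

test_that("annotation is deterministic for identical inputs", {
  sp <- theoretical_spectrum(lib_record(lib, "mal_rb1"), "negative")
  a <- annotate_spectra(sp, lib)
  b <- annotate_spectra(sp, lib)
  expect_identical(a, b)
  expect_equal(a$malonyl_count, 1L)
})

test_that("class summary reproduces share arithmetic", {
  counts <- c(ginsenoside = 155, astragaloside = 6, phenolic_acid = 16,
              tanshinone = 16, flavonoid = 13, iridoid = 6,
              phenylpropanoid = 10, other = 8)
  results <- tibble::tibble(class = rep(names(counts), counts),
                            confidence = "library_matched")
  s <- summarize_classes(results)
  expect_equal(sum(s$n), 230)
  expect_equal(s$percent[s$class == "ginsenoside"], 67.39)
  expect_lte(abs(sum(s$percent) - 100), 0.1)
  # uniform case and empty input
  u <- summarize_classes(tibble::tibble(
    class = rep(c("a", "b", "c", "d", "e"), 2), confidence = "library_matched"))
  expect_true(all(u$percent == 20))
  expect_equal(nrow(summarize_classes(results[0, ])), 0L)
})
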