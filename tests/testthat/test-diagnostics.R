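# diagnostic sapogenin classing, malonyl detection, glycan inference

test_that("diagnostic table reproduces the published 2-dp ion values", {
  d <- diagnostic_ions()
  val <- function(label, kind) round(d$mz[d$label == label & d$kind == kind], 2)
  expect_equal(val("PPT", "primary"), 475.38)
  expect_equal(val("PPT", "corroboration"), 391.29)
  expect_equal(val("PPD", "primary"), 459.38)
  expect_equal(val("PPD", "corroboration"), 375.29)
  expect_equal(val("OA", "primary"), 455.35)
  expect_setequal(val("OA_GlurA", "corroboration"), c(569.38, 523.38))
  expect_equal(val("cycloastragenol", "primary"), 489.36)
  expect_equal(val("soyasapogenol", "primary"), 457.37)
})

test_that("sapogenin cores are called from their diagnostic ions", {
  expect_identical(
    classify_sapogenin(make_peaks(c(475.379, 391.285)), "negative")$label,
    "PPT")
  expect_identical(
    classify_sapogenin(make_peaks(c(459.383, 375.290)), "negative")$label,
    "PPD")
  expect_identical(
    classify_sapogenin(make_peaks(c(455.353, 569.385, 523.379)),
                       "negative")$label,
    "OA_GlurA")
  expect_identical(
    classify_sapogenin(make_peaks(455.353), "negative")$label, "OA")
  expect_identical(
    classify_sapogenin(make_peaks(c(489.358, 383.29)), "negative")$label,
    "cycloastragenol")
  expect_identical(
    classify_sapogenin(make_peaks(457.369), "negative")$label,
    "soyasapogenol")
})

test_that("positive mode, misses and ties all yield none", {
  expect_identical(
    classify_sapogenin(make_peaks(c(475.379, 391.285)), "positive")$label,
    "none")
  expect_identical(classify_sapogenin(make_peaks(100.0), "negative")$label,
                   "none")
  # corroboration without the primary ion is not enough
  expect_identical(classify_sapogenin(make_peaks(391.285), "negative")$label,
                   "none")
  # PPT and PPD primaries together, equal evidence: unresolved tie
  tie <- classify_sapogenin(make_peaks(c(475.379, 459.383)), "negative")
  expect_identical(tie$label, "none")
  expect_setequal(tie$candidates, c("PPT", "PPD"))
})

test_that("malonyl counts follow the CO2 / whole-group losses", {
  node <- mz_from_adduct(formula_mass("C57H94O26"), "[M-H]-")
  expect_equal(round(node - loss_mass("CO2"), 3), 1149.606)
  expect_equal(round(node - loss_mass("malonyl"), 3), 1107.596)
  expect_equal(detect_malonyl(make_peaks(c(1149.606, 1107.595)), node), 1L)
  expect_equal(detect_malonyl(make_peaks(c(500, 600)), node), 0L)
  # dimalonyl from the double whole-group loss alone
  expect_equal(detect_malonyl(make_peaks(node - 172.0008), node), 2L)
  expect_equal(detect_malonyl(make_peaks(node - 2 * loss_mass("CO2")), node), 2L)
})

test_that("glycan inference reads sugars off the sapogenin-terminated chain", {
  start <- mz_from_adduct(formula_mass("C47H80O18"), "[M-H]-")
  nodes <- start - cumsum(loss_mass(c("Glc", "Pen", "Glc")))
  sp <- make_peaks(c(start, nodes, 391.2854))
  paths <- find_loss_paths(sp, start)
  sap <- classify_sapogenin(sp, "negative")
  expect_identical(sap$label, "PPT")
  g <- infer_glycan_composition(paths, sap)
  expect_equal(g$sugars, c(Glc = 2L, Pen = 1L))
  expect_true(g$terminal_resolved)
})

test_that("glycan inference handles empty chains and off-node terminals", {
  sap_none <- classify_sapogenin(make_peaks(100), "negative")
  empty <- infer_glycan_composition(find_loss_paths(make_peaks(100), 900)[0, ],
                                    sap_none)
  expect_equal(empty$sugars, integer(0))
  expect_false(empty$terminal_resolved)

  # two chains: a short one ending on the PPT node wins over a longer one
  # ending off-node
  start <- 1000
  ppt <- diagnostic_ions()
  ppt <- ppt$mz[ppt$label == "PPT" & ppt$kind == "primary"]
  sp <- make_peaks(c(start - loss_mass("Glc"),
                     start - loss_mass("Glc") - loss_mass("Glc"),
                     start - loss_mass("H2O"), start - loss_mass("H2O") - loss_mass("CO2"),
                     start - loss_mass("H2O") - loss_mass("CO2") - loss_mass("CO")))
  paths <- find_loss_paths(sp, start)
  fake_sap <- structure(list(label = "PPT",
                             matched = tibble::tibble(), candidates = character(0)),
                        class = "sapogenin_call")
  g <- infer_glycan_composition(paths, fake_sap)
  # nothing ends on the PPT node: falls back to nearest terminal above it
  expect_false(g$terminal_resolved)
  expect_gte(g$terminal_mz, ppt - 0.02)
})

test_that("glycan tie-breaks are deterministic: depth, sugar count, name", {
  paths <- tibble::tibble(
    losses = list(c("Glc", "H2O"), c("Glc", "Glc"), c("Rha", "Glc")),
    node_mz = list(1, 1, 1), matched_mz = list(1, 1, 1), ppm = list(0, 0, 0),
    terminal_mz = c(500, 500, 500), depth = c(2L, 2L, 2L),
    truncated = FALSE)
  sap_none <- structure(list(label = "none", matched = tibble::tibble(),
                             candidates = character(0)),
                        class = "sapogenin_call")
  g <- infer_glycan_composition(paths, sap_none)
  # equal depth; "Glc;Glc" has the most sugar losses and wins; between the
  # two all-sugar chains "Glc;Glc" sorts before "Rha;Glc"
  expect_equal(g$sugars, c(Glc = 2L))
})
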