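# library model, fixture content, I/O round trips, accurate-mass queries

test_that("builtin library is complete and internally consistent", {
  lib <- four_herb_library()
  expect_gte(nrow(lib), 30)
  expect_setequal(unique(lib$class),
                  c("ginsenoside", "astragaloside", "phenolic_acid",
                    "tanshinone", "flavonoid", "iridoid", "phenylpropanoid",
                    "other"))
  expect_false(anyDuplicated(lib$id) > 0)
  # neutral masses equal the formula-derived masses
  expect_equal(lib$neutral_mass, formula_mass(lib$formula), tolerance = 1e-9)
})

test_that("builtin library records match their published identities", {
  lib <- four_herb_library()
  r1 <- lib[lib$name == "Notoginsenoside R1", ]
  expect_identical(r1$formula, "C47H80O18")
  expect_identical(r1$class, "ginsenoside")
  expect_identical(r1$subclass, "PPT")
  expect_identical(r1$source_herb, "NRR")
  harp <- lib[lib$name == "Harpagoside", ]
  expect_identical(harp$formula, "C24H30O11")
  expect_identical(harp$class, "iridoid")
  expect_identical(harp$source_herb, "SR")
  soy <- lib[lib$name == "Soyasaponin I", ]
  expect_identical(soy$formula, "C48H78O18")
  expect_identical(soy$subclass, "soyasaponin")
  expect_identical(soy$source_herb, "AR")
})

test_that("schema and vocabulary violations are rejected with row context", {
  base <- tibble::tibble(id = "x", name = "X", formula = "C6H12O6",
                         class = "ginsenoside", subclass = "PPT")
  expect_error(validate_library(dplyr::select(base, -formula)),
               "missing required column")
  expect_error(validate_library(dplyr::mutate(base, class = "saponinX")),
               "unknown compound class")
  expect_error(validate_library(dplyr::mutate(base, formula = "NotAFormula")),
               "row 1")
  expect_error(validate_library(dplyr::bind_rows(base, base)), "duplicate")
  expect_error(validate_library(dplyr::mutate(base, subclass = "weird")),
               "subclass")
})

test_that("sugar composition must reconcile with the formula", {
  bad <- tibble::tibble(id = "x", name = "X", formula = "C47H80O18",
                        class = "ginsenoside", subclass = "PPT",
                        aglycone = "PPT", sugar_composition = "Glc:3")
  expect_error(validate_library(bad), "does not match formula")
  good <- dplyr::mutate(bad, sugar_composition = "Glc:2;Pen:1")
  expect_silent(validate_library(good))
})

test_that("sugar composition strings round-trip", {
  expect_equal(parse_sugar_composition("Glc:2;Pen:1"),
               c(Glc = 2L, Pen = 1L))
  expect_identical(format_sugar_composition(c(Pen = 1L, Glc = 2L)),
                   "Glc:2;Pen:1")
  expect_equal(parse_sugar_composition(NA_character_), integer(0))
  expect_error(parse_sugar_composition("Glc:two"), "malformed")
  expect_error(parse_sugar_composition("Fru:1"), "unknown sugar")
})

test_that("library round-trips through CSV and JSON field-for-field", {
  lib <- four_herb_library()
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_compound_library(lib, path)
    back <- read_compound_library(path)
    expect_equal(as.data.frame(back), as.data.frame(lib))
  }
})

test_that("mass query returns records in a closed ppm window, sorted", {
  lib <- four_herb_library()
  hits <- query_by_neutral_mass(lib, 932.5345, 10)
  expect_true("noto_r1" %in% hits$id)
  expect_equal(nrow(query_by_neutral_mass(lib, 932.60, 10)), 0L)
  # boundary: a query exactly +10 ppm away is still included
  m <- lib$neutral_mass[lib$id == "noto_r1"]
  edge <- m * (1 + 10e-6)
  expect_true("noto_r1" %in% query_by_neutral_mass(lib, edge, 10)$id)
  # isomers are all returned, ordered by |ppm| then id
  iso <- query_by_neutral_mass(lib, formula_mass("C48H82O19"), 10)
  expect_gte(nrow(iso), 7)
  expect_identical(iso$id, iso$id[order(abs(iso$ppm), iso$id)])
  # class filter
  expect_equal(nrow(query_by_neutral_mass(lib, 932.5345, 10,
                                          class = "tanshinone")), 0L)
})

test_that("query equals a brute-force linear scan over random draws", {
  lib <- four_herb_library()
  set.seed(7)
  for (i in 1:1000) {
    mass <- runif(1, 100, 1300)
    tol <- runif(1, 1, 500)
    got <- query_by_neutral_mass(lib, mass, tol)$id
    want <- lib$id[abs(1e6 * (mass - lib$neutral_mass) / lib$neutral_mass) <= tol]
    expect_setequal(got, want)
  }
})
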