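# Packaged registries: ESI adducts, the neutral-loss vocabulary, and the
# diagnostic sapogenin ion table. Adducts and losses ship as JSON under
# inst/extdata so the tables can be printed and extended from the CLI.

.registry_cache <- new.env(parent = emptyenv())

read_registry <- function(which) {
  if (!exists(which, envir = .registry_cache)) {
    path <- system.file("extdata", paste0(which, ".json"), package = "ladderms")
    if (!nzchar(path)) stop("registry file not found: ", which, call. = FALSE)
    assign(which, tibble::as_tibble(jsonlite::fromJSON(path)),
           envir = .registry_cache)
  }
  get(which, envir = .registry_cache)
}

#' ESI adduct registry
#'
#' The adduct set used for accurate-mass library search: deprotonation,
#' formate, acetate, chloride and electron attachment in negative mode;
#' protonation, sodiation and electron loss in positive mode. All deltas are
#' signed mass shifts in Da including the electron mass, all species are
#' singly charged.
#'
#' @param polarity Optional filter, `"negative"` or `"positive"`.
#' @return A tibble with columns `name`, `polarity`, `delta`, `charge`.
#' @examples
#' adducts("negative")
#' @export
adducts <- function(polarity = NULL) {
  tbl <- read_registry("adducts")
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("negative", "positive"))
    tbl <- dplyr::filter(tbl, .data$polarity == .env$polarity)
  }
  tbl
}

# Resolve one adduct name to its registry row (as a list).
adduct_spec <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  tbl <- read_registry("adducts")
  row <- tbl[tbl$name == name, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown adduct '%s'; see adducts() for the registry", name),
         call. = FALSE)
  }
  as.list(row)
}

#' Neutral-loss vocabulary
#'
#' The neutral losses recognised by the ladder search: glycosidic residues
#' (Glc 162.05, Rha 146.06, GlurA 176.03, and the generic pentose Pen
#' 132.04 standing for Xyl/Ara), acyl groups (malonyl C3H2O3, acetyl),
#' small molecules (H2O, CO2, CO, HCOOH, CH4, CH3OH and the methyl radical,
#' kept in the vocabulary for positive-mode rules), the C6H12 side-chain
#' fragment of dammarane sapogenins, and phenolic acid units (danshensu,
#' caffeoyl, feruloyl).
#'
#' @param role Optional filter: one of `"sugar"`, `"acyl"`, `"small"`,
#'   `"side-chain"`, `"acid-unit"`.
#' @return A tibble with columns `name`, `formula`, `mass`, `role`.
#' @examples
#' neutral_losses("sugar")
#' @export
neutral_losses <- function(role = NULL) {
  tbl <- read_registry("neutral_losses")
  if (!is.null(role)) {
    role <- match.arg(role, unique(tbl$role))
    tbl <- dplyr::filter(tbl, .data$role == .env$role)
  }
  tbl
}

#' Mass of a named neutral loss
#'
#' @param name Loss name(s) from [neutral_losses()].
#' @return Monoisotopic mass(es) in Da.
#' @export
loss_mass <- function(name) {
  tbl <- read_registry("neutral_losses")
  idx <- match(name, tbl$name)
  if (anyNA(idx)) {
    stop("unknown neutral loss: ", paste(name[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  tbl$mass[idx]
}

# Sapogenin (aglycone) formulas used for diagnostics and for reconciling
# sugar compositions against molecular formulas.
.SAPOGENIN_FORMULA <- c(
  PPT             = "C30H52O4",  # protopanaxatriol
  PPD             = "C30H52O3",  # protopanaxadiol
  OA              = "C30H48O3",  # oleanolic acid
  cycloastragenol = "C30H50O5",
  soyasapogenol   = "C30H50O3"   # soyasapogenol B
)

#' Sapogenin aglycone table
#'
#' @return A tibble with the aglycone label, formula and neutral
#'   monoisotopic mass for the sapogenin cores recognised by the
#'   diagnostic-ion rules.
#' @export
sapogenins <- function() {
  tibble::tibble(
    label = names(.SAPOGENIN_FORMULA),
    formula = unname(.SAPOGENIN_FORMULA),
    mass = formula_mass(unname(.SAPOGENIN_FORMULA))
  )
}

#' Diagnostic product-ion table for negative-mode saponin classing
#'
#' Deprotonated sapogenin ions and their corroborating fragments, all
#' derived from aglycone formulas: m/z 475.38/391.29 for protopanaxatriol
#' (PPT), 459.38/375.29 for protopanaxadiol (PPD, side-chain loss of C6H12
#' in both cases), 455.35 for oleanolic acid (OA), the decarboxylation pair
#' 569.38/523.38 diagnostic of OA saponins bearing 3-O-glucuronic acid,
#' 489.36/383.29 for cycloastragenol and 457.37 for soyasapogenol. The
#' 383.29 furan-ring rearrangement ion has no assignable elemental loss and
#' is stored at its reported 2-dp value.
#'
#' @return A tibble with columns `label`, `mz`, `kind`
#'   (`"primary"`/`"corroboration"`).
#' @export
diagnostic_ions <- function() {
  sap <- sapogenins()
  m <- stats::setNames(sap$mass, sap$label)
  deprot <- function(mass) mz_from_adduct(mass, "[M-H]-")
  c6h12 <- loss_mass("C6H12")
  # OA-GlurA core: [OA + GlurA - H]- after H2O + CO2 (and further HCOOH) loss
  oa_glura <- deprot(m[["OA"]] + loss_mass("GlurA"))
  tibble::tribble(
    ~label,            ~mz,                                             ~kind,
    "PPT",             deprot(m[["PPT"]]),                              "primary",
    "PPT",             deprot(m[["PPT"]]) - c6h12,                      "corroboration",
    "PPD",             deprot(m[["PPD"]]),                              "primary",
    "PPD",             deprot(m[["PPD"]]) - c6h12,                      "corroboration",
    "OA",              deprot(m[["OA"]]),                               "primary",
    "OA_GlurA",        deprot(m[["OA"]]),                               "primary",
    "OA_GlurA",        oa_glura - loss_mass("H2O") - loss_mass("CO2"),  "corroboration",
    "OA_GlurA",        oa_glura - loss_mass("H2O") - loss_mass("CO2") - loss_mass("HCOOH"), "corroboration",
    "cycloastragenol", deprot(m[["cycloastragenol"]]),                  "primary",
    "cycloastragenol", 383.29,                                          "corroboration",
    "soyasapogenol",   deprot(m[["soyasapogenol"]]),                    "primary"
  )
}
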