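# Monoisotopic mass arithmetic: formula parsing, adduct m/z, ppm errors.
# Everything downstream (library search, ladder inference, the simulator)
# reduces to sums over this table, so the constants live in one place.

# Most-abundant-isotope masses (Da). C is exactly 12 by definition.
.ATOMIC_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  Cl = 34.96885268,
  P  = 30.97376163,
  Na = 22.9897692809
)

#' @keywords internal
.ELECTRON_MASS <- 5.48579909e-4

#' Parse a molecular formula into element counts
#'
#' Parses strict Hill-notation formulas such as `"C47H80O18"` into a named
#' integer vector of element counts. Isotope labels, charges and parentheses
#' are not supported: every formula used by the annotation rules fits the
#' plain element-count grammar.
#'
#' @param formula A single formula string, e.g. `"C47H80O18"` or `"H2O"`.
#' @return A named integer vector of counts in Hill order (C first, then H,
#'   then the remaining elements alphabetically). Elements absent from the
#'   formula are absent from the vector.
#' @examples
#' parse_formula("C47H80O18")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || !nzchar(formula)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  counts <- integer(0)
  pos <- 1L
  n <- nchar(formula)
  while (pos <= n) {
    rest <- substr(formula, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      stop(sprintf("malformed formula '%s': unexpected character at position %d",
                   formula, pos), call. = FALSE)
    }
    elem <- m[2]
    if (!elem %in% names(.ATOMIC_MASS)) {
      stop(sprintf("unsupported element '%s' in formula '%s'", elem, formula),
           call. = FALSE)
    }
    count <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (count < 0L || is.na(count)) {
      stop(sprintf("malformed count in formula '%s' at position %d", formula, pos),
           call. = FALSE)
    }
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + count
    pos <- pos + nchar(m[1])
  }
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    stop(sprintf("formula '%s' contains no atoms", formula), call. = FALSE)
  }
  hill_order(counts)
}

# Hill order: C, H, then alphabetical; without C, fully alphabetical.
hill_order <- function(counts) {
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  counts[ord]
}

#' Serialize element counts back to a Hill-notation formula
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A formula string; `format_formula(parse_formula(x))` is `x` for
#'   any Hill-ordered input.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts[counts > 0L])
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of an element-count vector
#'
#' Sum of count times most-abundant-isotope mass. Additive by construction:
#' the mass of a combined formula equals the sum of the parts.
#'
#' @param counts Named integer vector of element counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C6H10O5")) # glucosyl residue, 162.0528
#' @export
monoisotopic_mass <- function(counts) {
  if (length(counts) == 0L) stop("empty element counts", call. = FALSE)
  if (any(counts < 0L)) stop("negative element counts", call. = FALSE)
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop(sprintf("unsupported element(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  sum(.ATOMIC_MASS[names(counts)] * as.numeric(counts))
}

#' Monoisotopic mass of a formula string
#'
#' @param formula Formula string in Hill notation.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("C47H80O18")
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) monoisotopic_mass(parse_formula(f)), numeric(1),
         USE.NAMES = FALSE)
}

#' m/z of an adduct ion from a neutral mass
#'
#' Computes `(M + delta) / z` where `delta` is the signed adduct mass shift
#' (electron mass included, so the deprotonated delta is -1.007276 Da).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0). Vectorised.
#' @param adduct Adduct name, e.g. `"[M-H]-"`, `"[M+HCOO]-"`, `"[M+H]+"`.
#'   See [adducts()] for the registry.
#' @return m/z value(s).
#' @examples
#' mz_from_adduct(formula_mass("C47H80O18"), "[M-H]-") # 931.5272
#' @export
mz_from_adduct <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  spec <- adduct_spec(adduct)
  (neutral_mass + spec$delta) / spec$charge
}

#' Neutral mass from an adduct m/z
#'
#' Exact inverse of [mz_from_adduct()].
#'
#' @param mz Observed m/z (> 0). Vectorised.
#' @inheritParams mz_from_adduct
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct) {
  stopifnot(all(mz > 0))
  spec <- adduct_spec(adduct)
  mz * spec$charge - spec$delta
}

#' Mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(931.5365, 931.5272) # ~ +10 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
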