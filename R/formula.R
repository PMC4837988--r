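#' @importFrom stats rnorm rlnorm runif setNames
#' @importFrom utils combn read.delim write.table head
NULL

# Closed element set. Monoisotopic masses are the masses of the most abundant
# isotope (CODATA/IUPAC); nominal masses are integer mass numbers.
.ELEMENTS <- c("C", "H", "N", "Na", "O", "P")

.MONO_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  Na = 22.9897692809,
  O  = 15.9949146196,
  P  = 30.97376163
)

.NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, Na = 23L, O = 16L, P = 31L)

# Mass of the proton (charge carrier for (de)protonation).
.PROTON <- 1.00727646688

.WATER <- c(C = 0L, H = 2L, N = 0L, Na = 0L, O = 1L, P = 0L)

#' Build an element composition
#'
#' An element composition is a named integer vector holding counts of the
#' supported elements (C, H, N, Na, O, P). It is the unit of all mass
#' arithmetic in the package. Unmentioned elements get a zero count.
#'
#' @param ... element counts, e.g. `composition(C = 3, H = 7, N = 1, O = 2)`.
#' @return named integer vector over the full element set, class
#'   `"element_composition"`.
#' @examples
#' composition(C = 12, H = 22, O = 11) # diglucose
#' @export
composition <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) return(.empty_composition())
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all counts must be named by element symbol")
  bad <- setdiff(names(counts), .ELEMENTS)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  out <- .empty_composition()
  out[names(counts)] <- out[names(counts)] + as.integer(counts)
  out
}

.empty_composition <- function() {
  structure(setNames(integer(length(.ELEMENTS)), .ELEMENTS),
            class = "element_composition")
}

.as_comp <- function(x) {
  if (inherits(x, "element_composition")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(do.call(composition, as.list(x)))
  stop("cannot interpret object as an element composition")
}

#' Parse a Hill-notation molecular formula
#'
#' @param text formula string such as `"C3H7NO2"`. Only C, H, N, Na, O and P
#'   are supported; counts are optional positive integers.
#' @return an [composition()] vector.
#' @examples
#' parse_formula("C12H22O11")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) return(.empty_composition())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || any(!nzchar(tokens)))
    stop("malformed formula: ", text)
  out <- .empty_composition()
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% .ELEMENTS)
      stop("unsupported element '", sym, "' in formula ", text)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (is.na(n) || n <= 0) stop("malformed count in formula ", text)
    out[sym] <- out[sym] + n
  }
  out
}

#' Format a composition as a Hill string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' zero counts are dropped, unit counts are implicit. Round-trips with
#' [parse_formula()].
#'
#' @param comp an element composition (or formula string).
#' @return single character string.
#' @export
format_formula <- function(comp) {
  comp <- .as_comp(comp)
  ord <- c("C", "H", setdiff(sort(.ELEMENTS), c("C", "H")))
  parts <- vapply(ord, function(el) {
    n <- comp[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.element_composition <- function(x, ...) {
  cat("<element composition> ", format_formula(x),
      "  (", format(round(monoisotopic_mass(x), 4), nsmall = 4), " amu)\n",
      sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' @param comp element composition or Hill formula string.
#' @return mass in amu; 0 for the empty composition.
#' @examples
#' monoisotopic_mass("C3H7NO2") # alanine, 89.0477
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_comp(comp)
  sum(unclass(comp) * .MONO_MASS[names(comp)])
}

#' Nominal (integer) mass of a composition
#'
#' @inheritParams monoisotopic_mass
#' @return integer amu.
#' @examples
#' nominal_mass("H2O") # 18
#' @export
nominal_mass <- function(comp) {
  comp <- .as_comp(comp)
  as.integer(sum(unclass(comp) * .NOMINAL_MASS[names(comp)]))
}

.comp_add <- function(a, b) {
  out <- unclass(a) + unclass(b)
  structure(as.integer(out), names = names(a), class = "element_composition")
}

.comp_sub <- function(a, b) {
  out <- unclass(a) - unclass(b)
  structure(as.integer(out), names = names(a), class = "element_composition")
}

#' Condense two compositions
#'
#' Element-wise sum minus `n_bonds` waters, the arithmetic of ester,
#' glycosidic and phosphodiester bond formation.
#'
#' @param a,b element compositions or formula strings.
#' @param n_bonds number of condensation bonds formed (>= 1).
#' @return the condensed composition; errors if any element count would go
#'   negative.
#' @examples
#' condense("C6H12O6", "C6H12O6") # diglucose C12H22O11
#' @export
condense <- function(a, b, n_bonds = 1L) {
  stopifnot(n_bonds >= 1)
  a <- .as_comp(a); b <- .as_comp(b)
  out <- .comp_sub(.comp_add(a, b), composition(H = 2L * n_bonds, O = n_bonds))
  if (any(out < 0))
    stop("condensation would give a negative element count")
  out
}

#' m/z of an ion formed from a neutral composition
#'
#' Adduct conventions: sodiated cations add the mass of the sodium atom;
#' deprotonated anions subtract the proton mass (1.007276); the doubly
#' deprotonated dianion subtracts two protons and halves; protonated cations
#' add one proton. No electron-mass correction is applied to the sodiated
#' ion.
#'
#' @param neutral element composition or formula string of the neutral.
#' @param adduct one of `"sodiated_cation"`, `"deprotonated_anion"`,
#'   `"double_deprotonated_dianion"`, `"protonated_cation"`.
#' @return m/z in amu.
#' @examples
#' ion_mz("C3H7NO2", "deprotonated_anion") # [Ala - H]-
#' @export
ion_mz <- function(neutral,
                   adduct = c("sodiated_cation", "deprotonated_anion",
                              "double_deprotonated_dianion",
                              "protonated_cation")) {
  adduct <- match.arg(adduct)
  neutral <- .as_comp(neutral)
  m <- monoisotopic_mass(neutral)
  switch(adduct,
    sodiated_cation = m + .MONO_MASS[["Na"]],
    protonated_cation = m + .PROTON,
    deprotonated_anion = {
      if (neutral[["H"]] < 1)
        stop("cannot deprotonate a composition without hydrogen")
      m - .PROTON
    },
    double_deprotonated_dianion = {
      if (neutral[["H"]] < 2)
        stop("cannot doubly deprotonate: fewer than two hydrogens")
      (m - 2 * .PROTON) / 2
    }
  )
}
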