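# Monoisotopic atomic masses (IUPAC), Da. The proton mass is the mass of H+
# (hydrogen atom minus electron), not the hydrogen atom mass.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass constants used throughout the package
#'
#' Monoisotopic atomic masses (C, H, N, O, S), the proton mass, and the
#' formula of water, fixed at IUPAC values so that every m/z the package
#' reports is reproducible without an external table.
#'
#' @return A list with elements `atomic` (named numeric vector of
#'   monoisotopic masses in Da), `proton` (Da) and `water`
#'   (an [elemental_formula]).
#' @examples
#' mass_constants()$proton
#' @export
mass_constants <- function() {
  list(
    atomic = .ATOMIC_MASS,
    proton = 1.00727646688,
    water = elemental_formula(H = 2, O = 1)
  )
}

.PROTON_MASS <- 1.00727646688

#' Elemental formula
#'
#' Integer element counts over C, H, N, O, S. Non-negative counts describe a
#' molecule; signed counts describe a group delta (e.g. the replacement of an
#' N-acetyl by a fatty acyl chain). All structure and fragment masses in the
#' package reduce to arithmetic on these objects.
#'
#' @param C,H,N,O,S Integer element counts (may be negative for deltas).
#' @return An object of class `elemental_formula`: a named integer vector.
#' @examples
#' glcnac <- elemental_formula(C = 8, H = 13, N = 1, O = 5)
#' monoisotopic_mass(glcnac)
#' @export
elemental_formula <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  counts <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(counts != round(counts))) {
    stop("element counts must be integers", call. = FALSE)
  }
  structure(as.integer(round(counts)),
            names = names(counts), class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", formula_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Add two formulas (or apply a group delta)
#'
#' Element-wise sum. Commutative and associative with the empty formula as
#' identity. If `check_molecule = TRUE` a result with any negative count is an
#' error, since no molecule can contain a negative number of atoms.
#'
#' @param a,b `elemental_formula` objects; `b` may be a signed delta.
#' @param check_molecule Require the result to be a valid molecule.
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b, check_molecule = FALSE) {
  stopifnot(inherits(a, "elemental_formula"), inherits(b, "elemental_formula"))
  res <- structure(unclass(a) + unclass(b),
                   names = names(.ATOMIC_MASS), class = "elemental_formula")
  if (check_molecule && any(res < 0)) {
    stop("invalid composition: negative element count in ",
         formula_to_string(res), call. = FALSE)
  }
  res
}

#' Scale a formula by an integer multiplier
#' @param f An `elemental_formula`.
#' @param k Integer multiplier.
#' @return An `elemental_formula`.
#' @export
formula_multiply <- function(f, k) {
  stopifnot(inherits(f, "elemental_formula"), k == round(k))
  structure(unclass(f) * as.integer(k),
            names = names(.ATOMIC_MASS), class = "elemental_formula")
}

#' Monoisotopic mass of a molecule
#'
#' Sum of count times monoisotopic atomic mass over the elements. Additive:
#' `monoisotopic_mass(formula_add(a, b)) == monoisotopic_mass(a) +
#' monoisotopic_mass(b)`.
#'
#' @param f An `elemental_formula` with non-negative counts.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  if (any(unclass(f) < 0)) {
    stop("monoisotopic_mass requires a molecule (non-negative counts), got ",
         formula_to_string(f), call. = FALSE)
  }
  sum(unclass(f) * .ATOMIC_MASS)
}

#' m/z of the singly protonated adduct [M+H]+
#'
#' The charge state is fixed at +1 throughout the package: the LCO/CO
#' precursor ions observed on a triple quadrupole in positive mode are the
#' singly charged proton adducts.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da, > 0.
#' @return m/z of \eqn{[M+H]^+}.
#' @export
mz_protonated <- function(neutral_mass) {
  if (any(neutral_mass <= 0)) {
    stop("neutral mass must be positive", call. = FALSE)
  }
  neutral_mass + .PROTON_MASS
}

#' Nominal (unit-resolution) m/z
#'
#' Rounds half away from zero, reproducing the unit-resolution values a
#' quadrupole instrument reports (e.g. 628 for chitotriose \eqn{[M+H]^+}).
#'
#' @param mz Exact m/z, > 0.
#' @return Integer m/z.
#' @export
nominal_mz <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  as.integer(sign(mz) * floor(abs(mz) + 0.5))
}

#' Hill-order text serialization of a formula
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; elements
#' with zero count are omitted and a count of one is left implicit
#' (e.g. `"C24H41N3O16"`).
#'
#' @param f An `elemental_formula`.
#' @return A character scalar ("" for the empty formula).
#' @export
formula_to_string <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  counts <- unclass(f)
  ord <- c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  parts <- vapply(ord, function(el) {
    k <- counts[[el]]
    if (k == 0) return("")
    paste0(el, if (k != 1) k else "")
  }, character(1))
  paste0(parts, collapse = "")
}

#' Parse a Hill-order formula string
#'
#' Inverse of [formula_to_string()] for the supported elements
#' (C, H, N, O, S).
#'
#' @param x Character scalar such as `"C8H13NO5"`.
#' @return An `elemental_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x == "") return(elemental_formula())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  tokens <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  if (sum(nchar(tokens)) != nchar(x)) {
    stop("cannot parse formula string: ", x, call. = FALSE)
  }
  counts <- stats::setNames(rep(0L, length(.ATOMIC_MASS)), names(.ATOMIC_MASS))
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% names(counts)) {
      stop("unsupported element symbol: ", el, call. = FALSE)
    }
    num <- sub("^[A-Za-z]+", "", tok)
    counts[[el]] <- counts[[el]] + if (num == "") 1L else as.integer(num)
  }
  do.call(elemental_formula, as.list(counts))
}
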