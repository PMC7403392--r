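# In-chain (anhydro) N-acetylglucosamine residue: C8H13NO5.
.GLCNAC <- c(C = 8L, H = 13L, N = 1L, O = 5L)

.glcnac_formula <- function() {
  elemental_formula(C = 8, H = 13, N = 1, O = 5)
}

# Substituent library. Each delta is the net formula change of replacing one
# hydrogen with the group. `sites` restricts where a code may sit: the
# backbone's non-reducing terminal residue (R2-R4), the reducing terminal
# residue (R5-R6), or anywhere.
.SUBSTITUENTS <- list(
  H     = list(delta = elemental_formula(),                                sites = "any"),
  Me    = list(delta = elemental_formula(C = 1, H = 2),                    sites = "nonreducing"),
  Ac    = list(delta = elemental_formula(C = 2, H = 2, O = 1),             sites = "any"),
  Cb    = list(delta = elemental_formula(C = 1, H = 1, N = 1, O = 1),      sites = "nonreducing"),
  S     = list(delta = elemental_formula(S = 1, O = 3),                    sites = "reducing"),
  Fuc   = list(delta = elemental_formula(C = 6, H = 10, O = 4),            sites = "reducing"),
  MeFuc = list(delta = elemental_formula(C = 7, H = 12, O = 4),            sites = "reducing"),
  FucS  = list(delta = elemental_formula(C = 6, H = 10, O = 7, S = 1),     sites = "reducing")
)

# R2-R4 decorate the non-reducing terminal residue (which also carries the
# acyl chain at R1); R5-R6 decorate the reducing terminal residue.
.POSITION_SITE <- c(R2 = "nonreducing", R3 = "nonreducing", R4 = "nonreducing",
                    R5 = "reducing", R6 = "reducing")

#' Substituent codes and formula deltas
#'
#' The chemical substitutions found on lipo-chitooligosaccharides: hydrogen
#' (H, no change), N-methyl (Me), O-acetyl (Ac), carbamoyl (Cb), sulfate (S),
#' fucosyl (Fuc), methylfucosyl (MeFuc) and fucosyl sulfate (FucS). Each
#' entry's `delta` is the net elemental change of substituting one hydrogen.
#'
#' @return A data.frame with columns `code`, `formula_delta` (Hill string),
#'   `mass_delta` (Da) and `sites`.
#' @export
substituent_library <- function() {
  data.frame(
    code = names(.SUBSTITUENTS),
    formula_delta = vapply(.SUBSTITUENTS, function(s)
      formula_to_string(s$delta), character(1)),
    mass_delta = vapply(.SUBSTITUENTS, function(s)
      sum(unclass(s$delta) * .ATOMIC_MASS), numeric(1)),
    sites = vapply(.SUBSTITUENTS, `[[`, character(1), "sites"),
    row.names = NULL
  )
}

#' Fatty acyl chain
#'
#' The R1 fatty acid on the non-reducing terminal nitrogen of an LCO,
#' described by carbon count, number of double bonds, and number of hydroxyl
#' groups. Attaching the chain replaces the residue's N-acetyl group, so the
#' formula delta relative to a plain GlcNAc residue is
#' \eqn{-C_2H_2O + C_cH_{2c-2-2d}O_{1+h}}.
#'
#' @param carbons Chain length, integer >= 2.
#' @param double_bonds Number of C=C double bonds, integer >= 0 and
#'   <= carbons - 1.
#' @param hydroxyls Number of hydroxyl groups on the chain (default 0).
#' @return An object of class `acyl_chain`.
#' @examples
#' acyl_chain(16, 0)   # palmitoyl
#' acyl_chain(18, 1)   # oleoyl/vaccenoyl
#' @export
acyl_chain <- function(carbons, double_bonds = 0, hydroxyls = 0) {
  stopifnot(carbons == round(carbons), double_bonds == round(double_bonds),
            hydroxyls == round(hydroxyls))
  if (carbons < 2) stop("acyl chain needs at least 2 carbons", call. = FALSE)
  if (double_bonds < 0 || double_bonds > carbons - 1) {
    stop("double bond count must lie in [0, carbons - 1]", call. = FALSE)
  }
  if (hydroxyls < 0) stop("hydroxyl count must be >= 0", call. = FALSE)
  structure(list(carbons = as.integer(carbons),
                 double_bonds = as.integer(double_bonds),
                 hydroxyls = as.integer(hydroxyls)),
            class = "acyl_chain")
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl_chain> ", acyl_label(x), "\n", sep = "")
  invisible(x)
}

#' Display label of an acyl chain, e.g. "C16:0" or "C18:1-OH"
#' @param chain An `acyl_chain`.
#' @return Character scalar.
#' @export
acyl_label <- function(chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  lab <- sprintf("C%d:%d", chain$carbons, chain$double_bonds)
  if (chain$hydroxyls == 1L) lab <- paste0(lab, "-OH")
  if (chain$hydroxyls > 1L) lab <- paste0(lab, "-", chain$hydroxyls, "OH")
  lab
}

# Net delta of swapping the N-acetyl of a GlcNAc residue for this acyl chain.
acyl_delta <- function(chain) {
  c <- chain$carbons; d <- chain$double_bonds; h <- chain$hydroxyls
  group <- elemental_formula(C = c, H = 2 * c - 2 - 2 * d, O = 1 + h)
  formula_add(group, elemental_formula(C = -2, H = -2, O = -1))
}

#' Chitooligosaccharide structure
#'
#' An unmodified chitin oligomer of `n` beta-1,4-linked GlcNAc residues
#' (CO3-CO6 in the short-chain range). Formula: n x C8H13NO5 + H2O.
#'
#' @param n Number of GlcNAc residues, integer >= 2.
#' @return An object of classes `co_structure`, `chito_structure`.
#' @examples
#' precursor_mz(co_structure(3))   # 628.256
#' @export
co_structure <- function(n) {
  stopifnot(n == round(n))
  if (n < 2) stop("a chitooligosaccharide needs n >= 2 residues", call. = FALSE)
  structure(list(n = as.integer(n)),
            class = c("co_structure", "chito_structure"))
}

#' Lipo-chitooligosaccharide structure
#'
#' A chitin backbone of `n` GlcNAc residues whose non-reducing terminal
#' nitrogen carries a fatty acyl chain (R1) in place of the N-acetyl, with
#' optional substituents at positions R2-R4 (non-reducing terminal residue)
#' and R5-R6 (reducing terminal residue).
#'
#' @param n Backbone length, integer >= 2 (Nod factors have 3-5).
#' @param acyl An [acyl_chain()].
#' @param substituents Named character vector over positions R2-R6 with codes
#'   from [substituent_library()]; unnamed positions default to "H".
#' @return An object of classes `lco_structure`, `chito_structure`.
#' @examples
#' lco_structure(4, acyl_chain(16, 0), c(R6 = "S"))   # sulfated C16:0 LCO-IV
#' @export
lco_structure <- function(n, acyl, substituents = character()) {
  stopifnot(n == round(n), inherits(acyl, "acyl_chain"))
  if (n < 2) stop("an LCO needs n >= 2 residues", call. = FALSE)
  subs <- stats::setNames(rep("H", 5L), names(.POSITION_SITE))
  if (length(substituents)) {
    bad <- setdiff(names(substituents), names(.POSITION_SITE))
    if (length(bad) || is.null(names(substituents))) {
      stop("substituents must be named with positions R2-R6", call. = FALSE)
    }
    subs[names(substituents)] <- substituents
  }
  for (pos in names(subs)) {
    code <- subs[[pos]]
    if (!code %in% names(.SUBSTITUENTS)) {
      stop("unknown substituent code: ", code, call. = FALSE)
    }
    allowed <- .SUBSTITUENTS[[code]]$sites
    if (allowed != "any" && allowed != .POSITION_SITE[[pos]]) {
      stop("invalid structure: substituent ", code, " not allowed at ", pos,
           " (", .POSITION_SITE[[pos]], " site)", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), acyl = acyl, substituents = subs),
            class = c("lco_structure", "chito_structure"))
}

#' @export
print.chito_structure <- function(x, ...) {
  cat("<", class(x)[1], "> ", canonical_name(x),
      "  [", formula_to_string(structure_formula(x)), "]\n", sep = "")
  invisible(x)
}

#' Backbone length of a structure
#' @param s A `chito_structure`.
#' @return Integer number of GlcNAc residues.
#' @export
backbone_length <- function(s) {
  stopifnot(inherits(s, "chito_structure"))
  s$n
}

#' Neutral elemental formula of a CO or LCO structure
#'
#' For a CO: n GlcNAc residues plus one water. For an LCO: the CO formula
#' minus the N-acetyl it loses at R1, plus the acyl group, plus the net
#' deltas of all non-H substituents. Independent of the order substituents
#' were assigned in.
#'
#' @param s A `chito_structure`.
#' @return An [elemental_formula].
#' @examples
#' formula_to_string(structure_formula(co_structure(4)))  # "C32H54N4O21"
#' @export
structure_formula <- function(s) {
  stopifnot(inherits(s, "chito_structure"))
  f <- formula_add(formula_multiply(.glcnac_formula(), s$n),
                   elemental_formula(H = 2, O = 1))
  if (inherits(s, "co_structure")) return(f)
  f <- formula_add(f, acyl_delta(s$acyl))
  for (code in s$substituents) {
    f <- formula_add(f, .SUBSTITUENTS[[code]]$delta)
  }
  if (any(unclass(f) < 0)) {
    stop("invalid structure: negative element count in ",
         formula_to_string(f), call. = FALSE)
  }
  f
}

#' Canonical structure name
#'
#' Unique, assignment-order-independent label: `CO<n>` for
#' chitooligosaccharides and `LCO-<Roman n>(<acyl>[,<codes>])` for
#' lipo-chitooligosaccharides, with the non-H substituent codes sorted
#' alphabetically (standard Nod-factor nomenclature, e.g.
#' `LCO-IV(C16:0,S)`). Two structures with the same name are treated as the
#' same database entry.
#'
#' @param s A `chito_structure`.
#' @return Character scalar.
#' @export
canonical_name <- function(s) {
  stopifnot(inherits(s, "chito_structure"))
  if (inherits(s, "co_structure")) return(paste0("CO", s$n))
  codes <- sort(s$substituents[s$substituents != "H"])
  inner <- paste(c(acyl_label(s$acyl), codes), collapse = ",")
  paste0("LCO-", as.character(utils::as.roman(s$n)), "(", inner, ")")
}

#' Structure grammar for combinatorial enumeration
#'
#' Describes the structure space to enumerate: backbone length range, acyl
#' chain library, and the substituent codes allowed at each position R2-R6.
#' The default grammar covers the commonly described Nod-factor space:
#' backbones of 3-5 GlcNAc, even-chain fatty acids C12-C22 with 0-3 double
#' bonds, N-methylation at R2, O-acetyl/carbamoyl on the non-reducing
#' residue, and the reducing-end decorations (S, Fuc, MeFuc, FucS, Ac) at R6.
#'
#' @param n_range Integer vector of backbone lengths.
#' @param acyl_library List of [acyl_chain()] objects.
#' @param allowed Named list over R2-R6 of allowed substituent codes.
#' @return An object of class `structure_grammar`.
#' @export
structure_grammar <- function(n_range = 3:5,
                              acyl_library = default_acyl_library(),
                              allowed = list(
                                R2 = c("H", "Me"),
                                R3 = c("H", "Ac", "Cb"),
                                R4 = c("H", "Cb"),
                                R5 = c("H", "Ac"),
                                R6 = c("H", "S", "Fuc", "MeFuc", "FucS", "Ac")
                              )) {
  if (!length(acyl_library)) stop("empty acyl library", call. = FALSE)
  stopifnot(all(vapply(acyl_library, inherits, logical(1), "acyl_chain")),
            all(n_range >= 2), length(n_range) > 0)
  if (!setequal(names(allowed), names(.POSITION_SITE))) {
    stop("allowed sets must cover exactly positions R2-R6", call. = FALSE)
  }
  for (pos in names(allowed)) {
    bad <- setdiff(allowed[[pos]], names(.SUBSTITUENTS))
    if (length(bad)) stop("unknown substituent code(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_range = sort(unique(as.integer(n_range))),
                 acyl_library = acyl_library,
                 allowed = allowed[names(.POSITION_SITE)]),
            class = "structure_grammar")
}

#' Default fatty acyl library: even chains C12-C22, 0-3 double bonds
#'
#' Natural fatty acids are synthesised two carbons at a time, so even chain
#' lengths dominate; restricting the default library to them also keeps the
#' enumerated space free of exact mass degeneracies between odd-chain acyls
#' and (even-chain + N-methyl) structures, which unit-resolution MRM could
#' not distinguish anyway. Pass your own list to [structure_grammar()] for a
#' different chain range.
#'
#' @param carbons Integer vector of chain lengths.
#' @param double_bonds Integer vector of double-bond counts.
#' @return List of [acyl_chain()] objects.
#' @export
default_acyl_library <- function(carbons = seq(12L, 22L, by = 2L),
                                 double_bonds = 0:3) {
  grid <- expand.grid(d = double_bonds, c = carbons)
  grid <- grid[grid$d <= grid$c - 1, ]
  mapply(function(c, d) acyl_chain(c, d), grid$c, grid$d, SIMPLIFY = FALSE)
}

#' Enumerate the LCO structure space of a grammar
#'
#' Cartesian product of backbone lengths, acyl library and the allowed
#' substituent set at each position, deduplicated by canonical name and
#' returned sorted by name, so enumeration order is deterministic.
#'
#' @param grammar A [structure_grammar()].
#' @return Named list of `lco_structure` objects (names = canonical names).
#' @export
enumerate_structures <- function(grammar) {
  stopifnot(inherits(grammar, "structure_grammar"))
  sub_grid <- expand.grid(grammar$allowed, stringsAsFactors = FALSE)
  out <- vector("list",
                length(grammar$n_range) * length(grammar$acyl_library) *
                  nrow(sub_grid))
  nm <- character(length(out))
  k <- 0L
  for (n in grammar$n_range) {
    for (acyl in grammar$acyl_library) {
      for (r in seq_len(nrow(sub_grid))) {
        k <- k + 1L
        s <- lco_structure(n, acyl,
                           stats::setNames(as.character(sub_grid[r, ]),
                                           colnames(sub_grid)))
        out[[k]] <- s
        nm[k] <- canonical_name(s)
      }
    }
  }
  keep <- !duplicated(nm)
  out <- out[keep]
  names(out) <- nm[keep]
  out[order(names(out), method = "radix")]
}
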