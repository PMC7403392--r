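# Independent oracles, deliberately separate from the package code paths.

# Per-atom mass summation over a Hill string, with its own parsing and its
# own copy of the IUPAC monoisotopic masses.
oracle_mass <- function(hill) {
  masses <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, S = 31.97207069)
  total <- 0
  pos <- 1L
  while (pos <= nchar(hill)) {
    el <- substr(hill, pos, pos)
    pos <- pos + 1L
    digits <- ""
    while (pos <= nchar(hill) && grepl("[0-9]", substr(hill, pos, pos))) {
      digits <- paste0(digits, substr(hill, pos, pos))
      pos <- pos + 1L
    }
    count <- if (digits == "") 1 else as.numeric(digits)
    total <- total + masses[[el]] * count
  }
  total
}

# 20-formula fixture covering molecules, residues and substituted species.
oracle_formula_fixture <- c(
  "H2O", "C8H13NO5", "C16H26N2O10", "C24H41N3O16", "C32H54N4O21",
  "C40H67N5O26", "C48H80N6O31", "C46H82N4O21", "C2H2O", "CH2",
  "CHNO", "O3S", "C6H10O4", "C7H12O4", "C6H10O7S",
  "C16H30O", "C18H32O", "C46H82N4O24S", "C52H92N4O25", "C38H69N3O16"
)

# Brute-force Cartesian-product enumeration oracle: counts distinct
# (n, acyl label, R2..R6 codes) tuples collapsed by a name built the same
# way the package documents its canonical naming (sorted non-H codes).
oracle_enumeration_count <- function(n_range, acyl_labels, allowed) {
  grid <- expand.grid(c(list(n = n_range, acyl = acyl_labels), allowed),
                      stringsAsFactors = FALSE)
  codes <- apply(grid[, names(allowed), drop = FALSE], 1, function(r) {
    paste(sort(r[r != "H"]), collapse = ",")
  })
  length(unique(paste(grid$n, grid$acyl, codes)))
}

# A small deterministic grammar used by several tests.
small_grammar <- function() {
  structure_grammar(
    n_range = 3:4,
    acyl_library = list(acyl_chain(16, 0), acyl_chain(18, 1)),
    allowed = list(R2 = "H", R3 = c("H", "Cb"), R4 = "H",
                   R5 = "H", R6 = c("H", "S", "Fuc"))
  )
}

# A random grammar of moderate size (seeded by the caller).
random_grammar <- function() {
  carbons <- sample(seq(12, 22, 2), 4)
  structure_grammar(
    n_range = 3:5,
    acyl_library = default_acyl_library(carbons = carbons,
                                        double_bonds = 0:3),
    allowed = list(R2 = c("H", "Me"), R3 = c("H", "Ac"), R4 = c("H", "Cb"),
                   R5 = "H", R6 = c("H", "S", "Fuc", "MeFuc", "FucS"))
  )
}

# A noise-free Gaussian trace on a fixed grid.
gaussian_trace <- function(t0, amplitude = 1000, sigma = 0.05,
                           grid = seq(1, 11, by = 0.01)) {
  data.frame(rt_min = grid,
             intensity = amplitude * exp(-(grid - t0)^2 / (2 * sigma^2)))
}
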