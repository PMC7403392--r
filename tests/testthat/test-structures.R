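test_that("CO and LCO formulas follow the residue-sum composition rules", {
  co4 <- co_structure(4)
  expect_identical(formula_to_string(structure_formula(co4)), "C32H54N4O21")
  expect_equal(monoisotopic_mass(structure_formula(co4)), 830.3281,
               tolerance = 1e-3)
  # acylation swaps the N-acetyl for the fatty chain
  lco <- lco_structure(4, acyl_chain(16, 0))
  expect_equal(monoisotopic_mass(structure_formula(lco)), 1026.5472,
               tolerance = 1e-3)
  # sulfation adds exactly SO3
  lco_s <- lco_structure(4, acyl_chain(16, 0), c(R6 = "S"))
  expect_equal(monoisotopic_mass(structure_formula(lco_s)) -
                 monoisotopic_mass(structure_formula(lco)),
               79.9568, tolerance = 1e-3)
  # formula independent of substituent assignment order
  a <- lco_structure(5, acyl_chain(18, 1), c(R6 = "Fuc", R3 = "Ac"))
  b <- lco_structure(5, acyl_chain(18, 1), c(R3 = "Ac", R6 = "Fuc"))
  expect_equal(structure_formula(a), structure_formula(b))
})

test_that("substituent deltas carry the documented compositions", {
  lib <- substituent_library()
  deltas <- setNames(lib$formula_delta, lib$code)
  expect_identical(deltas[["H"]], "")
  expect_identical(deltas[["Me"]], "CH2")
  expect_identical(deltas[["Ac"]], "C2H2O")
  expect_identical(deltas[["Cb"]], "CHNO")
  expect_identical(deltas[["S"]], "O3S")
  expect_identical(deltas[["Fuc"]], "C6H10O4")
  expect_identical(deltas[["MeFuc"]], "C7H12O4")
  expect_identical(deltas[["FucS"]], "C6H10O7S")
  # FucS is exactly Fuc + S
  masses <- setNames(lib$mass_delta, lib$code)
  expect_equal(masses[["FucS"]], masses[["Fuc"]] + masses[["S"]],
               tolerance = 1e-9)
})

test_that("site restrictions reject substituents on the wrong residue", {
  expect_error(lco_structure(4, acyl_chain(16, 0), c(R2 = "S")),
               "not allowed")
  expect_error(lco_structure(4, acyl_chain(16, 0), c(R6 = "Cb")),
               "not allowed")
  expect_error(lco_structure(4, acyl_chain(16, 0), c(R6 = "Xy")),
               "unknown substituent")
  expect_silent(lco_structure(4, acyl_chain(16, 0), c(R6 = "FucS")))
  expect_error(acyl_chain(16, 16), "double bond")
  expect_error(co_structure(1), "n >= 2")
})

test_that("canonical names are unique, order-independent Nod-factor labels", {
  expect_identical(canonical_name(co_structure(4)), "CO4")
  expect_identical(
    canonical_name(lco_structure(4, acyl_chain(16, 0), c(R6 = "S"))),
    "LCO-IV(C16:0,S)")
  expect_identical(canonical_name(lco_structure(5, acyl_chain(18, 1))),
                   "LCO-V(C18:1)")
  a <- lco_structure(5, acyl_chain(18, 1), c(R6 = "Fuc", R3 = "Ac"))
  b <- lco_structure(5, acyl_chain(18, 1), c(R3 = "Ac", R6 = "Fuc"))
  expect_identical(canonical_name(a), canonical_name(b))
  expect_identical(canonical_name(a), "LCO-V(C18:1,Ac,Fuc)")
})

test_that("enumeration matches brute-force Cartesian-product counts", {
  # single-option grammar
  g1 <- structure_grammar(n_range = 3, acyl_library = list(acyl_chain(16, 0)),
                          allowed = list(R2 = "H", R3 = "H", R4 = "H",
                                         R5 = "H", R6 = "H"))
  expect_length(enumerate_structures(g1), 1L)
  # 1 backbone x 2 acyls x 2 R6 options
  g2 <- structure_grammar(n_range = 4,
                          acyl_library = list(acyl_chain(16, 0),
                                              acyl_chain(18, 1)),
                          allowed = list(R2 = "H", R3 = "H", R4 = "H",
                                         R5 = "H", R6 = c("H", "S")))
  expect_length(enumerate_structures(g2), 4L)
  # 2 backbones x 1 acyl x 2 R2 x 3 R6
  g3 <- structure_grammar(n_range = 3:4,
                          acyl_library = list(acyl_chain(16, 0)),
                          allowed = list(R2 = c("H", "Me"), R3 = "H",
                                         R4 = "H", R5 = "H",
                                         R6 = c("H", "S", "Fuc")))
  expect_length(enumerate_structures(g3), 12L)
  # randomized grammars against the independent counting oracle
  set.seed(7)
  for (rep in 1:5) {
    g <- random_grammar()
    st <- enumerate_structures(g)
    expected <- oracle_enumeration_count(
      g$n_range, vapply(g$acyl_library, acyl_label, character(1)), g$allowed)
    expect_length(st, expected)
    # deterministic sorted order, no name duplicates
    expect_identical(names(st), sort(names(st), method = "radix"))
    expect_false(anyDuplicated(names(st)) > 0)
  }
  expect_error(structure_grammar(acyl_library = list()), "empty acyl")
})

test_that("every enumerated structure has a valid molecular composition", {
  set.seed(11)
  st <- enumerate_structures(random_grammar())
  ok <- vapply(st, function(s) {
    f <- structure_formula(s)
    all(unclass(f) >= 0) && monoisotopic_mass(f) > 0
  }, logical(1))
  expect_true(all(ok))
})
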