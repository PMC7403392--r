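test_that("CO precursors and the common B1 reproduce the unit-resolution panel", {
  expect_identical(vapply(3:6, function(n)
    nominal_mz(precursor_mz(co_structure(n))), integer(1)),
    c(628L, 831L, 1034L, 1237L))
  for (n in 3:6) {
    expect_identical(nominal_mz(b_ion_mz(co_structure(n), 1)), 204L)
  }
  expect_equal(precursor_mz(lco_structure(4, acyl_chain(16, 0),
                                          c(R6 = "S"))),
               1107.5113, tolerance = 1e-3)
})

test_that("B ions sum the non-reducing residues and exclude reducing-end substituents", {
  expect_equal(b_ion_mz(co_structure(4), 2), 407.1661, tolerance = 1e-3)
  lco <- lco_structure(4, acyl_chain(16, 0))
  lco_s <- lco_structure(4, acyl_chain(16, 0), c(R6 = "S"))
  lco_fuc <- lco_structure(4, acyl_chain(16, 0), c(R6 = "Fuc", R5 = "Ac"))
  idx <- 1:3
  expect_equal(b_ion_mz(lco, idx), b_ion_mz(lco_s, idx))
  expect_equal(b_ion_mz(lco, idx), b_ion_mz(lco_fuc, idx))
  # a non-reducing substituent shifts every B ion by its delta
  lco_me <- lco_structure(4, acyl_chain(16, 0), c(R2 = "Me"))
  expect_equal(b_ion_mz(lco_me, idx) - b_ion_mz(lco, idx),
               rep(14.0157, 3), tolerance = 1e-3)
  expect_error(b_ion_mz(lco, 4), "1..n-1")
  expect_error(b_ion_mz(lco, 0), "1..n-1")
})

test_that("transition DB has one record per B ion with correct stats", {
  db1 <- build_transition_db(lco_structure(4, acyl_chain(16, 0)))
  expect_identical(nrow(db1), 3L)
  expect_identical(db1$ion_label, c("B1", "B2", "B3"))

  g2 <- structure_grammar(n_range = 4,
                          acyl_library = list(acyl_chain(16, 0),
                                              acyl_chain(18, 1)),
                          allowed = list(R2 = "H", R3 = "H", R4 = "H",
                                         R5 = "H", R6 = c("H", "S")))
  db <- build_transition_db(enumerate_structures(g2))
  s <- db_stats(db)
  expect_identical(s$structures, 4L)
  expect_identical(s$records, 12L)
  expect_identical(s$precursors_by_structure, 4L)
  expect_identical(s$precursors_unique_mz, 4L)
  # sulfated/non-sulfated pairs share their B-ion (product) m/z values
  expect_identical(length(unique(round(db$product_mz, 4))), 6L)
  # merging a DB with itself leaves stats unchanged
  both <- rbind(db, db)
  class(both) <- c("transition_db", "data.frame")
  dedup <- both[!duplicated(both[, c("structure", "ion_label")]), ]
  class(dedup) <- c("transition_db", "data.frame")
  expect_identical(db_stats(dedup), s)
  # empty db
  e <- db[0, ]
  class(e) <- c("transition_db", "data.frame")
  expect_identical(db_stats(e)$structures, 0L)
})

test_that("structural invariants hold across a large random grammar", {
  set.seed(19)
  st <- enumerate_structures(random_grammar())
  expect_gt(length(st), 500)
  db <- build_transition_db(st)
  expect_true(all(db$product_mz < db$precursor_mz))
  # B ions strictly increase with cleavage index
  for (s in st[sample(length(st), 200)]) {
    expect_true(all(diff(b_ion_mz(s, seq_len(s$n - 1))) > 0))
  }
  stats <- db_stats(db)
  expect_lte(stats$precursors_unique_mz, stats$structures)
  expect_lte(stats$unique_transitions,
             sum(vapply(st, function(s) s$n - 1L, integer(1))))
})

test_that("panel selection keeps all transitions of the named structures", {
  db <- build_transition_db(lapply(3:6, co_structure))
  panel <- select_panel(db, names = c("CO3", "CO4", "CO5", "CO6"))
  expect_identical(nrow(panel), 14L)  # 2+3+4+5 B ions
  expect_true(all(paste(panel$structure, panel$ion_label) %in%
                    paste(db$structure, db$ion_label)))
  empty <- select_panel(db, names = character(0))
  expect_identical(nrow(empty), 0L)
  expect_warning(select_panel(db, names = c("CO3", "CO99")),
                 "unknown structure")
  capped <- select_panel(db, max_size = 5)
  expect_identical(nrow(capped), 5L)
})

test_that("transition CSV round-trips and rejects malformed rows", {
  db <- build_transition_db(
    c(lapply(3:4, co_structure),
      list(lco_structure(4, acyl_chain(16, 0), c(R6 = "S")))),
    expected_rt = c("CO3" = 2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transitions(db, path)
  back <- read_transitions(path)
  expect_identical(back$structure, db$structure)
  expect_equal(round(back$precursor_mz, 4), round(db$precursor_mz, 4))
  expect_equal(round(back$product_mz, 4), round(db$product_mz, 4))
  expect_identical(db_stats(back), db_stats(db))
  expect_equal(back$expected_rt[back$structure == "CO3"][1], 2.5)

  # file without the optional expected_rt column
  df <- utils::read.csv(path)
  df$expected_rt <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_true(all(is.na(read_transitions(path2)$expected_rt)))

  # negative m/z is a parse error with a line number
  df2 <- utils::read.csv(path)
  df2$precursor_mz[2] <- -5
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, path3, row.names = FALSE)
  expect_error(read_transitions(path3), "line 3")
})
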