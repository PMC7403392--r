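test_that("peak extraction finds Gaussian apexes and ignores flat traces", {
  tr <- gaussian_trace(5.0)
  pk <- extract_peaks(tr$rt_min, tr$intensity)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$rt, 5.0, tolerance = 0.011)

  flat <- extract_peaks(seq(1, 11, 0.01), rep(0, 1001))
  expect_identical(nrow(flat), 0L)
  expect_identical(nrow(extract_peaks(numeric(0), numeric(0))), 0L)

  two <- gaussian_trace(4.0)
  two$intensity <- two$intensity + gaussian_trace(6.0)$intensity
  pk2 <- extract_peaks(two$rt_min, two$intensity)
  expect_identical(nrow(pk2), 2L)
  expect_equal(pk2$rt, c(4.0, 6.0), tolerance = 0.011)

  # bumps below the SNR threshold on a noisy baseline are rejected
  set.seed(3)
  noisy <- gaussian_trace(5.0, amplitude = 10)
  noisy$intensity <- pmax(noisy$intensity + 100 +
                            rnorm(nrow(noisy), 0, 20), 0)
  expect_identical(nrow(extract_peaks(noisy$rt_min, noisy$intensity,
                                      snr_threshold = 10)), 0L)
})

test_that("confidence tiers follow the two/one-transition evidence rules", {
  expect_identical(confidence_tier(3, FALSE), "high")
  expect_identical(confidence_tier(2, FALSE), "high")
  expect_identical(confidence_tier(1, TRUE), "low")
  expect_identical(confidence_tier(1, FALSE), "none")
  expect_identical(confidence_tier(0, FALSE), "none")
})

make_traces <- function(panel, rts, grid = seq(1, 11, by = 0.01)) {
  # noise-free traces: a Gaussian on each panel transition whose structure
  # appears in rts, flat zero elsewhere
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    s <- panel$structure[i]
    y <- if (s %in% names(rts))
      1000 * exp(-(grid - rts[[s]])^2 / (2 * 0.05^2)) else rep(0, length(grid))
    data.frame(precursor_mz = panel$precursor_mz[i],
               product_mz = panel$product_mz[i], rt_min = grid, intensity = y)
  })
  do.call(rbind, rows)
}

test_that("co-eluting transitions yield tiered detection calls", {
  structures <- list(lco_structure(4, acyl_chain(16, 0)),
                     lco_structure(4, acyl_chain(16, 0), c(R6 = "S")),
                     lco_structure(5, acyl_chain(18, 1), c(R6 = "FucS")))
  panel <- build_transition_db(structures)
  rts <- c("LCO-IV(C16:0)" = 4.2, "LCO-V(C18:1,FucS)" = 7.5)
  calls <- match_mrm(panel, make_traces(panel, rts))
  calls <- calls[order(calls$structure), ]
  expect_identical(calls$tier[calls$structure == "LCO-IV(C16:0)"], "high")
  expect_identical(calls$tier[calls$structure == "LCO-V(C18:1,FucS)"], "high")
  expect_identical(calls$tier[calls$structure == "LCO-IV(C16:0,S)"], "none")
  expect_equal(calls$rt[calls$structure == "LCO-IV(C16:0)"], 4.2,
               tolerance = 0.02)

  # single remaining transition: low only at the expected RT
  one <- panel[panel$structure == "LCO-IV(C16:0)" & panel$ion_label == "B1", ]
  class(one) <- c("transition_db", "data.frame")
  tr1 <- make_traces(one, rts)
  expect_identical(match_mrm(one, tr1)$tier, "none")  # no expected RT known
  one$expected_rt <- 4.2
  expect_identical(match_mrm(one, tr1)$tier, "low")
  one$expected_rt <- 9.0  # peak elutes elsewhere
  expect_identical(match_mrm(one, tr1)$tier, "none")
})

test_that("widening the m/z tolerance never loses matched transitions", {
  panel <- build_transition_db(list(lco_structure(4, acyl_chain(16, 0))))
  traces <- make_traces(panel, c("LCO-IV(C16:0)" = 5.0))
  traces$product_mz <- traces$product_mz + 0.3  # slight miscalibration
  counts <- vapply(c(0.1, 0.35, 0.6, 1.0), function(tol) {
    match_mrm(panel, traces, mz_tolerance = tol)$matched_transitions
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 0L)
  expect_identical(counts[4], 3L)
})

test_that("ambiguous traces go to the nearest transition with a warning", {
  panel <- build_transition_db(list(co_structure(3)))
  # two panel rows within tolerance of one trace key
  tr <- gaussian_trace(5.0)
  traces <- data.frame(precursor_mz = panel$precursor_mz[1] + 0.1,
                       product_mz = mean(panel$product_mz),
                       rt_min = tr$rt_min, intensity = tr$intensity)
  expect_warning(match_mrm(panel, traces, mz_tolerance = 150),
                 "nearest m/z")
})

test_that("untargeted annotation filters by backbone and ranks by matched products", {
  db <- build_transition_db(c(lapply(3:7, co_structure)))
  co5 <- db[db$structure == "CO5", ]
  sp <- data.frame(spectrum_id = "s1",
                   precursor_mz = co5$precursor_mz[1],
                   product_mz = co5$product_mz[1],  # B1 = 204 only
                   intensity = 500)
  ann <- match_untargeted(sp, db, min_products = 1)
  expect_identical(ann$structure[ann$rank == 1], "CO5")
  # min_products = 2 rejects the single-product spectrum
  expect_identical(nrow(match_untargeted(sp, db, min_products = 2)), 0L)
  # a 7-residue precursor is excluded by the 3-6 GlcNAc filter
  co7 <- db[db$structure == "CO7", ]
  sp7 <- data.frame(spectrum_id = "s7", precursor_mz = co7$precursor_mz[1],
                    product_mz = co7$product_mz[1:3], intensity = 500)
  expect_identical(nrow(match_untargeted(sp7, db, min_products = 1)), 0L)
  # empty input
  expect_identical(nrow(match_untargeted(sp[0, ], db)), 0L)
})
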