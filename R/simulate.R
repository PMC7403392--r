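#' Simulation configuration for synthetic MRM chromatograms
#'
#' Describes an in-silico injection: which structures are present
#' ("planted"), where they elute, peak shape and amplitude, the time grid,
#' baseline noise, decoys and per-transition dropout. Planted retention
#' times left `NA` are drawn uniformly within the LC window at simulation
#' time.
#'
#' @param planted data.frame with columns `structure` (canonical names) and
#'   optionally `rt` (true retention time, min).
#' @param amplitude_range Length-2 numeric, uniform range of peak apex
#'   amplitudes (arbitrary units).
#' @param sigma Gaussian peak width (standard deviation), min.
#' @param time_start,time_end,time_step Acquisition grid, min; the default
#'   1-11 min window matches a short reversed-phase gradient.
#' @param noise_sd Standard deviation of the additive Gaussian baseline
#'   noise (intensities are clipped at zero).
#' @param baseline Constant detector baseline level added to every trace;
#'   the default, three noise standard deviations, keeps the zero-clipping
#'   of the noise negligible so the simulated baseline stays Gaussian.
#' @param decoys_on_panel Number of decoy peaks placed on non-planted panel
#'   transitions at random retention times (exercises co-elution logic).
#' @param decoys_off_panel Number of decoy traces at random off-panel m/z
#'   pairs (exercises m/z tolerance logic).
#' @param dropout Per-transition probability that a planted transition emits
#'   no peak.
#' @param seed Random seed; identical seeds give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(planted, amplitude_range = c(500, 2000),
                       sigma = 0.05, time_start = 1, time_end = 11,
                       time_step = 0.01, noise_sd = 5,
                       baseline = 3 * noise_sd,
                       decoys_on_panel = 0, decoys_off_panel = 0,
                       dropout = 0, seed = NULL) {
  stopifnot(is.data.frame(planted), "structure" %in% names(planted),
            time_step > 0, sigma > 0, noise_sd >= 0,
            baseline >= 0, dropout >= 0, dropout <= 1,
            length(amplitude_range) == 2, all(amplitude_range > 0))
  if (!"rt" %in% names(planted)) planted$rt <- NA_real_
  structure(list(planted = planted, amplitude_range = amplitude_range,
                 sigma = sigma, time_start = time_start, time_end = time_end,
                 time_step = time_step, noise_sd = noise_sd,
                 baseline = baseline,
                 decoys_on_panel = decoys_on_panel,
                 decoys_off_panel = decoys_off_panel,
                 dropout = dropout, seed = seed),
            class = "sim_config")
}

#' Simulate MRM chromatograms for a transition panel
#'
#' Every non-dropped transition of a planted structure receives a Gaussian
#' elution peak \eqn{A e^{-(t-t_0)^2 / 2\sigma^2}} at its structure's true
#' retention time; all monitored traces carry additive Gaussian baseline
#' noise (clipped at zero); decoy peaks are placed on non-planted panel
#' transitions at random times and on random off-panel m/z pairs. Fully
#' reproducible under the config seed.
#'
#' @param panel A `transition_db` containing every planted structure.
#' @param config A [sim_config()].
#' @return A list: `traces` (long-format data.frame `precursor_mz`,
#'   `product_mz`, `rt_min`, `intensity`), `truth` (data.frame `structure`,
#'   `true_rt`, `transitions_emitted`, `transitions_dropped`).
#' @export
simulate_chromatograms <- function(panel, config) {
  stopifnot(inherits(panel, "transition_db"), inherits(config, "sim_config"))
  planted <- config$planted
  missing <- setdiff(planted$structure, panel$structure)
  if (length(missing)) {
    stop("planted structure(s) absent from panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- seq(config$time_start, config$time_end, by = config$time_step)
  rt <- planted$rt
  draw <- is.na(rt)
  rt[draw] <- stats::runif(sum(draw), config$time_start, config$time_end)
  names(rt) <- planted$structure

  gauss <- function(a, t0) a * exp(-(grid - t0)^2 / (2 * config$sigma^2))
  n_tr <- nrow(panel)
  signal <- matrix(0, nrow = length(grid), ncol = n_tr)
  emitted <- dropped <- stats::setNames(rep(0L, nrow(planted)),
                                        planted$structure)
  for (i in seq_len(n_tr)) {
    sname <- panel$structure[i]
    if (sname %in% planted$structure) {
      if (stats::runif(1) < config$dropout) {
        dropped[sname] <- dropped[sname] + 1L
      } else {
        a <- stats::runif(1, config$amplitude_range[1],
                          config$amplitude_range[2])
        signal[, i] <- signal[, i] + gauss(a, rt[[sname]])
        emitted[sname] <- emitted[sname] + 1L
      }
    }
  }
  # decoy peaks on non-planted panel transitions, at random RTs
  free <- which(!panel$structure %in% planted$structure)
  k_on <- min(config$decoys_on_panel, length(free))
  if (k_on > 0) {
    pick <- if (length(free) == 1L) free else sample(free, k_on)
    for (i in pick) {
      a <- stats::runif(1, config$amplitude_range[1],
                        config$amplitude_range[2])
      signal[, i] <- signal[, i] +
        gauss(a, stats::runif(1, config$time_start, config$time_end))
    }
  }
  signal <- signal + config$baseline
  if (config$noise_sd > 0) {
    signal <- signal + matrix(stats::rnorm(length(signal), 0,
                                           config$noise_sd),
                              nrow = nrow(signal))
  }
  signal <- pmax(signal, 0)
  traces <- data.frame(
    precursor_mz = rep(panel$precursor_mz, each = length(grid)),
    product_mz = rep(panel$product_mz, each = length(grid)),
    rt_min = rep(grid, times = n_tr),
    intensity = as.vector(signal)
  )
  # off-panel decoy traces at m/z pairs no panel transition claims
  if (config$decoys_off_panel > 0) {
    for (d in seq_len(config$decoys_off_panel)) {
      repeat {
        prec <- stats::runif(1, 300, 1400)
        prod <- stats::runif(1, 150, prec - 50)
        clash <- any(abs(panel$precursor_mz - prec) <= 1 &
                       abs(panel$product_mz - prod) <= 1)
        if (!clash) break
      }
      a <- stats::runif(1, config$amplitude_range[1],
                        config$amplitude_range[2])
      y <- config$baseline +
        gauss(a, stats::runif(1, config$time_start, config$time_end))
      if (config$noise_sd > 0) {
        y <- y + stats::rnorm(length(grid), 0, config$noise_sd)
      }
      traces <- rbind(traces, data.frame(
        precursor_mz = prec, product_mz = prod, rt_min = grid,
        intensity = pmax(y, 0)))
    }
  }
  panel_per_structure <- table(panel$structure)[planted$structure]
  truth <- data.frame(
    structure = planted$structure,
    true_rt = unname(rt[planted$structure]),
    transitions_emitted = unname(emitted[planted$structure]),
    transitions_dropped = unname(dropped[planted$structure])
  )
  stopifnot(all(truth$transitions_emitted + truth$transitions_dropped ==
                  as.integer(panel_per_structure)))
  list(traces = traces, truth = truth)
}

#' Simulate untargeted precursor/product spectra from a database
#'
#' Draws `k_structures` structures without replacement; each yields one
#' spectrum containing its precursor m/z, all of its true B ions, and
#' `noise_products` random extra product ions. Reproducible under `seed`.
#'
#' @param db A non-empty `transition_db`.
#' @param k_structures Number of spectra to generate (<= structures in db).
#' @param noise_products Random extra product ions per spectrum (default 2).
#' @param seed Random seed.
#' @return A list: `spectra` (long-format data.frame `spectrum_id`,
#'   `precursor_mz`, `product_mz`, `intensity`), `truth` (data.frame
#'   `spectrum_id`, `structure`).
#' @export
simulate_untargeted <- function(db, k_structures, noise_products = 2,
                                seed = NULL) {
  stopifnot(inherits(db, "transition_db"), nrow(db) > 0)
  snames <- unique(db$structure)
  if (k_structures > length(snames)) {
    stop("k_structures exceeds the number of structures in the database",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (k_structures == 0L) {
    return(list(
      spectra = data.frame(spectrum_id = character(0),
                           precursor_mz = numeric(0),
                           product_mz = numeric(0), intensity = numeric(0)),
      truth = data.frame(spectrum_id = character(0), structure = character(0))
    ))
  }
  pick <- sample(snames, k_structures)
  spectra <- list()
  for (i in seq_along(pick)) {
    rows <- db[db$structure == pick[i], ]
    sid <- sprintf("spec%03d", i)
    prods <- rows$product_mz
    ints <- stats::runif(length(prods), 100, 1000)
    if (noise_products > 0) {
      noise_mz <- stats::runif(noise_products, 150,
                               rows$precursor_mz[1] - 20)
      prods <- c(prods, noise_mz)
      ints <- c(ints, stats::runif(noise_products, 10, 200))
    }
    spectra[[i]] <- data.frame(spectrum_id = sid,
                               precursor_mz = rows$precursor_mz[1],
                               product_mz = prods, intensity = ints)
  }
  list(spectra = do.call(rbind, spectra),
       truth = data.frame(spectrum_id = sprintf("spec%03d",
                                                seq_along(pick)),
                          structure = pick))
}
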