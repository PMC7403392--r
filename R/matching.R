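#' Extract chromatographic peaks from one MRM trace
#'
#' Local-maximum peak picking with a robust noise floor: the baseline level
#' is the median of the trace and the baseline noise its median absolute
#' deviation (both robust to the peak itself occupying part of the trace);
#' apexes must rise above the baseline by at least
#' `max(min_height, snr_threshold * noise)`. Accepted apexes are separated
#' by at least one full width at half maximum (above baseline), taller
#' peaks winning.
#'
#' @param rt_min Strictly increasing time grid (min).
#' @param intensity Non-negative intensity series, same length.
#' @param snr_threshold Minimum signal-to-noise ratio (default 5, the usual detection limit).
#' @param min_height Absolute intensity floor (default 1).
#' @return A data.frame with columns `rt`, `intensity`, `snr`, one row per
#'   accepted apex, ordered by rt. Empty input gives an empty frame.
#' @export
extract_peaks <- function(rt_min, intensity, snr_threshold = 5,
                          min_height = 1) {
  empty <- data.frame(rt = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  if (length(rt_min) < 3L) return(empty)
  stopifnot(length(rt_min) == length(intensity), all(diff(rt_min) > 0),
            all(intensity >= 0))
  baseline <- stats::median(intensity)
  noise <- stats::mad(intensity)
  threshold <- baseline + max(min_height, snr_threshold * noise)
  y <- intensity
  n <- length(y)
  # plateau-tolerant local maxima: >= left neighbour, > right neighbour
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max & y > threshold)
  if (!length(cand)) return(empty)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (idx in cand) {
    half <- baseline + (y[idx] - baseline) / 2
    left <- idx
    while (left > 1L && y[left] > half) left <- left - 1L
    right <- idx
    while (right < n && y[right] > half) right <- right + 1L
    fwhm <- rt_min[right] - rt_min[left]
    if (!length(accepted) ||
        all(abs(rt_min[accepted] - rt_min[idx]) >= fwhm)) {
      accepted <- c(accepted, idx)
    }
  }
  accepted <- sort(accepted)
  data.frame(rt = rt_min[accepted], intensity = y[accepted],
             snr = if (noise > 0) (y[accepted] - baseline) / noise else Inf)
}

#' Confidence tier of a detection
#'
#' Two or more co-eluting transitions give a high-confidence detection;
#' a single transition is only accepted, at low confidence, when its peak
#' sits at the structure's expected retention time; anything else is a
#' non-detection (a single uncorroborated transition is reported as "none").
#'
#' @param matched_count Number of co-eluting matched transitions (>= 0).
#' @param at_expected_rt Logical: does the (single) peak sit at the
#'   structure's expected retention time?
#' @return `"high"`, `"low"` or `"none"`.
#' @export
confidence_tier <- function(matched_count, at_expected_rt = FALSE) {
  stopifnot(matched_count >= 0)
  if (matched_count >= 2) return("high")
  if (matched_count == 1 && isTRUE(at_expected_rt)) return("low")
  "none"
}

# Assign each distinct trace (precursor, product) key to the nearest panel
# transition within mz_tolerance on both coordinates. Ambiguous assignments
# go to the nearest key with a warning, keeping results deterministic.
assign_traces <- function(panel, trace_keys, mz_tolerance) {
  assignment <- rep(NA_integer_, nrow(trace_keys))
  for (j in seq_len(nrow(trace_keys))) {
    dprec <- abs(panel$precursor_mz - trace_keys$precursor_mz[j])
    dprod <- abs(panel$product_mz - trace_keys$product_mz[j])
    hits <- which(dprec <= mz_tolerance & dprod <= mz_tolerance)
    if (!length(hits)) next
    if (length(hits) > 1L) {
      warning("trace (", trace_keys$precursor_mz[j], ", ",
              trace_keys$product_mz[j], ") matches ", length(hits),
              " panel transitions; assigning to nearest m/z", call. = FALSE)
      hits <- hits[order(dprec[hits] + dprod[hits])]
    }
    assignment[j] <- hits[1]
  }
  assignment
}

#' Match MRM chromatograms against a transition panel
#'
#' Each trace is assigned to the panel transition whose precursor and
#' product m/z both lie within `mz_tolerance`. Per structure, peak apexes
#' across its transitions are grouped into co-elution clusters (apex
#' retention times within `rt_coelution_window` of a common centre); the
#' cluster covering the most distinct transitions determines the detection:
#' two or more co-eluting transitions give tier `"high"`, a single peaked
#' transition at the structure's expected retention time gives `"low"`,
#' otherwise `"none"`.
#'
#' @param panel A `transition_db` (the monitored transitions).
#' @param traces Long-format data.frame with columns `precursor_mz`,
#'   `product_mz`, `rt_min`, `intensity` (one row per time point).
#' @param mz_tolerance m/z matching tolerance in Da (default 0.5,
#'   unit-resolution triple quadrupole).
#' @param rt_coelution_window Maximum apex RT spread of co-eluting
#'   transitions, min (default 0.1).
#' @param snr_threshold,min_height Passed to [extract_peaks()].
#' @return A data.frame of detection calls, one row per panel structure,
#'   ordered by name: `structure`, `matched_transitions`, `rt`, `tier`,
#'   `note`.
#' @export
match_mrm <- function(panel, traces, mz_tolerance = 0.5,
                      rt_coelution_window = 0.1, snr_threshold = 5,
                      min_height = 1) {
  stopifnot(inherits(panel, "transition_db"), nrow(panel) > 0)
  stopifnot(all(c("precursor_mz", "product_mz", "rt_min", "intensity") %in%
                  names(traces)))
  keys <- unique(traces[, c("precursor_mz", "product_mz")])
  assignment <- assign_traces(panel, keys, mz_tolerance)
  # apex table: one row per (panel transition, peak)
  apexes <- list()
  for (j in which(!is.na(assignment))) {
    sel <- traces$precursor_mz == keys$precursor_mz[j] &
      traces$product_mz == keys$product_mz[j]
    tr <- traces[sel, ]
    tr <- tr[order(tr$rt_min), ]
    pk <- extract_peaks(tr$rt_min, tr$intensity, snr_threshold, min_height)
    if (nrow(pk)) {
      apexes[[length(apexes) + 1L]] <-
        data.frame(transition = assignment[j], rt = pk$rt)
    }
  }
  apexes <- if (length(apexes)) do.call(rbind, apexes) else
    data.frame(transition = integer(0), rt = numeric(0))
  structures <- sort(unique(panel$structure), method = "radix")
  calls <- lapply(structures, function(sname) {
    trans_idx <- which(panel$structure == sname)
    ap <- apexes[apexes$transition %in% trans_idx, ]
    expected <- panel$expected_rt[trans_idx]
    expected <- expected[!is.na(expected)][1]
    if (!nrow(ap)) {
      return(data.frame(structure = sname, matched_transitions = 0L,
                        rt = NA_real_, tier = "none", note = ""))
    }
    # best co-elution cluster: centre on each apex, count distinct transitions
    best_count <- 0L
    best_rt <- NA_real_
    for (centre in sort(unique(ap$rt))) {
      inwin <- abs(ap$rt - centre) <= rt_coelution_window
      count <- length(unique(ap$transition[inwin]))
      if (count > best_count) {
        best_count <- count
        best_rt <- mean(ap$rt[inwin])
      }
    }
    at_expected <- !is.na(expected) && !is.na(best_rt) &&
      abs(best_rt - expected) <= rt_coelution_window
    tier <- confidence_tier(best_count, at_expected)
    note <- if (best_count == 1L && tier == "none")
      "uncorroborated single transition" else ""
    data.frame(structure = sname, matched_transitions = best_count,
               rt = best_rt, tier = tier, note = note)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Annotate untargeted precursor/product spectra against the database
#'
#' Emulates full-scan acquisition followed by product-ion accumulation:
#' candidate structures are restricted to backbones of `residue_range`
#' GlcNAc residues (default 3-6), must match the spectrum precursor within
#' `mz_tolerance`, and must have at least `min_products` of their B ions
#' present among the spectrum's product ions. Candidates are ranked by
#' matched product count, then by absolute precursor error, then by name.
#'
#' @param spectra Long-format data.frame with columns `spectrum_id`,
#'   `precursor_mz`, `product_mz`, `intensity` (one row per product ion).
#' @param db A `transition_db`.
#' @param mz_tolerance Matching tolerance in Da (default 0.3).
#' @param residue_range Length-2 integer vector, inclusive backbone-length
#'   filter (default `c(3, 6)`).
#' @param min_products Minimum number of matched B ions (default 2).
#' @return A data.frame of annotations: `spectrum_id`, `rank`, `structure`,
#'   `n_matched_products`, `precursor_error`. Spectra without candidates
#'   contribute no rows.
#' @export
match_untargeted <- function(spectra, db, mz_tolerance = 0.3,
                             residue_range = c(3, 6), min_products = 2) {
  stopifnot(inherits(db, "transition_db"))
  empty <- data.frame(spectrum_id = character(0), rank = integer(0),
                      structure = character(0),
                      n_matched_products = integer(0),
                      precursor_error = numeric(0))
  if (!nrow(spectra)) return(empty)
  stopifnot(all(c("spectrum_id", "precursor_mz", "product_mz") %in%
                  names(spectra)))
  # per-structure candidate table
  first <- !duplicated(db$structure)
  cand <- data.frame(structure = db$structure[first],
                     n_residues = db$n_residues[first],
                     precursor_mz = db$precursor_mz[first])
  cand <- cand[!is.na(cand$n_residues) &
                 cand$n_residues >= residue_range[1] &
                 cand$n_residues <= residue_range[2], ]
  prods <- split(db$product_mz, db$structure)
  out <- list()
  for (sid in unique(spectra$spectrum_id)) {
    sp <- spectra[spectra$spectrum_id == sid, ]
    prec <- sp$precursor_mz[1]
    err <- abs(cand$precursor_mz - prec)
    hits <- which(err <= mz_tolerance)
    if (!length(hits)) next
    nmatch <- vapply(hits, function(h) {
      b <- unique(round(prods[[cand$structure[h]]], 4))
      sum(vapply(b, function(mz) any(abs(sp$product_mz - mz) <= mz_tolerance),
                 logical(1)))
    }, integer(1))
    keep <- nmatch >= min_products
    if (!any(keep)) next
    hits <- hits[keep]; nmatch <- nmatch[keep]
    ord <- order(-nmatch, err[hits], cand$structure[hits], method = "radix")
    out[[length(out) + 1L]] <- data.frame(
      spectrum_id = sid, rank = seq_along(ord),
      structure = cand$structure[hits][ord],
      n_matched_products = nmatch[ord],
      precursor_error = err[hits][ord])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
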