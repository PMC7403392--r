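#' Precursor m/z of a structure ([M+H]+, charge +1)
#'
#' @param s A `chito_structure`.
#' @return Exact m/z of the singly protonated molecule.
#' @examples
#' nominal_mz(precursor_mz(co_structure(5)))   # 1034
#' @export
precursor_mz <- function(s) {
  mz_protonated(monoisotopic_mass(structure_formula(s)))
}

#' B-ion m/z of a structure at cleavage index i
#'
#' The glycosidic B ion retaining the i non-reducing-side residues as a
#' protonated oxocarbenium: the sum of those residue masses (including the
#' acyl chain and any R2-R4 substituents they carry) plus the proton mass.
#' Substituents on the reducing terminal residue (R5, R6) never appear in
#' any B ion, so e.g. a sulfated and a non-sulfated LCO share their entire
#' B-ion series. Strictly increasing in `i`; B1 of any unmodified
#' chitooligosaccharide is the GlcNAc oxocarbenium at nominal m/z 204.
#'
#' @param s A `chito_structure` with backbone length n.
#' @param i Cleavage index, 1 <= i <= n - 1 (scalar or vector).
#' @return Exact product-ion m/z (same length as `i`).
#' @export
b_ion_mz <- function(s, i) {
  stopifnot(inherits(s, "chito_structure"))
  n <- s$n
  if (any(i != round(i)) || any(i < 1) || any(i > n - 1)) {
    stop("cleavage index must lie in 1..n-1 (n = ", n, ")", call. = FALSE)
  }
  residue_mass <- monoisotopic_mass(.glcnac_formula())
  extra <- 0
  if (inherits(s, "lco_structure")) {
    f <- acyl_delta(s$acyl)
    for (pos in c("R2", "R3", "R4")) {
      f <- formula_add(f, .SUBSTITUENTS[[s$substituents[[pos]]]]$delta)
    }
    extra <- sum(unclass(f) * .ATOMIC_MASS)
  }
  i * residue_mass + extra + .PROTON_MASS
}

#' Build the MRM transition database for a set of structures
#'
#' One record per (structure, B ion): the precursor proton adduct paired with
#' each of the n - 1 B ions. Records are deduplicated on (structure name,
#' ion label) and ordered by structure name then cleavage index, so the
#' database is deterministic for a given structure set.
#'
#' @param structures A list of `chito_structure` objects (e.g. from
#'   [enumerate_structures()]), or a single structure.
#' @param expected_rt Optional named numeric vector of expected retention
#'   times (min) keyed by canonical name, e.g. measured from synthetic
#'   standards.
#' @return A `transition_db`: a data.frame with columns `structure`,
#'   `n_residues`, `precursor_mz`, `product_mz`, `ion_label`, `expected_rt`.
#' @examples
#' db <- build_transition_db(lapply(3:6, co_structure))
#' db_stats(db)
#' @export
build_transition_db <- function(structures, expected_rt = NULL) {
  if (inherits(structures, "chito_structure")) structures <- list(structures)
  if (!length(structures)) stop("empty structure list", call. = FALSE)
  stopifnot(all(vapply(structures, inherits, logical(1), "chito_structure")))
  recs <- lapply(structures, function(s) {
    name <- canonical_name(s)
    idx <- seq_len(s$n - 1L)
    data.frame(
      structure = name,
      n_residues = s$n,
      precursor_mz = precursor_mz(s),
      product_mz = b_ion_mz(s, idx),
      ion_label = paste0("B", idx),
      expected_rt = if (!is.null(expected_rt) && name %in% names(expected_rt))
        unname(expected_rt[[name]]) else NA_real_
    )
  })
  db <- do.call(rbind, recs)
  db <- db[!duplicated(db[, c("structure", "ion_label")]), ]
  ord <- order(db$structure, as.integer(sub("^B", "", db$ion_label)),
               method = "radix")
  db <- db[ord, ]
  rownames(db) <- NULL
  class(db) <- c("transition_db", "data.frame")
  db
}

new_transition_db <- function(df) {
  needed <- c("structure", "n_residues", "precursor_mz", "product_mz",
              "ion_label", "expected_rt")
  stopifnot(all(needed %in% names(df)))
  df <- df[, needed]
  rownames(df) <- NULL
  class(df) <- c("transition_db", "data.frame")
  df
}

#' Summary statistics of a transition database
#'
#' Counts structures, precursor entries and transitions. "Precursor ions"
#' can be read as either one entry per structure or one entry per unique
#' precursor m/z, so both are reported; uniqueness of m/z is assessed after
#' rounding to 4 decimals (below instrument resolution, above floating-point
#' noise).
#'
#' @param db A `transition_db`.
#' @return A list: `structures`, `precursors_by_structure` (one per
#'   structure), `precursors_unique_mz`, `unique_transitions` (distinct
#'   precursor/product pairs at 4 decimals), `records`.
#' @export
db_stats <- function(db) {
  stopifnot(inherits(db, "transition_db"))
  if (nrow(db) == 0L) {
    return(list(structures = 0L, precursors_by_structure = 0L,
                precursors_unique_mz = 0L, unique_transitions = 0L,
                records = 0L))
  }
  prec4 <- round(db$precursor_mz, 4)
  prod4 <- round(db$product_mz, 4)
  list(
    structures = length(unique(db$structure)),
    precursors_by_structure = length(unique(db$structure)),
    precursors_unique_mz = length(unique(prec4)),
    unique_transitions = nrow(unique(cbind(prec4, prod4))),
    records = nrow(db)
  )
}

#' Select a reduced transition panel
#'
#' An MRM assay can only monitor a limited number of transitions at proper
#' sensitivity, so analyses run on a reduced panel (the most commonly
#' described Nod-LCOs, in the original assay). Selection takes every
#' transition of the named structures; a size cap, if given, truncates after
#' sorting by structure name.
#'
#' @param db A `transition_db`.
#' @param names Character vector of canonical structure names to keep
#'   (unknown names are skipped with a warning). `NULL` keeps all.
#' @param max_size Optional positive cap on the number of records.
#' @return A `transition_db` subset.
#' @export
select_panel <- function(db, names = NULL, max_size = NULL) {
  stopifnot(inherits(db, "transition_db"))
  out <- db
  if (!is.null(names)) {
    unknown <- setdiff(names, db$structure)
    if (length(unknown)) {
      warning("skipping unknown structure name(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- db[db$structure %in% names, ]
  }
  out <- out[order(out$structure,
                   as.integer(sub("^B", "", out$ion_label)),
                   method = "radix"), ]
  if (!is.null(max_size)) {
    stopifnot(max_size > 0)
    out <- out[seq_len(min(nrow(out), max_size)), ]
  }
  rownames(out) <- NULL
  class(out) <- c("transition_db", "data.frame")
  out
}

#' Write / read a transition database as CSV
#'
#' Plain CSV with fixed column order (`structure`, `precursor_mz`,
#' `product_mz`, `ion_label`, `expected_rt`); m/z round-trips exactly to
#' well below 4 decimals. `read_transitions()` accepts files without the
#' optional `expected_rt` column and reports malformed or negative-m/z rows
#' with their line number.
#'
#' @param db A `transition_db`.
#' @param path File path.
#' @return `write_transitions()` returns `path` invisibly;
#'   `read_transitions()` returns a `transition_db`.
#' @export
write_transitions <- function(db, path) {
  stopifnot(inherits(db, "transition_db"))
  out <- data.frame(
    structure = db$structure,
    n_residues = db$n_residues,
    precursor_mz = sprintf("%.8f", db$precursor_mz),
    product_mz = sprintf("%.8f", db$product_mz),
    ion_label = db$ion_label,
    expected_rt = ifelse(is.na(db$expected_rt), "",
                         sprintf("%.4f", db$expected_rt))
  )
  utils::write.csv(out, path, row.names = FALSE,
                   quote = which(names(out) == "structure"))
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("structure", "precursor_mz", "product_mz", "ion_label")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("transition file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("precursor_mz", "product_mz")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop("parse error in ", path, " line ", bad[1] + 1L,
           ": non-positive or non-numeric ", col, call. = FALSE)
    }
    df[[col]] <- v
  }
  if (!"expected_rt" %in% names(df)) {
    df$expected_rt <- NA_real_
  } else {
    df$expected_rt <- suppressWarnings(as.numeric(df$expected_rt))
  }
  if (!"n_residues" %in% names(df)) df$n_residues <- NA_integer_
  new_transition_db(df)
}
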