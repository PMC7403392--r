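#' Aggregate detection calls for one sample into an evidence record
#'
#' Collapses a sample's per-structure detection calls to the three MS
#' evidence flags of the per-species summary matrix: `ms_high` (any
#' high-confidence LCO detection, by co-eluting MRM transitions or an
#' untargeted hit), `ms_low` (no high-confidence detection but at least one
#' single-transition detection at the expected retention time) and
#' `co_detected` (any chitooligosaccharide precursor detected). `ms_high`
#' and `ms_low` are mutually exclusive: the sample is reported at its
#' maximum tier. Wet-lab bioassay flags (root-hair branching, reporter-gene
#' induction) are externally supplied pass-through booleans, never computed
#' here.
#'
#' @param sample Sample/species label.
#' @param lco_calls Detection calls from [match_mrm()] on the LCO panel.
#' @param co_calls Optional detection calls on the CO panel.
#' @param untargeted_hit Logical: did untargeted annotation identify an LCO
#'   in this sample?
#' @param bioassay Optional named logical vector of externally measured
#'   bioassay outcomes, carried through unchanged.
#' @return One-row data.frame: `sample`, `ms_high`, `ms_low`, `co_detected`,
#'   plus any bioassay columns.
#' @export
aggregate_sample <- function(sample, lco_calls, co_calls = NULL,
                             untargeted_hit = FALSE, bioassay = NULL) {
  tiers <- if (!is.null(lco_calls) && nrow(lco_calls)) lco_calls$tier else
    character(0)
  ms_high <- any(tiers == "high") || isTRUE(untargeted_hit)
  ms_low <- !ms_high && any(tiers == "low")
  co_detected <- !is.null(co_calls) && nrow(co_calls) > 0 &&
    any(co_calls$tier != "none")
  rec <- data.frame(sample = sample, ms_high = ms_high, ms_low = ms_low,
                    co_detected = co_detected)
  if (!is.null(bioassay)) {
    stopifnot(is.logical(bioassay), !is.null(names(bioassay)))
    for (nm in names(bioassay)) rec[[nm]] <- bioassay[[nm]]
  }
  rec
}

#' Evidence matrix across samples
#'
#' One row per sample, one logical column per evidence flag; `FALSE` means
#' "no detection" (a clear symbol in the usual graphical summary). Rows keep
#' their first-appearance order; duplicate sample labels are merged with a
#' logical OR (logged), so merging is idempotent and adding evidence never
#' clears a flag.
#'
#' @param records data.frame of evidence records from [aggregate_sample()]
#'   (rows may repeat sample labels).
#' @return A data.frame, one row per distinct sample.
#' @export
evidence_matrix <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            "sample" %in% names(records))
  flags <- setdiff(names(records), "sample")
  dup <- duplicated(records$sample)
  if (any(dup)) {
    message("merging duplicate sample label(s): ",
            paste(unique(records$sample[dup]), collapse = ", "))
  }
  samples <- unique(records$sample)
  out <- lapply(samples, function(smp) {
    rows <- records[records$sample == smp, flags, drop = FALSE]
    merged <- as.data.frame(lapply(rows, function(col) any(col, na.rm = TRUE)))
    cbind(data.frame(sample = smp), merged)
  })
  out <- do.call(rbind, out)
  # max-tier rule must survive the OR-merge
  if (all(c("ms_high", "ms_low") %in% names(out))) {
    out$ms_low <- out$ms_low & !out$ms_high
  }
  rownames(out) <- NULL
  out
}

#' Write / read an evidence matrix as TSV
#'
#' @param matrix A data.frame from [evidence_matrix()].
#' @param path File path.
#' @return `write_evidence_matrix()` returns `path` invisibly;
#'   `read_evidence_matrix()` returns the data.frame.
#' @export
write_evidence_matrix <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_evidence_matrix
#' @export
read_evidence_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), "sample")) df[[col]] <- as.logical(df[[col]])
  df
}
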