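#' Read and write chromatogram traces in long-format CSV
#'
#' The long format carries one row per acquired time point:
#' `precursor_mz`, `product_mz`, `rt_min`, `intensity`. This is both the
#' input format of [match_mrm()] and the output format of
#' [simulate_chromatograms()], so simulated data round-trip through disk
#' byte-identically for a fixed seed.
#'
#' @param traces Long-format data.frame.
#' @param path File path.
#' @return `write_traces_csv()` returns `path` invisibly;
#'   `read_traces_csv()` returns the data.frame.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(all(c("precursor_mz", "product_mz", "rt_min", "intensity") %in%
                  names(traces)))
  out <- data.frame(
    precursor_mz = sprintf("%.6f", traces$precursor_mz),
    product_mz = sprintf("%.6f", traces$product_mz),
    rt_min = sprintf("%.6f", traces$rt_min),
    intensity = sprintf("%.6f", traces$intensity)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("precursor_mz", "product_mz", "rt_min", "intensity")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trace file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Read SRM chromatograms from an mzML file
#'
#' Extracts the selected-reaction-monitoring chromatogram list of a
#' standard mzML file into the long-format trace table used throughout the
#' package. Chromatograms without both a precursor and a product isolation
#' target (e.g. the TIC) are skipped. Retention times are converted to
#' minutes if the file stores seconds.
#'
#' @param path Path to an mzML file.
#' @param time_in_seconds Logical; set `FALSE` if the file already stores
#'   minutes (default `TRUE`, the mzML convention).
#' @return Long-format data.frame (`precursor_mz`, `product_mz`, `rt_min`,
#'   `intensity`).
#' @export
read_traces_mzml <- function(path, time_in_seconds = TRUE) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::chromatogramHeader(handle)
  keep <- which(!is.na(hdr$precursorIsolationWindowTargetMZ) &
                  !is.na(hdr$productIsolationWindowTargetMZ))
  out <- lapply(keep, function(i) {
    ch <- mzR::chromatogram(handle, hdr$chromatogramIndex[i])
    t <- ch[, 1]
    if (time_in_seconds) t <- t / 60
    data.frame(precursor_mz = hdr$precursorIsolationWindowTargetMZ[i],
               product_mz = hdr$productIsolationWindowTargetMZ[i],
               rt_min = t, intensity = ch[, 2])
  })
  if (!length(out)) {
    return(data.frame(precursor_mz = numeric(0), product_mz = numeric(0),
                      rt_min = numeric(0), intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Read untargeted spectra from a two-level CSV
#'
#' One row per product ion: `spectrum_id`, `precursor_mz`, `product_mz`,
#' `intensity`. The format of [match_untargeted()] input and
#' [simulate_untargeted()] output.
#'
#' @param spectra Long-format data.frame.
#' @param path File path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns the data.frame.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(all(c("spectrum_id", "precursor_mz", "product_mz", "intensity")
                %in% names(spectra)))
  out <- data.frame(
    spectrum_id = spectra$spectrum_id,
    precursor_mz = sprintf("%.6f", spectra$precursor_mz),
    product_mz = sprintf("%.6f", spectra$product_mz),
    intensity = sprintf("%.6f", spectra$intensity)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("spectrum_id", "precursor_mz", "product_mz", "intensity")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("spectra file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed[-1]) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write detection calls as TSV or JSON
#'
#' @param calls Detection calls from [match_mrm()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(calls, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(calls, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
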