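#!/usr/bin/env Rscript
# Aggregate per-sample detection calls into the species-level evidence
# matrix: one row per sample, logical flags for high-confidence LCO
# detection, low-confidence LCO detection, and CO detection (FALSE = clear
# symbol, no detection). Bioassay columns, when available, are pass-through
# inputs; here the simulated samples carry none.

library(chitoMRM)

read_calls <- function(name) {
  utils::read.delim(sprintf("results/%s_calls.tsv", name),
                    stringsAsFactors = FALSE)
}

split_lco_co <- function(calls) {
  is_co <- grepl("^CO[0-9]+$", calls$structure)
  list(lco = calls[!is_co, ], co = calls[is_co, ])
}

records <- do.call(rbind, lapply(c("sampleA", "sampleB", "sampleC"),
  function(name) {
    parts <- split_lco_co(read_calls(name))
    aggregate_sample(name, parts$lco, co_calls = parts$co)
  }))

m <- evidence_matrix(records)
write_evidence_matrix(m, "results/evidence_matrix.tsv")
print(m)
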