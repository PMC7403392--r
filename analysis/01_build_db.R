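#!/usr/bin/env Rscript
# Build the theoretical MRM transition database.
#
# Enumerates the default LCO grammar (backbones of 3-5 GlcNAc, even-chain
# fatty acids C12-C22 with 0-3 double bonds, the usual non-reducing and
# reducing-end substituents), computes every precursor [M+H]+ and B-ion m/z,
# and writes the database, its summary statistics, and two reduced panels:
# the CO3-CO6 chitooligosaccharide assay and a small panel of the four
# standard Nod-factor LCOs.

library(chitoMRM)
dir.create("results", showWarnings = FALSE)

grammar <- structure_grammar()
structures <- enumerate_structures(grammar)
cat("enumerated", length(structures), "distinct LCO structures\n")

db <- build_transition_db(structures)
stats <- db_stats(db)
cat(sprintf("database: %d structures, %d unique precursor m/z, %d unique transitions\n",
            stats$structures, stats$precursors_unique_mz,
            stats$unique_transitions))
write_transitions(db, "results/transition_db.csv")
jsonlite::write_json(stats, "results/db_stats.json", auto_unbox = TRUE)

# CO assay: precursors 628/831/1034/1237 -> common B1 204
co_db <- build_transition_db(lapply(3:6, co_structure))
write_transitions(co_db, "results/co_panel.csv")
cat("CO panel (nominal):",
    paste(sprintf("%d->%d", nominal_mz(co_db$precursor_mz[co_db$ion_label == "B1"]),
                  nominal_mz(co_db$product_mz[co_db$ion_label == "B1"])),
          collapse = ", "), "\n")

# reduced LCO panel: the four standard Nod-factor compounds
standards <- c("LCO-IV(C16:0)", "LCO-IV(C16:0,S)",
               "LCO-IV(C18:1)", "LCO-IV(C18:1,S)")
panel <- select_panel(db, names = standards)
write_transitions(panel, "results/lco_standard_panel.csv")
cat("standard LCO panel:", nrow(panel), "transitions for",
    length(standards), "structures\n")
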