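#!/usr/bin/env Rscript
# Simulate MRM acquisitions for three in-silico "exudate samples".
#
# Each sample monitors the same mixed panel (CO3-CO6 plus eight LCOs) and
# plants a different ground-truth structure set: sampleA carries two LCOs
# and one CO at clean intensities, sampleB carries one LCO monitored by a
# single transition with a known expected retention time (the low-confidence
# scenario), and sampleC is blank except for decoy peaks. Traces and truth
# tables go to results/.

library(chitoMRM)
dir.create("results", showWarnings = FALSE)
seed <- 20260927L

structures <- c(
  lapply(3:6, co_structure),
  list(lco_structure(4, acyl_chain(16, 0)),
       lco_structure(4, acyl_chain(16, 0), c(R6 = "S")),
       lco_structure(4, acyl_chain(18, 1)),
       lco_structure(4, acyl_chain(18, 1), c(R6 = "S")),
       lco_structure(5, acyl_chain(18, 1), c(R6 = "Fuc")),
       lco_structure(5, acyl_chain(16, 0), c(R6 = "MeFuc")),
       lco_structure(3, acyl_chain(14, 0)),
       lco_structure(3, acyl_chain(16, 1), c(R6 = "FucS"))))
panel <- build_transition_db(structures)
write_transitions(panel, "results/sim_panel.csv")

# sampleB panel: LCO-IV(C18:1) reduced to its B1 transition, with the
# retention time known from a synthetic standard
panel_b <- panel[!(panel$structure == "LCO-IV(C18:1)" &
                     panel$ion_label != "B1"), ]
class(panel_b) <- c("transition_db", "data.frame")
panel_b$expected_rt[panel_b$structure == "LCO-IV(C18:1)"] <- 6.9
write_transitions(panel_b, "results/sim_panel_b.csv")

samples <- list(
  sampleA = list(panel = panel, cfg = sim_config(
    data.frame(structure = c("LCO-IV(C16:0,S)", "LCO-V(C18:1,Fuc)", "CO4"),
               rt = c(6.2, 7.8, 2.4)),
    noise_sd = 5, decoys_on_panel = 3, decoys_off_panel = 2, seed = seed)),
  sampleB = list(panel = panel_b, cfg = sim_config(
    data.frame(structure = "LCO-IV(C18:1)", rt = 6.9),
    noise_sd = 5, seed = seed + 1L)),
  sampleC = list(panel = panel, cfg = sim_config(
    data.frame(structure = character(0), rt = numeric(0)),
    noise_sd = 5, decoys_on_panel = 4, decoys_off_panel = 2,
    seed = seed + 2L))
)

for (name in names(samples)) {
  sim <- simulate_chromatograms(samples[[name]]$panel, samples[[name]]$cfg)
  write_traces_csv(sim$traces, sprintf("results/%s_traces.csv", name))
  utils::write.table(sim$truth, sprintf("results/%s_truth.tsv", name),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat(name, ": ", sum(sim$truth$transitions_emitted), " planted transitions (",
      sum(sim$truth$transitions_dropped), " dropped)\n", sep = "")
}
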