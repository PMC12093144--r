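#!/usr/bin/env Rscript
# Circularization efficiencies from simulated qPCR Ct tables for a WT-like
# construct panel: full Alu deletions ablate circles, partial deletions of
# the downstream Alu retain near-WT efficiency.
#
# Writes: results/qpcr_ct.csv, results/qpcr_efficiency.csv

library(circscaffold)
dir.create("results", showWarnings = FALSE)

ratios <- c(WT = 1.00, d157AluSq2 = 0.95, d189AluSq2 = 0.90,
            dAluSz = NA, dAluSq2 = NA, ddAlu = NA)
ct <- gen_qpcr_table(ratios, ct_noise_sd = 0.15, n_replicates = 3, seed = 71)
utils::write.csv(ct, "results/qpcr_ct.csv", row.names = FALSE)

eff <- circularization_table(read_qpcr_csv("results/qpcr_ct.csv"))
utils::write.csv(eff, "results/qpcr_efficiency.csv", row.names = FALSE)
cat("circularization efficiency (circRNA / pre-mRNA, each normalized 2^-dCt):\n")
print(eff[, c("construct", "efficiency", "efficiency_sd", "detected")],
      digits = 3)
cat("\nfull Alu deletions report 0 (undetected); partial deletions stay near WT\n")
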