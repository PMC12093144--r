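#!/usr/bin/env Rscript
# Circularization enrichment by flank pattern: log-odds differences against
# the No-Alus baseline with case-bootstrap CIs, plus downstream-Alu length
# distributions (no length filter).
#
# Reads:  results/classified.tsv, results/genome/*
# Writes: results/enrichment.tsv, results/alu_length_distributions.tsv,
#         results/enrichment_violin.pdf (when ggplot2 is installed)

library(circscaffold)

classified <- utils::read.delim("results/classified.tsv")
et <- enrichment_table(classified, baseline = "NONE", B = 1000, seed = 42)
utils::write.table(et, "results/enrichment.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("log-odds enrichment vs the No-Alus baseline:\n")
print(et, digits = 3)
cat(sprintf("\nIR exons are %.2f log-odds units (odds ratio %.2f) more likely to circularize\n",
            et$diff[et$pattern == "IR"], exp(et$diff[et$pattern == "IR"])))

exons <- read_bed("results/genome/exons.bed", "bed6")
alus <- read_bed("results/genome/alus.bed", "bed6")
circs <- read_bed("results/genome/circs.bed12", "bed12")
lens <- downstream_alu_lengths(exons, alus, circs)
lt <- rbind(data.frame(group = "circularizing", length = lens$circ),
            data.frame(group = "non_circularizing", length = lens$noncirc))
utils::write.table(lt, "results/alu_length_distributions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
mw <- mann_whitney_u(lens$circ, lens$noncirc, mode = "normal_approx")
cat(sprintf("downstream Alu length medians: circ %.0f vs non-circ %.0f (MWU p = %.3f)\n",
            median(lens$circ), median(lens$noncirc), mw$p))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  bs <- do.call(rbind, lapply(setdiff(FLANK_PATTERNS, "NONE"), function(p) {
    b <- bootstrap_log_odds(classified, p, "NONE", B = 1000, seed = 42)
    data.frame(pattern = p, diff = b$bootstrap_samples)
  }))
  gg <- ggplot2::ggplot(bs, ggplot2::aes(pattern, diff)) +
    ggplot2::geom_violin(fill = "firebrick", alpha = 0.5) +
    ggplot2::labs(y = "difference in log odds ratio vs No Alus", x = NULL) +
    ggplot2::theme_classic()
  ggplot2::ggsave("results/enrichment_violin.pdf", gg, width = 5, height = 4)
}
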