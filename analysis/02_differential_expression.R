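#!/usr/bin/env Rscript
# Stage 2 — two-group differential expression for all three RNA layers.
#
# TMM-normalized counts are tested per feature with the conditional
# negative-binomial exact test under a common dispersion. circRNAs and
# mRNAs are called at |log2FC| >= 1 with BH q <= 0.05; miRNAs at raw
# p <= 0.05. Two contrasts are analyzed: ovarian development (Som vs Stm)
# and fecundity (Sad vs Ud).

suppressPackageStartupMessages(library(cernapipe))

design <- read_design("results/data/design.tsv")
cfg <- cerna_config(rng_seed = 1)
contrasts <- list(c("Som", "Stm"), c("Sad", "Ud"))
dir.create("results/de", recursive = TRUE, showWarnings = FALSE)

for (ct in contrasts) {
  nm <- paste(ct, collapse = "_vs_")
  for (layer in c("circRNA", "mRNA", "miRNA")) {
    counts <- read_counts(sprintf("results/data/counts_%s.tsv", layer),
                          design)
    de <- call_de(counts, design, ct, layer, cfg)
    cernapipe:::write_tsv(de, sprintf("results/de/de_%s_%s.tsv", layer, nm))
    cat(sprintf("%-10s %-9s up %3d  down %3d  ns %3d\n", nm, layer,
                sum(de$call == "up"), sum(de$call == "down"),
                sum(de$call == "ns")))
  }
}
cat("wrote results/de\n")
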