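#!/usr/bin/env Rscript
# Stage 3 — sequence-based target prediction for the differential features.
#
# Differentially expressed miRNAs (either contrast) are scanned against the
# 3'UTRs of differential mRNAs and the (circular) sequences of differential
# circRNAs. A pair is kept when its best seed site scores >= 50 on the
# 0-100 scale AND its nearest-neighbor duplex energy is <= -10 kcal/mol —
# the two-filter intersection used to call miRNA targets.

suppressPackageStartupMessages(library(cernapipe))

cfg <- cerna_config(rng_seed = 1)
de_ids <- function(path) {
  d <- read.delim(path)
  d$feature_id[d$call != "ns"]
}
dem <- unique(c(de_ids("results/de/de_miRNA_Som_vs_Stm.tsv"),
                de_ids("results/de/de_miRNA_Sad_vs_Ud.tsv")))
dec <- unique(c(de_ids("results/de/de_circRNA_Som_vs_Stm.tsv"),
                de_ids("results/de/de_circRNA_Sad_vs_Ud.tsv")))
deg <- unique(c(de_ids("results/de/de_mRNA_Som_vs_Stm.tsv"),
                de_ids("results/de/de_mRNA_Sad_vs_Ud.tsv")))

mirs <- read_fasta("results/data/miRNA.fasta", "miRNA")
utrs <- read_fasta("results/data/utr3.fasta", "utr3")
circs <- read_fasta("results/data/circRNA.fasta", "circRNA")

pairs <- predict_pairs(mirs[mirs$id %in% dem, ],
                       rbind(circs[circs$id %in% dec, ],
                             utrs[utrs$id %in% deg, ]), cfg)
dir.create("results/targets", recursive = TRUE, showWarnings = FALSE)
cernapipe:::write_tsv(pairs, "results/targets/target_pairs.tsv")

cat(sprintf("DE features scanned: %d miRNAs x (%d circRNAs + %d 3'UTRs)\n",
            length(dem), sum(circs$id %in% dec), sum(utrs$id %in% deg)))
cat("retained pairs by target kind:\n")
print(table(pairs$target_kind))
cat("site types among retained pairs:\n")
print(table(pairs$site_type))
cat("wrote results/targets/target_pairs.tsv\n")
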