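#!/usr/bin/env Rscript
# Stage 4 — sign-constrained correlation network and ceRNA triads.
#
# Within each contrast, candidate pairs among differential features with
# predicted binding are filtered by Pearson correlation on log2(CPM+1):
# circRNA-miRNA and miRNA-mRNA pairs must satisfy r <= -0.4, circRNA-mRNA
# pairs r >= +0.4, all at p <= 0.05. Triads sharing a miRNA across all
# three edge classes form the ceRNA network. The per-contrast networks are
# reduced to the intersection of the top-10 miRNAs by pair degree (the
# core), then integrated across contrasts over the reproduction-associated
# gene set, and exported in Cytoscape-loadable SIF plus GraphML.

suppressPackageStartupMessages(library(cernapipe))

design <- read_design("results/data/design.tsv")
cfg <- cerna_config(rng_seed = 1)
contrasts <- list(c("Som", "Stm"), c("Sad", "Ud"))
counts <- list(
  circRNA = read_counts("results/data/counts_circRNA.tsv", design),
  mRNA = read_counts("results/data/counts_mRNA.tsv", design),
  miRNA = read_counts("results/data/counts_miRNA.tsv", design))
pairs <- read.delim("results/targets/target_pairs.tsv")
dir.create("results/network", recursive = TRUE, showWarnings = FALSE)

triads <- list()
for (ct in contrasts) {
  nm <- paste(ct, collapse = "_vs_")
  de <- lapply(c(circRNA = "circRNA", mRNA = "mRNA", miRNA = "miRNA"),
               function(l) read.delim(
                 sprintf("results/de/de_%s_%s.tsv", l, nm)))
  edges <- build_pairs(de, pairs, counts, design, ct, cfg)
  tr <- assemble_triads(edges)
  triads[[nm]] <- tr
  cernapipe:::write_tsv(tr, sprintf("results/network/triads_%s.tsv", nm))
  write_network(triads_to_edges(tr),
                sprintf("results/network/network_%s.sif", nm), "sif")
  write_network(triads_to_edges(tr),
                sprintf("results/network/network_%s.graphml", nm),
                "graphml")
  cat(sprintf("%-12s edges: %d sponge, %d target, %d circ-mRNA; triads: %d\n",
              nm, nrow(edges$circ_mir), nrow(edges$mir_mrna),
              nrow(edges$circ_mrna), nrow(tr)))

  # bipartite DEM-DEG regulatory network for this contrast
  dd <- dem_deg_network(de$miRNA, de$mRNA, pairs, counts, design, ct, cfg)
  cernapipe:::write_tsv(dd, sprintf("results/network/dem_deg_%s.tsv", nm))
  cat(sprintf("%-12s DEM-DEG edges: %d (%d miRNAs x %d mRNAs)\n", nm,
              nrow(dd), length(unique(dd$node_a)),
              length(unique(dd$node_b))))
}

core <- select_core(triads, k = cfg$top_k_mirnas)
writeLines(core$mirnas, "results/network/core_mirnas.txt")
cat(sprintf("core miRNAs (top-%d intersection): %d\n", cfg$top_k_mirnas,
            length(core$mirnas)))

# reproduction-associated screen: the first annotation term's gene set
ann <- read.delim("results/data/annotation.tsv")
whitelist <- ann$gene_id[ann$term_id == "TERM:0001"]
ig <- integrate_networks(core$triads[[1]], core$triads[[2]], whitelist)
cernapipe:::write_tsv(ig$triads, "results/network/integrated_triads.tsv")
cernapipe:::write_tsv(ig$pairs, "results/network/integrated_pairs.tsv")
cat(sprintf(
  "integrated network: %d triads over %d circRNAs / %d miRNAs / %d mRNAs, %d interaction pairs\n",
  nrow(ig$triads), length(unique(ig$triads$circ_id)),
  length(unique(ig$triads$mir_id)), length(unique(ig$triads$mrna_id)),
  nrow(ig$pairs)))
cat("wrote results/network\n")
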