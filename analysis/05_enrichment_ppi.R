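#!/usr/bin/env Rscript
# Stage 5 — functional enrichment of network targets and PPI hub analysis.
#
# The mRNAs recruited into the ceRNA networks are tested for term
# enrichment against the annotation universe with the upper-tail
# hypergeometric test (BH within namespace), and the synthetic PPI table
# is filtered at confidence >= 0.40 to rank hub genes by degree.

suppressPackageStartupMessages(library(cernapipe))

cfg <- cerna_config(rng_seed = 1)
ann <- read.delim("results/data/annotation.tsv")
universe <- unique(ann$gene_id)
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

tr1 <- read.delim("results/network/triads_Som_vs_Stm.tsv")
tr2 <- read.delim("results/network/triads_Sad_vs_Ud.tsv")
query <- intersect(unique(c(tr1$mrna_id, tr2$mrna_id)), universe)
cat(sprintf("query: %d network mRNAs against a universe of %d genes\n",
            length(query), length(universe)))

en <- hypergeom_enrich(query, ann, universe)
cernapipe:::write_tsv(en, "results/enrichment/enrichment.tsv")
cernapipe:::write_tsv(pathway_gene_table(en),
                      "results/enrichment/pathway_genes.tsv")
cat("top enriched terms:\n")
print(head(en[, c("term_id", "term_name", "k", "K", "p", "q")], 5),
      row.names = FALSE)

ppi <- read.delim("results/data/ppi.tsv")
ph <- ppi_filter_and_hubs(ppi, min_conf = cfg$ppi_conf_min, top_n = 5)
cernapipe:::write_tsv(ph$edges, "results/enrichment/ppi_edges.tsv")
cernapipe:::write_tsv(ph$hubs, "results/enrichment/ppi_hubs.tsv")
cat(sprintf("PPI: %d/%d edges at confidence >= %.2f; top hubs:\n",
            nrow(ph$edges), nrow(ppi), cfg$ppi_conf_min))
print(ph$hubs, row.names = FALSE)
cat("wrote results/enrichment\n")
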