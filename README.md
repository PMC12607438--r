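# cernapipe

Inference of circRNA–miRNA–mRNA competing endogenous RNA (ceRNA) networks
from grouped RNA-seq count matrices of three layers, for transcriptomics
studies that profile circRNAs, miRNAs and mRNAs across the same samples
(e.g. ovarian tissue across developmental stages and fecundity phenotypes)
and want the sponge axes those layers jointly support.

A sponge axis circRNA–miRNA–mRNA must survive a cascade of filters:

* **Differential expression** per layer and two-group contrast, tested with
  an exact conditional negative-binomial test on TMM-normalized,
  library-equalized counts. Conditional on the total *t* of the two group
  sums, `Pr(S_A = s | t) ∝ C(s + n_A/φ − 1, s) · C(t − s + n_B/φ − 1, t − s)`,
  with the two-sided p summing all splits at most as likely as the observed
  one. circRNA/mRNA calls: |log2FC| ≥ 1 and BH q ≤ 0.05; miRNA calls:
  p ≤ 0.05.
* **Predicted binding**: canonical seed sites (6mer / 7mer-A1 / 7mer-m8 /
  8mer, with back-splice-junction-spanning sites on circRNAs) scored on a
  0–100 scale (base points + AU-context bonus) and by a nearest-neighbor
  duplex free energy (kcal/mol). A pair passes at score ≥ 50 **and**
  energy ≤ −10.
* **Sign-constrained Pearson correlation** on log2(CPM+1): r ≤ −0.4 for
  circRNA–miRNA and miRNA–mRNA, r ≥ +0.4 for circRNA–mRNA, all at p ≤ 0.05.
* **Triad assembly, core selection, integration**: triads share a miRNA
  across all three edge classes; per-contrast top-10 miRNAs by relationship
  pair degree are intersected into a core, and cores from two contrasts are
  integrated over a gene set of interest.

Hypergeometric term enrichment (BH within namespace), confidence-filtered
PPI hub ranking and a 2^−ΔΔCt qPCR utility round out the pipeline. A
synthetic-data module generates the full study design — negative-binomial
counts with planted sponge axes, miRNA/3'UTR/circRNA sequences carrying
real seed sites — so every stage is testable end to end with no downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package API.
`Rscript analysis/01_simulate.R` generates the four-group × three-replicate
study (groups Som, Stm, Sad, Ud; 300 mRNAs, 80 circRNAs, 60 miRNAs, 10
planted axes of 3 log2 units) under `results/data/`, and the later stages
print, for example:

```
$ Rscript analysis/02_differential_expression.R
Som_vs_Stm circRNA   up   7  down   8  ns  65
Som_vs_Stm mRNA      up   9  down  15  ns 276
Som_vs_Stm miRNA     up  12  down   8  ns  40
...

$ Rscript analysis/04_cerna_network.R
Som_vs_Stm   edges: 9 sponge, 10 target, 8 circ-mRNA; triads: 8
Sad_vs_Ud    edges: 9 sponge, 11 target, 9 circ-mRNA; triads: 9
core miRNAs (top-10 intersection): 8
integrated network: 8 triads over 8 circRNAs / 8 miRNAs / 8 mRNAs, 16 interaction pairs

$ Rscript analysis/05_enrichment_ppi.R
top enriched terms:
   term_id            term_name k  K            p            q
 TERM:0001 reproductive process 9 30 7.531779e-10 6.778601e-09
 ...
```

Reading: each contrast calls ~15 differential circRNAs, ~20 miRNAs and
~24 mRNAs (10 of each planted); binding plus correlation filtering
assembles 8–9 triads per contrast, nearly all of them planted axes; the
core/integration step reduces the two networks to the 16 interaction pairs
they share over the reproduction-associated gene set, and those mRNAs are
strongly enriched for the term the generator seeded them into
(q ≈ 7 × 10⁻⁹). Networks are exported as Cytoscape-loadable SIF
(`sponges` / `targets` relations) and GraphML.

The same machinery is available programmatically:

```r
library(cernapipe)
res <- run_pipeline(cerna_config(rng_seed = 1, out_dir = "cerna_run"))
score_recovery(res$triads[[1]], res$dataset$truth)
#> $recall [1] 0.8   $unplanted [1] 0   $n_triads [1] 8
```

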