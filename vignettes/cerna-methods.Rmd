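---
title: "Methods: ceRNA network inference from three-layer count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference from three-layer count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernapipe)
```

## The model

Competing endogenous RNA (ceRNA) regulation posits that circRNAs sequester
miRNAs through shared response elements, de-repressing the miRNAs' mRNA
targets. The observable signature of a sponge axis
circRNA–miRNA–mRNA in expression data is therefore a sign pattern: the
miRNA is negatively correlated with both the circRNA and the mRNA, while
circRNA and mRNA are positively correlated, and all three members respond
to the biological contrast. `cernapipe` operationalizes this as a filter
cascade over three count layers:

1. **Differential expression** per layer and contrast (exact
   negative-binomial test, below), with circRNA/mRNA calls at
   $|\log_2 FC| \ge 1$ and BH $q \le 0.05$ and miRNA calls at raw
   $p \le 0.05$ (miRNA layers are small; the raw-p rule is deliberate and
   configurable).
2. **Sequence-based binding** between differential miRNAs and the
   sequences of differential circRNAs / mRNA 3'UTRs, requiring a site
   score $\ge 50$ (0–100 scale) *and* a duplex free energy
   $\le -10$ kcal/mol — an intersection of a context-style and an
   energy-style predictor.
3. **Sign-constrained correlation** on $\log_2(\mathrm{CPM}+1)$ profiles:
   $r \le -0.4$ for circRNA–miRNA and miRNA–mRNA, $r \ge +0.4$ for
   circRNA–mRNA, all at $p \le 0.05$ (two-sided t, $n-2$ df). The positive
   threshold mirrors the negative one symmetrically; both are
   configurable, as is the sample set used (contrast groups, the default,
   or all samples).
4. **Triad assembly**: a triple is a ceRNA triad when all three edges
   exist for a shared miRNA.
5. **Core selection and integration** across two contrasts: per contrast,
   miRNAs are ranked by the number of unique relationship pairs they
   appear in (degree over circRNA–miRNA plus miRNA–mRNA pairs; ties by
   id), the top-$k$ sets ($k=10$) are intersected, and triads whose
   (miRNA, mRNA) identity is shared by both cores and whose mRNA lies in a
   user-supplied gene set (e.g. reproduction-associated genes) form the
   integrated network. "Interaction probability" rankings in this
   literature are rarely pinned down; pair degree is the one quantity
   defined per miRNA across relationship pairs, so it is the default and
   the ranking is pluggable.

No correlation p-value is multiplicity-adjusted (step 3 uses raw
$p \le 0.05$): the triad definition is a conjunction of three tests plus
two binding filters plus three DE filters, and the label-permutation
control below measures what that conjunction lets through.

## The exact negative-binomial test

Counts are normalized with trimmed-mean-of-M-values (TMM) factors in the
standard convention: M- and A-values on library-scaled proportions against
a reference sample, 30%/5% trim, precision-weighted mean, factors rescaled
to geometric mean 1. Factors correct composition, not depth; effective
library size is depth × factor.

For a two-group test the per-sample counts are first scaled to the
geometric mean effective library size (rounded half to even), which makes
the replicate group sums $S_A, S_B$ negative-binomial convolutions with a
shared success parameter. Conditional on the total $t = S_A + S_B$ the
split distribution is free of the unknown mean,

$$\Pr(S_A = s \mid t) \propto
  \binom{s + n_A/\phi - 1}{s}\binom{t - s + n_B/\phi - 1}{t - s},$$

with $n_A, n_B$ replicate counts and $\phi$ the common dispersion
(variance $\mu + \phi\mu^2$; $\phi = 0$ reduces the split law to the
Poisson-limit binomial). The two-sided p-value follows the
minimum-likelihood rule — the sum of the probabilities of all splits at
most as likely as the observed one (with the usual $1 + 10^{-7}$ tie
tolerance) — which is exhaustively enumerable and is checked against an
independent enumeration oracle in the tests. The symmetric split returns
$p = 1$ exactly.

The common dispersion is a deliberately simple method-of-moments
estimate: per feature and replicated group, $(s^2 - \bar x)/\bar x^2$ on
library-equalized counts, averaged over groups, median over features,
floored at zero. It is estimated from **all** replicated groups of the
design, not only the contrast pair — within-group variance is unaffected
by group offsets, and at $2\times 3$ replicates the median estimate is
noticeably biased low (the per-group statistic has $\chi^2_2$-type skew).
Even with four groups a residual downward bias of roughly 10% remains, so
the raw-p miRNA rule runs mildly liberal: in null simulations at the
generator's conditions the $p<0.05$ fraction sits near 0.05–0.07 rather
than at 0.05. Supplied with the true dispersion the test itself is
calibrated-to-conservative (0.04–0.05). Tagwise or trended shrinkage is
out of scope by design.

$\log_2$ fold changes are computed on group-mean CPM with a 0.5
pseudocount, `log2((CPM_B + 0.5) / (CPM_A + 0.5))`, for contrast "A vs B".

## The binding model

Canonical seed sites are found by exact string matching: a 6mer core
wherever the target carries the reverse complement of miRNA positions
2–7, upgraded to 7mer-m8 (pairing extends to position 8), 7mer-A1 (target
adenine opposite position 1) or 8mer (both). All windows are reported;
overlapping sites are not merged. Coordinates are 0-based starts of the
core on the target as given (5'→3', no reverse-strand scan). circRNAs are
scanned with their first 7 nt appended so back-splice-junction-spanning
sites are found, each circular window counted once.

The 0–100 site score is transparent rather than a re-derivation of any
published context model: base points 30/50/60/75 for
6mer/7mer-A1/7mer-m8/8mer plus $25 \times$ (A/U fraction of the ±30 nt
flanks), clamped to $[0, 100]$. It preserves the two properties the
pipeline needs — site-type ordering and AU-context reward — and makes the
"score ≥ 50" threshold meaningful: a 6mer can never pass on its own.

Duplex free energy is a simplified nearest-neighbor sum: +4.09 kcal/mol
initiation plus stacking terms over consecutive pairs in the seed duplex
and in the longest contiguous complementary block between the miRNA 3'
region and the 20 nt of target upstream of the site. The stack table
ships with the package (Turner-style values for the sixteen Watson–Crick
stacks; fixed mildly stabilizing constants for wobble-containing stacks);
every entry is negative, so more pairing always lowers the energy. G:U
wobbles are allowed in the supplementary block, never in the seed. The
supplementary search window is miRNA positions 12–21: the canonical
supplementary region (13–17) alone cannot hold the $\ge 6$ nt blocks the
planted sites carry, and with AU-rich seeds a 6-nt block leaves planted
duplexes at only −8 to −9.5 kcal/mol — above the −10 cutoff — so the
generator plants 9-nt blocks (reverse complement of positions 13–21) and
the energy model credits them.

## The synthetic-data generator

The generator emulates the study design this pipeline targets: four
groups (e.g. two ovarian developmental stages and two fecundity
phenotypes) × three replicates, twelve samples. Defaults: 300 mRNAs, 80
circRNAs, 60 miRNAs, 10 planted axes, effect size 3 log2 units,
dispersion $\phi = 0.05$, log-normal baselines (mean 150), library
factors log-uniform in $[0.7, 1.4]$, plus 20/10/8 non-axis DE features
per layer so the DE lists contain more than the axes. Counts are
$\mathrm{NB}(\mu = \mathrm{baseline}\times 2^{\mathrm{offset}}\times
\mathrm{libfactor},\ \phi)$.

Planted axes receive an alternating $\pm\,\mathrm{effect}/2$ group
profile on the miRNA and the negated profile on its circRNA and mRNA
partners, so anti-correlation is induced **through shared group-level
effects**, not per-sample latent noise; adjacent-group contrasts see the
full effect. Sequences: miRNAs are 20–24 nt (mode 22) with a 5' uridine
at probability 0.8; 3'UTRs 150–400 nt; circRNAs 200–1500 nt (within the
200–20,000 nt range typical of exonic circRNAs, kept short for desk-scale
scanning; typical circRNAs circularize a handful of exons). Every planted
(miRNA, target) pair carries one exact 8mer site plus the 9-nt
supplementary block; decoys are scrubbed of 7mer-or-better sites for
planted miRNAs (checked on the circular extension for circRNAs).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: read-level artifacts (the NB law is exact by
construction, with no QC, mapping or junction-calling noise), isoform
structure, shared miRNA families and overlapping target repertoires,
conservation signal, tagwise dispersion, and correlated baselines between
host genes and their circRNAs. Recovery rates on this generator are an
upper bound on what identical thresholds achieve on sequencing data.

One deliberate consequence of the shared-group-effect design: label
permutation breaks differential expression but **not** the sample-level
correlations, and all planted axes share one high/low sample partition.
The permuted-label control is therefore heavy-tailed — most permutations
yield zero triads, an occasional permutation re-aligns with the planted
partition and recovers several — and its mean sits near one triad per run
at defaults, rather than at zero.

## Numerical and degenerate-input conventions

* Equalized counts are rounded half to even; pseudocount 0.5 on CPM.
* BH is the standard step-up (`stats::p.adjust`), order-preserving;
  enrichment q-values are adjusted within annotation namespace.
* Pearson $r = \pm 1$ maps to the smallest representable positive p;
  constant profiles return an explicit degenerate record, never a silent
  zero, and degenerate edges are dropped.
* Best site per pair: maximal score, ties by lower energy, then smaller
  position. All pipeline tables are sorted deterministically; one master
  seed drives every stage through per-stage derived seeds, so identical
  configurations reproduce byte-identical run directories.
* Thresholds named `*_max`/`*_min` are inclusive; `q_max = 0` silences
  every circRNA/mRNA call (p-values are strictly positive).
* Empty DE tables propagate as empty (not failing) edge sets with a
  warning; a failing stage aborts with the stage name.
* The hypergeometric universe is the annotated gene set supplied by the
  user, not a genome; terms without query overlap are skipped.

## Problem sizes used by the test-suite

Unit and acceptance checks run at desk scale, chosen to keep the full
suite around a minute while leaving Monte-Carlo bands well separated from
their thresholds: exact-test enumeration sweeps totals ≤ 50 for three
replicate designs and $\phi \in \{0, 0.1, 0.5\}$; type-I calibration uses
2000 null features; planted-axis recovery averages 20 simulated datasets
at generator defaults (mean recall ≥ 0.8, unplanted fraction ≤ 0.2)
plus ten permuted-label controls; the seed-site oracle covers 100 random
miRNA/target pairs including circular targets.

## Known limitations

* The site score and energy model are declared stand-ins on the
  conventional scales; they are not TargetScan context++ or a full
  hybridization fold, and conservation, CLIP support and non-canonical
  sites are out of scope.
* Classic exact test only: no GLM/quasi-likelihood path, no multi-factor
  designs, no tagwise dispersion.
* Correlation-based triad filtering cannot separate direct sponging from
  co-regulation; partial-correlation/sensitivity-style ceRNA scores are
  intentionally out of scope.
* Enrichment ignores the term DAG and pathway topology.
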