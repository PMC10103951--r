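# circtype

Downstream analysis of circular RNA (circRNA) back-splice junction (BSJ)
calls from cell-type-resolved RNA-seq, built for the question: *which
circRNAs are tailored to the identity of a cell type, and what do their
host loci tell us about disease?* The intended users are transcriptomics
analysts working with circRNA call tables (circExplorer-style BED12+),
BSJ count matrices and paired RNase-R treated/mock libraries — typically
from brain cell types (dopamine neurons, pyramidal neurons, non-neuronal
cells), where protected raw data often cannot travel with the analysis.
A first-class synthetic-data generator reproduces the statistical
structure the methods assume, so the entire workflow is testable without
access to any restricted dataset.

## What it computes

**Validation filtering.** A circRNA is *expressed* when its unique BSJ
reads summed over samples reach 2, and *validated* when at least one
RNase-R treated/mock pair shows ≥ 20 raw treated reads together with
≥ 2-fold library-scaled enrichment of treated over mock (RNase R digests
linear RNA but spares circles, so a true circle is enriched and a linear
artifact depleted).

**Cell-type specificity.** For a circRNA with mean expression profile
across cell groups expressed as a density of (RPM + 1),

    S(c, i) = 1 − JSD(p_c, q̂_i)

where JSD is the Jensen–Shannon *distance* (square root of the base-2
Jensen–Shannon divergence) and q̂_i is the unit vector of perfect
expression in group *i*. A circRNA is specific to group *i* when
S ≥ 0.5 and its group-mean RPM exceeds the across-sample mean plus one
standard deviation of its expression; disease samples are excluded so
disease-driven shifts cannot masquerade as cell-type identity.

**Locus architecture.** Host genes are classified as *exclusive*
producers (all specific circRNAs in one group) or *super-hosts* (distinct
specific back-spliced variants tailored to two or more groups), and each
circRNA gets a circular-to-linear ratio
`circ / (mean(donor, acceptor) + 1)` compared between neurons and
non-neurons by a Mann–Whitney test.

**Genomic features.** Flanking intron lengths, interval-track overlaps
(repeats, RBP eCLIP peaks), circRNAs-per-gene versus exon count, and the
fraction of GWAS SNPs within 1 Mb of a circRNA.

**Enrichment.** One-sided Fisher's exact over-representation of host
genes in gene sets (hypergeometric upper tail on k, K, n, N with BH FDR
and greedy Jaccard term slimming) and in disease–gene associations
filtered at GDA score > 0.1.

**Differential expression.** circRNA counts aggregated to host genes,
median-of-ratios size factors, and a per-gene negative-binomial GLM with
sex, age, PMI and RIN as covariates; the condition effect is reported as
a Wald test.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated study
(300 genes, cell groups DA 20 / PY 20 / NN 7, six RNase-R pairs, 27
ILB cases vs 59 HC controls):

```sh
Rscript analysis/01_simulate.R      # writes results/data/
Rscript analysis/02_filter.R
Rscript analysis/03_specificity.R
Rscript analysis/04_loci_and_features.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_diffexp.R       # tables land in results/
```

With the default seed this prints, among other things:

```
828 candidates; 828 expressed; 584 validated ( 70.5 % )
Cell-type-specific circRNAs (control samples only):
DA NN PY
46 57 63
Locus architecture:
exclusive-DA exclusive-NN exclusive-PY         none   super-host
          27           35           36          136           25
Circular-to-linear ratio, neurons vs non-neurons: medians 0.101 vs 0.034, Mann-Whitney p = 1.57e-174
Mean recovered log2FC on the 35 affected genes: -0.89 (designed -1.0)
```

The 584 validated candidates are exactly the simulated true circles that
survive the RNase-R filter (70.5% of candidates; the generator planted
30% linear artifacts). The specific counts recover the planted ~10% per
group; super-hosts are loci whose specific circRNAs span two or more
groups; the elevated neuronal circular-to-linear ratio and the
case/control fold change are both designed into the generator and
recovered by the analysis.

The same computation is available as a single call:

```r
library(circtype)
ds  <- simulate_dataset(sim_config(seed = 1), outdir = "results/data")
res <- run_pipeline(pipeline_config("results/data", seed = 1), "results/run")
res$summary
```

A single specificity score, for a profile expressed only in dopamine
neurons:

```r
specificity_score(c(DA = 10, PY = 0, NN = 0), "DA")
#> [1] 0.7144261
```

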