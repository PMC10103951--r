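---
title: "circtype: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circtype: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circtype)
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The data model

The unit of observation is a back-splice junction (BSJ): the
non-colinear junction diagnostic of a circular RNA, quantified by the
number of unique reads spanning it. Everything downstream works on a
circRNA-by-sample count matrix plus per-sample metadata (cell type,
condition, sex, age, post-mortem interval in hours, RNA integrity
number, library size in mapped reads). Genomic coordinates are 0-based
half-open (BED convention) everywhere inside the package; GTF input is
converted on read (`gtf_interval_to_bed()`), because the upstream
circRNA callers emit BED and a single internal convention removes a
whole class of off-by-one errors. Cell types map onto three analysis
groups by default — dopamine neurons (DA), pyramidal neurons of temporal
and motor cortex pooled (PY), and blood cells plus fibroblasts pooled as
non-neuronal (NN) — via a configurable table (`default_group_map()`).

## Validation filtering

Two filters are applied in sequence:

* **Expression**: total unique BSJ reads across all samples ≥
  `min_total_reads` (default 2). With fewer than two independent
  back-spliced reads a junction cannot be distinguished from a chimeric
  alignment artifact.
* **RNase-R validation**: RNase R is a 3'→5' exoribonuclease that
  digests linear RNA but not circles, so in a treated/mock library pair
  a true circle is enriched and a linear artifact depleted. A candidate
  is validated when at least one pair shows *both* ≥ `min_treated_reads`
  (default 20) raw reads in the treated library *and* fold enrichment ≥
  `min_fold` (default 2).

Whether the fold should be computed on raw or depth-normalized reads was
an open question; the package scales each library to reads-per-million
before forming the fold, because treated and mock libraries routinely
differ in depth and a raw-count fold would conflate depth with
enrichment. The read floor, in contrast, is applied to *raw* treated
reads, taking the "20 unique reads" requirement literally as evidence
volume. Both thresholds are exposed. Degenerate cases are defined
explicitly: mock = 0 with treated > 0 gives fold +Inf (complete
digestion of the linear background is the expected behaviour of a true
circle) and passes the fold criterion; treated = mock = 0 gives fold 0
and fails. "At least one pair" is a logical OR, with both criteria
required within the *same* pair.

## The specificity score

For circRNA $c$ with mean normalized expression $\mu_{c,i}$ (RPM for
circRNAs, FPKM for linear transcripts) in each of $G$ cell groups, the
expression profile is the density

$$p_c = \frac{\mu_c + 1}{\sum_i (\mu_{c,i} + 1)},$$

and the specificity score for group $i$ is

$$S_{c,i} = 1 - \mathrm{JSD}(p_c,\ \hat q_i),$$

where $\hat q_i$ is the unit vector of perfect expression in group $i$
and JSD is the Jensen–Shannon *distance*: the square root of the
symmetrized, bounded Jensen–Shannon divergence computed with base-2
logarithms. The base-2 / square-root convention makes $S \in [0, 1]$
with the classification threshold $S = 0.5$ attainable in the interior
of the range. The +1 pseudo-count keeps the density strictly positive
(the JSD against a one-hot vector would otherwise be degenerate for any
profile with zeros) and pulls low-expression profiles toward the uniform
density, a deliberate shrinkage: a circRNA seen at 0.1 RPM in one group
and 0 elsewhere should not score as perfectly specific. For three
groups the uniform profile scores $S \approx 0.322$, so the 0.5
threshold sits comfortably between "flat" and "concentrated".

A transcript is classified specific to group $i$ when $S_{c,i} \ge 0.5$
**and** its group-mean expression exceeds the across-sample mean plus
one standard deviation (n−1 denominator) of its expression over all
included samples. "Overall expression" is read as the per-transcript
distribution *across samples* — the only reading in which the standard
deviation does meaningful work. Only control-condition samples enter
the calculation by default, so that disease-state shifts are not
mistaken for cell identity. A transcript is assigned to at most one
group: among qualifying groups the highest score wins, with ties broken
deterministically in group order (DA, PY, NN).

Scores are computed over the three pooled groups by default — the
specificity counts of interest are reported per group — but
`classify_specific()` accepts any grouping, so a five-cell-type mode is
a matter of passing the finer `group` column and its levels.

## Locus architecture and circular-to-linear ratios

A host gene whose specific circRNAs all belong to one group is an
*exclusive* producer for that group; a gene with specific circRNAs in
two or more groups is a *super-host* tailoring distinct back-spliced
variants to different cell types. The counting identity — per-group
sums over loci equal the sizes of the per-group specific sets — is
enforced by tests.

The linear abundance at a back-splice site is taken as the arithmetic
mean of donor-spanning and acceptor-spanning linear junction reads
(which junction to use was unspecified in the underlying method
description; the mean uses both symmetrically), and the ratio is

$$\rho = \frac{\text{circ reads}}{\tfrac{1}{2}(\text{donor} + \text{acceptor}) + 1},$$

with a pseudo-count of 1 bounding the ratio when no linear reads are
observed. Ratios are computed from counts summed over a sample group by
default (the per-sample mode is a matter of passing single-column
matrices). Group comparisons use a two-sided Mann–Whitney test whose
core (`rank_sum_test()`) enumerates all labelings exactly when both
groups have ≤ 8 observations — the exact branch handles ties naturally,
which is why it is implemented by enumeration rather than by the
classical tie-free network algorithm — and otherwise uses the normal
approximation with tie correction and no continuity correction.

## Genomic features

Flanking introns of a circRNA are located in the transcript whose exon
chain contains the circRNA's blocks; when several transcripts qualify,
the one with the largest total exon length is used (the annotation does
not say which transcript a circle came from, and the longest compatible
chain is a deterministic, conservative choice). Strict mode requires
both circRNA boundaries to lie on annotated exon borders; lenient mode
accepts off-border records — as emitted by low-confidence caller modes —
and flags them. Interval overlap uses half-open semantics (intervals
sharing only a boundary do not overlap) via IRanges. SNP proximity is
measured from the SNP position to the nearest interval *edge* (0 inside;
window default 1 Mb), so `window = 0` degenerates exactly to "inside a
circRNA".

The background set for feature comparisons (non-circularized exons,
their flanking introns) defaults to the annotated exons of
circRNA-producing genes not included in any circRNA block; this is a
documented choice, not derivable from the method description, and is
configurable to genome-wide exons.

## Enrichment

Over-representation uses the one-sided hypergeometric upper tail
$P(X \ge k)$ on the 2×2 table $(k, K-k; n-k, N-K-n+k)$ — query genes in
the set, set size within the universe, query size, universe size — with
Benjamini–Hochberg adjustment. The universe is all annotated genes for
gene-set mode and all annotated protein-coding genes for disease mode.
Disease associations are pre-filtered at GDA score strictly greater
than 0.1, and a brain-only mode keeps diseases whose MeSH classes
include C10 (nervous system) or F03 (mental disorders). Term slimming
is greedy: visit rows in order of increasing p (ties by set id), drop a
set whose member-gene Jaccard similarity with an already-kept set
exceeds 0.7. The threshold is exposed; any count of "slimmed terms" is
sensitive to it, which is why no such count is treated as a reference
value.

## Differential expression

circRNA counts are aggregated to host genes (per-sample sums), and each
gene is fit with a negative-binomial GLM, log link, median-of-ratios
size factors as offsets, and the design
`condition + sex + age + pmi + rin`; continuous covariates are
standardized for conditioning, and only the condition coefficient is
reported (log2 scale, Wald statistic = coefficient / SE, two-sided
normal p, BH q across genes).

Two deliberate numerical choices:

* **Dispersion.** Per-gene dispersion is estimated by a
  degrees-of-freedom-corrected Pearson chi-square estimator — solve
  $\sum_j (y_j - \mu_j)^2 / (\mu_j + \alpha \mu_j^2) = n - p$ for
  $\alpha$, iterated three times with GLM refits — rather than per-gene
  maximum likelihood. The per-gene ML estimate is biased low at a few
  dozen samples, which silently shrinks standard errors and inflates
  the Wald test; the df-corrected estimator restores calibration, which
  the test suite checks directly on simulated null genes. A plain
  method-of-moments estimate is the fallback when the root-finder
  fails, and such genes are flagged. No shrinkage of dispersion across
  genes is applied — calibration is demonstrated by simulation rather
  than by matching any particular reference implementation's output.
* **Convergence.** IRLS runs to a relative deviance change below 1e-8
  or 100 iterations; non-converged genes are flagged, not dropped.
  All-zero genes yield an NA row with an `all_zero` flag.

One property worth knowing: median-of-ratios size factors absorb part of
a strongly *asymmetric* differential signal (if 10% of genes move in one
direction, the per-sample median ratio moves slightly with them), which
attenuates fold changes and perturbs calibration end-to-end. This is a
property of the normalization, not of the Wald machinery; the
calibration experiments in the tests therefore fix unit size factors
(their simulated designs have no depth variation), while end-to-end
recovery with estimated factors is checked against the generator's
looser ±0.15 recovery bound. Relatedly, rescaling one sample's counts
and offset by a constant changes that sample's weight in the GLM score
equation, so coefficient estimates are stable under depth rescaling but
not bit-identical.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 20 DA, 20 PY and 7 NN
control libraries; a fraction 0.1 per group of circRNAs designed
cell-type specific at a 20-fold mean ratio over the 20-read baseline;
negative-binomial noise with common dispersion 0.1; library sizes
uniform on 20–60 million reads; six RNase-R pairs with 5-fold
enrichment of true circles and 10-fold depletion of the 30% planted
linear artifacts (enrichment acts on expected counts before sampling,
treated and mock libraries get independent depths); and a disease
contrast of 27 cases vs 59 controls with log2 fold change −1 on 10% of
genes, covariates drawn independently of condition so that Wald
calibration is testable. Annotation structure: one transcript per gene,
2–20 exons, circRNA candidates per gene Poisson with mean proportional
to exon count (so the circRNAs-per-exons correlation holds by
construction), exonic circles spanning contiguous exon runs and a 5%
admixture of single-intron ciRNAs.

The dispersion default deserves a note: 0.1 is a typical RNA-seq
gene-level value and the value used in the differential-expression
reference design. It was chosen once, by a power calculation done
before the recovery tests were written: with a 20-fold specificity
ratio and groups of 20/20/7, the "group mean > overall mean + sd"
criterion leaves a margin of roughly 28 normalized counts for a
DA-specific circRNA, and the group-mean standard error must sit well
below that margin for the designed ≥ 90% recovery to be achievable,
which bounds the usable dispersion at about 0.1.

Determinism: one master seed; each stage derives a fixed child seed, so
`simulate_annotation()` output is identical whether or not later stages
run, and repeated full runs are byte-identical (tests compare files
literally).

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: batch and amplification effects,
sample-quality gradients correlated with covariates, the empirical
(heavy-tailed, gene-dependent) dispersion distribution of real BSJ
counts, correlated splicing structure between a circle and its linear
cognate, positional sequence biases, and any realistic effect-size
distribution — the real data's dispersions and effect sizes are simply
unknown, so the defaults were chosen for testability, not fidelity.
Recovery bounds demonstrated on this generator are statements about the
implementation's correctness under its own assumptions, not about
sensitivity on any real tissue.

## Problem sizes used in checks

The shipped tests and the acceptance script run the generator at its
default 300 genes (~800 circRNA candidates, 47 + 12 + 86 libraries) and
the differential-expression reference design at 2,000 genes × 40
samples; exhaustive oracles (hypergeometric enumeration, rank-test
labelings, brute-force validation) run on universes of ≤ 12 genes,
groups of ≤ 8 and matrices of ≤ 10×10, where enumeration is exact and
cheap. These sizes were chosen so each property is measured with
comfortable statistical resolution.

## Known limitations

* Exclusive/super-host bookkeeping at whole-study scale depends on the
  upstream specific-set sizes; the package enforces internal counting
  identities but cannot reconcile externally reported locus tallies.
* The enrichment stage treats MeSH classes as given labels; no ontology
  traversal is performed.
* The DE stage offers no dispersion shrinkage across genes; with very
  few samples per condition its per-gene estimates will be noisy, and
  users wanting moderated estimates should export the aggregated matrix
  to a dedicated DE package.
* `compare_circ_vs_linear()` matches circle to host locus 1:1; loci with
  several dominant transcripts are represented by a single linear
  profile.
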