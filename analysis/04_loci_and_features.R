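#!/usr/bin/env Rscript
# Locus architecture (exclusive vs super-host producers of specific
# circRNAs), circular-to-linear ratios by cell group, and genomic
# feature characterization against the annotation and interval tracks.

library(circtype)

spec <- read.delim("results/specificity.tsv")
circs <- read_circ_bed("results/data/circ_calls.bed")
counts <- read_count_matrix("results/data/bsj_counts.tsv")
donor <- read_count_matrix("results/data/linear_donor.tsv")
acceptor <- read_count_matrix("results/data/linear_acceptor.tsv")
samples <- read_sample_table("results/data/samples.tsv")
models <- read_gtf_models("results/data/genes.gtf")
host <- setNames(circs$host_gene, circs$circ_id)

loci <- classify_loci(spec, host)
write.table(loci, "results/loci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Locus architecture:\n")
print(table(loci$architecture))

ids <- unique(spec$id)
ratios <- NULL
for (g in c("DA", "PY", "NN")) {
  cols <- samples$sample_id[samples$group == g]
  r <- circ_linear_ratio(rowSums(counts[ids, cols]),
                         rowSums(donor[ids, cols]),
                         rowSums(acceptor[ids, cols]))
  ratios <- rbind(ratios, data.frame(circ_id = ids, group = g, ratio = r))
}
write.table(ratios, "results/circ_linear_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
rt <- compare_ratio_groups(ratios$ratio, ratios$group)
cat(sprintf(
  "Circular-to-linear ratio, neurons vs non-neurons: medians %.3f vs %.3f, Mann-Whitney p = %.3g\n",
  rt$median_neuron, rt$median_non_neuron, rt$p_value))

cpe <- circ_per_gene_vs_exons(circs, models)
cat(sprintf("circRNAs per gene vs exon count: Pearson r = %.2f over %d genes\n",
            attr(cpe, "pearson_r"), nrow(cpe)))

eclip <- read_track("results/data/eclip.bed")
circ_rbp <- overlap_count(circs, eclip)
cat(sprintf("RBP peaks per circRNA: median %d\n", median(circ_rbp)))

snps <- read_snp_table("results/data/snps.tsv")
frac <- snp_proximity_fraction(snps, circs, window = 1e6)
cat(sprintf("SNPs within 1 Mb of a circRNA: %.0f%% (%d of %d)\n",
            100 * frac, round(frac * nrow(snps)), nrow(snps)))
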