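#!/usr/bin/env Rscript
# Gene-aggregated negative-binomial differential expression of circRNAs
# between prodromal-disease (ILB) and control (HC) dopamine-neuron
# samples, Wald test with sex, age, PMI and RIN adjusted.

library(circtype)

counts <- read_count_matrix("results/data/disease_counts.tsv")
samples <- read_sample_table("results/data/disease_samples.tsv")
circs <- read_circ_bed("results/data/circ_calls.bed")
truth <- read.delim("results/data/truth_gene.tsv")

gene_counts <- aggregate_to_gene(counts,
                                 setNames(circs$host_gene, circs$circ_id))
de <- nb_wald(gene_counts, samples, case_level = "ILB",
              control_level = "HC")
write.table(de, "results/diffexp.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
volcano <- data.frame(gene_id = de$gene_id,
                      log2_fold_change = de$log2_fold_change,
                      neg_log10_p = -log10(de$p))
write.table(volcano, "results/volcano.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

aff <- truth$gene_id[truth$designed_disease_lfc != 0]
cat(nrow(de), "genes tested;", sum(de$q < 0.05, na.rm = TRUE),
    "at q < 0.05\n")
cat(sprintf("Mean recovered log2FC on the %d affected genes: %.2f (designed %.1f)\n",
            length(aff),
            mean(de$log2_fold_change[de$gene_id %in% aff], na.rm = TRUE),
            truth$designed_disease_lfc[truth$gene_id %in% aff][1]))
cat(sprintf("Median log2FC on unaffected genes: %.3f\n",
            median(de$log2_fold_change[!de$gene_id %in% aff],
                   na.rm = TRUE)))
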