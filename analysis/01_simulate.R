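#!/usr/bin/env Rscript
# Generate the synthetic study dataset: BSJ calls and counts for three
# cell groups (DA 20 / PY 20 / NN 7 control libraries), six paired
# RNase-R treated/mock libraries, linear junction and FPKM tables, a
# prodromal-disease contrast (27 ILB vs 59 HC), and external tracks
# (gene sets, disease-gene associations, SNPs, repeats, RBP peaks).
# All downstream scripts read from results/data.

library(circtype)

seed <- 1L
cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg, outdir = "results/data")

cat("Simulated", length(ds$models), "genes,", nrow(ds$circs),
    "circRNA candidates (",
    sum(ds$circs$circ_class == "ciRNA"), "ciRNAs ),",
    nrow(ds$samples), "expression libraries and",
    cfg$rnase_pairs, "RNase-R pairs; seed", seed, "\n")
cat("Designed cell-type-specific circRNAs:",
    sum(!is.na(ds$truth$circ$designed_specific_group)), "\n")
cat("True circles:", sum(ds$truth$circ$is_true_circle), "of",
    nrow(ds$truth$circ), "candidates\n")
cat("Disease-affected genes (log2FC",
    cfg$disease$log2_fold, "):",
    sum(ds$truth$gene$designed_disease_lfc != 0), "\n")
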