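#!/usr/bin/env Rscript
# Two-stage candidate filter: minimum total back-splice read support,
# then RNase-R validation (>= 20 raw treated reads and >= 2-fold
# library-scaled enrichment over mock in at least one pair).

library(circtype)

counts <- read_count_matrix("results/data/bsj_counts.tsv")
circs <- read_circ_bed("results/data/circ_calls.bed")
rn_counts <- read_count_matrix("results/data/rnase_counts.tsv")
rn_pairs <- read_sample_table("results/data/rnase_pairs.tsv")

expressed <- filter_expressed(counts, min_total_reads = 2)
v <- rnase_validate(rn_counts, rn_pairs,
                    min_treated_reads = 20, min_fold = 2)
v$expressed <- v$circ_id %in% expressed
v$validated <- v$validated & v$expressed

dir.create("results", showWarnings = FALSE)
write.table(v, "results/validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(nrow(counts), "candidates;", length(expressed), "expressed;",
    sum(v$validated), "validated (",
    validation_rate(sum(v$validated), nrow(counts)), "% )\n")
for (cls in c("exonic", "ciRNA")) {
  ids <- circs$circ_id[circs$circ_class == cls]
  cat(sprintf("  %s: %s%% (%d of %d)\n", cls,
              validation_rate(sum(v$validated & v$circ_id %in% ids),
                              length(ids)),
              sum(v$validated & v$circ_id %in% ids), length(ids)))
}
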