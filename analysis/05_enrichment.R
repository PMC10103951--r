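#!/usr/bin/env Rscript
# Fisher's exact over-representation of specific-circRNA host genes in
# gene sets (with Jaccard term slimming) and in disease-gene
# associations (GDA score > 0.1), per cell group.

library(circtype)

spec <- read.delim("results/specificity.tsv")
circs <- read_circ_bed("results/data/circ_calls.bed")
models <- read_gtf_models("results/data/genes.gtf")
sets <- read_gmt("results/data/gene_sets.gmt")
gda <- read_gda("results/data/gda.tsv", score_threshold = 0.1)
host <- setNames(circs$host_gene, circs$circ_id)
universe <- names(models)

ss <- specific_set(spec)
hosts_by_group <- lapply(split(ss$id, ss$assigned_group),
                         function(i) unique(unname(host[i])))

enr <- NULL
for (g in names(hosts_by_group)) {
  fe <- fisher_enrich(hosts_by_group[[g]], sets, universe)
  fe <- slim_terms(fe, jaccard_threshold = 0.7)
  fe$group <- g
  enr <- rbind(enr, fe[, c("group", "set_id", "k", "K", "n", "N",
                           "odds_ratio", "p", "q")])
}
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Gene-set enrichment (q < 0.05):\n")
print(enr[enr$q < 0.05, c("group", "set_id", "k", "K", "q")],
      row.names = FALSE)

dis <- disease_enrich(hosts_by_group, gda, universe)
write.table(dis, "results/disease_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Disease enrichment (q < 0.05):\n")
print(dis[dis$q < 0.05, c("group", "disease_name", "k", "K", "q")],
      row.names = FALSE)
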