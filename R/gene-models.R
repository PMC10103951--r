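# Gene models: a named list (by gene_id), each element a list with
# gene_id, chrom, strand, biotype and `transcripts` -- a named list of
# two-column matrices (start, end) of exon intervals, 0-based half-open,
# sorted and non-overlapping within a transcript.

new_gene_model <- function(gene_id, chrom, strand, transcripts,
                           biotype = "protein_coding") {
  transcripts <- lapply(transcripts, function(ex) {
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 2L] <= ex[, 1L]))
      stop("gene ", gene_id, ": exon with end <= start")
    if (nrow(ex) > 1L && any(utils::head(ex[, 2L], -1) > utils::tail(ex[, 1L], -1)))
      stop("gene ", gene_id, ": overlapping exons within a transcript")
    colnames(ex) <- c("start", "end")
    ex
  })
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       biotype = biotype, transcripts = transcripts)
}

#' Read gene models from a GTF file
#'
#' Exon features are grouped by `transcript_id` within `gene_id`; GTF
#' 1-based closed coordinates are converted to the package's 0-based
#' half-open convention on read.
#'
#' @param path Path to a GTF file with exon features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @return Named list of gene models (see package internals): per gene,
#'   `chrom`, `strand`, `biotype` and a named list `transcripts` of exon
#'   interval matrices.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  bed <- gtf_interval_to_bed(GenomicRanges::start(gr), GenomicRanges::end(gr))
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    tx_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = bed[, "start"], end = bed[, "end"],
    biotype = if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
              else "protein_coding",
    stringsAsFactors = FALSE)
  models <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$tx_id), function(t)
      cbind(start = t$start, end = t$end))
    new_gene_model(g$gene_id[1L], g$chrom[1L], g$strand[1L], txs,
                   g$biotype[1L])
  })
  models[order(names(models))]
}

#' Write gene models as GTF
#'
#' Deterministic inverse of [read_gtf_models()]: genes, transcripts and
#' exons are emitted in sorted order with 1-based closed coordinates.
#'
#' @param models Named list of gene models.
#' @param path Output path.
#' @export
write_gtf_models <- function(models, path) {
  lines <- character()
  for (g in models[order(names(models))]) {
    for (tx_id in sort(names(g$transcripts))) {
      ex <- g$transcripts[[tx_id]]
      for (i in seq_len(nrow(ex))) {
        attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                         g$gene_id, tx_id, g$biotype)
        lines <- c(lines, paste(g$chrom, "circtype", "exon",
                                ex[i, 1L] + 1L, ex[i, 2L], ".", g$strand,
                                ".", attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
}

#' Maximum exon count of a gene across its transcripts
#' @param model A single gene model.
#' @return Integer exon count.
#' @export
n_exons <- function(model) {
  max(vapply(model$transcripts, nrow, 0L))
}
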