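#' Introns flanking a circRNA within its host gene
#'
#' Locates the transcript whose exon chain contains the circRNA's blocks
#' (ambiguity resolved by the transcript with the largest total exon
#' length) and returns the annotated introns immediately upstream and
#' downstream of the circularized exons. "Upstream"/"downstream" follow
#' transcription: on the minus strand the genomic-left and genomic-right
#' introns swap labels. `NULL` is returned at transcript termini.
#'
#' @param circ One circRNA record: a list or single-row data frame with
#'   `chrom`, `start`, `end`, `strand`, `host_gene` and `blocks`.
#' @param models Named list of gene models (see [read_gtf_models()]).
#' @param strict When `TRUE` (default) both circRNA boundaries must lie on
#'   annotated exon borders, else an error is raised; when `FALSE`
#'   off-border circRNAs are accepted and flagged.
#' @return List with `upstream` and `downstream` (each `c(start, end)` or
#'   `NULL`) and `boundary_exact` (logical).
#' @export
flanking_introns <- function(circ, models, strict = TRUE) {
  if (is.data.frame(circ)) {
    blocks <- circ$blocks[[1L]]
    circ <- as.list(circ[1L, setdiff(names(circ), "blocks")])
    circ$blocks <- blocks
  }
  model <- models[[circ$host_gene]]
  if (is.null(model)) stop("host gene '", circ$host_gene,
                           "' absent from gene models")
  blocks <- circ$blocks
  contains_blocks <- function(ex) {
    all(vapply(seq_len(nrow(blocks)), function(i) {
      bs <- blocks[i, 1L]; be <- blocks[i, 1L] + blocks[i, 2L]
      any(ex[, 1L] <= bs & ex[, 2L] >= be)
    }, TRUE))
  }
  cand <- Filter(contains_blocks, model$transcripts)
  if (length(cand) == 0L) cand <- model$transcripts
  len <- vapply(cand, function(ex) sum(ex[, 2L] - ex[, 1L]), 0)
  ex <- cand[[which.max(len)]]
  on_border <- any(ex[, 1L] == circ$start) && any(ex[, 2L] == circ$end)
  if (!on_border && strict)
    stop("circRNA boundary not at an annotated exon border (",
         circ$start, ", ", circ$end, ")")
  i_first <- if (any(ex[, 1L] == circ$start)) which(ex[, 1L] == circ$start)[1L]
             else max(c(1L, which(ex[, 2L] > circ$start)[1L]), na.rm = TRUE)
  i_last <- if (any(ex[, 2L] == circ$end)) which(ex[, 2L] == circ$end)[1L]
            else {
              w <- which(ex[, 1L] < circ$end)
              if (length(w)) max(w) else nrow(ex)
            }
  left <- if (i_first > 1L)
    unname(c(ex[i_first - 1L, 2L], ex[i_first, 1L])) else NULL
  right <- if (i_last < nrow(ex))
    unname(c(ex[i_last, 2L], ex[i_last + 1L, 1L])) else NULL
  if (identical(circ$strand, "-")) {
    tmp <- left; left <- right; right <- tmp
  }
  list(upstream = left, downstream = right, boundary_exact = on_border)
}

#' Count track intervals intersecting query intervals
#'
#' Intersection uses half-open semantics: intervals sharing only a
#' boundary point do not overlap.
#'
#' @param query Data frame with `chrom`, `start`, `end` (0-based
#'   half-open); one count is returned per row.
#' @param track Data frame with `chrom`, `start`, `end`.
#' @return Integer vector of overlap counts.
#' @export
overlap_count <- function(query, track) {
  if (any(query$end <= query$start)) stop("query with end <= start")
  out <- integer(nrow(query))
  if (nrow(track) == 0L) return(out)
  if (any(track$end <= track$start)) stop("track with end <= start")
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    ti <- which(track$chrom == chr)
    if (length(ti) == 0L) next
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    tr <- IRanges::IRanges(track$start[ti] + 1L, track$end[ti])
    out[qi] <- IRanges::countOverlaps(qr, tr)
  }
  out
}

#' Rank-test comparison of a feature between two groups
#'
#' @param group_a,group_b Numeric vectors of feature values (e.g. exon
#'   lengths, repeat counts), both non-empty.
#' @return List with `p_value`, `U`, `method` (see [rank_sum_test()]) and
#'   the two group medians.
#' @export
compare_feature <- function(group_a, group_b) {
  res <- rank_sum_test(group_a, group_b)
  res$median_a <- median(group_a)
  res$median_b <- median(group_b)
  res
}

#' circRNAs per gene versus host exon count
#'
#' @param circs circRNA table (needs `host_gene`).
#' @param models Named list of gene models.
#' @return Data frame per gene (`gene_id`, `n_circ`, `n_exons`) with
#'   attributes `pearson_r` and `r_defined` (FALSE when a variance is
#'   zero, in which case r is reported as 0).
#' @export
circ_per_gene_vs_exons <- function(circs, models) {
  if (length(models) < 3L) stop("need >= 3 genes")
  genes <- names(models)
  n_circ <- as.integer(table(factor(circs$host_gene, levels = genes)))
  n_ex <- vapply(models, n_exons, 0L)
  df <- data.frame(gene_id = genes, n_circ = n_circ, n_exons = unname(n_ex),
                   stringsAsFactors = FALSE)
  defined <- sd(df$n_circ) > 0 && sd(df$n_exons) > 0
  attr(df, "pearson_r") <- if (defined) cor(df$n_circ, df$n_exons) else 0
  attr(df, "r_defined") <- defined
  df
}

#' Fraction of SNPs within a window of any circRNA
#'
#' Distance is measured from the SNP position to the nearest edge of a
#' circRNA interval (0 when inside); a SNP counts when that distance is
#' at most `window`. With `window = 0` only SNPs inside a circRNA count.
#'
#' @param snps Data frame with `chrom` and `pos` (0-based position).
#' @param circs circRNA table with `chrom`, `start`, `end`.
#' @param window Maximum distance in bp, default 1e6.
#' @return Fraction in \[0, 1\].
#' @export
snp_proximity_fraction <- function(snps, circs, window = 1e6) {
  if (nrow(snps) == 0L) stop("empty SNP table")
  if (window < 0) stop("window must be >= 0")
  if (nrow(circs) == 0L) return(0)
  hit <- logical(nrow(snps))
  for (chr in unique(snps$chrom)) {
    si <- which(snps$chrom == chr)
    ci <- which(circs$chrom == chr)
    if (length(ci) == 0L) next
    s <- circs$start[ci]; e <- circs$end[ci]
    for (k in si) {
      p <- snps$pos[k]
      d <- pmax(0, pmax(s - p, p - (e - 1L)))
      hit[k] <- min(d) <= window
    }
  }
  mean(hit)
}
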