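#' @importFrom utils read.delim write.table head tail
#' @importFrom stats median sd setNames cor
NULL

# All genomic intervals inside the package are 0-based half-open (BED
# convention). GTF input is converted on read; see gtf_interval_to_bed().

#' Convert a 1-based closed (GTF-style) interval to 0-based half-open
#'
#' @param start1,end1 integer vectors, 1-based inclusive coordinates.
#' @return A two-column matrix with columns `start` (0-based inclusive) and
#'   `end` (exclusive).
#' @export
gtf_interval_to_bed <- function(start1, end1) {
  stopifnot(all(start1 >= 1), all(end1 >= start1))
  cbind(start = as.integer(start1) - 1L, end = as.integer(end1))
}

.circ_bed_cols <- c("chrom", "chromStart", "chromEnd", "name", "score",
                    "strand", "thickStart", "thickEnd", "itemRgb",
                    "blockCount", "blockSizes", "blockStarts",
                    "circType", "geneName", "readNumber")

circ_id_of <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d|%s", chrom, start, end, strand)
}

validate_circ_blocks <- function(start, end, blocks, circ_class, where = "") {
  if (!(start >= 0 && start < end))
    stop("invalid interval [", start, ",", end, ")", where, call. = FALSE)
  bs <- blocks[, 1L]
  be <- blocks[, 1L] + blocks[, 2L]
  if (any(blocks[, 2L] <= 0))
    stop("non-positive block size", where, call. = FALSE)
  if (is.unsorted(bs, strictly = TRUE) || any(utils::head(be, -1) > utils::tail(bs, -1)))
    stop("blocks overlap or are unsorted", where, call. = FALSE)
  if (bs[1L] != start || be[length(be)] != end)
    stop("blocks do not span [start,end)", where, call. = FALSE)
  if (any(bs < start) || any(be > end))
    stop("block outside [start,end)", where, call. = FALSE)
  if (identical(circ_class, "ciRNA") && nrow(blocks) != 1L)
    stop("ciRNA must have exactly one block spanning the record", where,
         call. = FALSE)
  invisible(TRUE)
}

#' Read circRNA calls from a BED12+ file
#'
#' Parses the BED12 dialect emitted by exon-aware back-splice callers:
#' the twelve standard BED columns followed by `circType`, `geneName` and
#' `readNumber`. Block offsets are converted to genomic coordinates and
#' every record is validated (blocks sorted, non-overlapping, spanning
#' `[start, end)`; a ciRNA has a single block). Records whose boundaries
#' are not annotated exon borders are accepted; boundary checking against
#' an annotation is done downstream (see [flanking_introns()]).
#'
#' @param path Path to a tab-separated BED12+ file without header.
#' @return A data frame with one row per circRNA, columns `circ_id`,
#'   `chrom`, `start`, `end`, `strand`, `circ_class` (`exonic` or `ciRNA`),
#'   `host_gene`, `bsj_reads_total`, a list-column `blocks` (two-column
#'   matrix of genomic `start` and `size` per exon block) and `extra`
#'   (opaque tail columns, tab-joined). Rows sorted by (chrom, start, end).
#' @export
read_circ_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_circ_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    where <- paste0(" at line ", i, " of ", path)
    if (length(f) < 15L)
      stop("expected >= 15 tab-separated columns (BED12 + circType, geneName, readNumber)",
           where, call. = FALSE)
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop("non-integer coordinates", where, call. = FALSE)
    if (!(f[6L] %in% c("+", "-")))
      stop("strand must be + or -", where, call. = FALSE)
    if (end <= start)
      stop("end <= start", where, call. = FALSE)
    n_blocks <- suppressWarnings(as.integer(f[10L]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]]))
    offsets <- suppressWarnings(as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(sizes) || anyNA(offsets) ||
        length(sizes) != n_blocks || length(offsets) != n_blocks)
      stop("malformed block columns", where, call. = FALSE)
    blocks <- cbind(start = start + offsets, size = sizes)
    circ_class <- f[13L]
    if (circ_class %in% c("circRNA", "exon")) circ_class <- "exonic"
    if (circ_class %in% c("intron")) circ_class <- "ciRNA"
    if (!circ_class %in% c("exonic", "ciRNA"))
      stop("unknown circType '", f[13L], "'", where, call. = FALSE)
    reads <- suppressWarnings(as.integer(f[15L]))
    if (is.na(reads) || reads < 0)
      stop("readNumber must be a non-negative integer", where, call. = FALSE)
    validate_circ_blocks(start, end, blocks, circ_class, where)
    recs[[i]] <- list(chrom = f[1L], start = start, end = end,
                      strand = f[6L], circ_class = circ_class,
                      host_gene = f[14L], bsj_reads_total = reads,
                      blocks = blocks,
                      extra = if (length(f) > 15L)
                        paste(f[-seq_len(15L)], collapse = "\t") else "")
  }
  circs <- data.frame(
    circ_id = vapply(recs, function(r)
      circ_id_of(r$chrom, r$start, r$end, r$strand), ""),
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    strand = vapply(recs, `[[`, "", "strand"),
    circ_class = vapply(recs, `[[`, "", "circ_class"),
    host_gene = vapply(recs, `[[`, "", "host_gene"),
    bsj_reads_total = vapply(recs, `[[`, 0L, "bsj_reads_total"),
    extra = vapply(recs, `[[`, "", "extra"),
    stringsAsFactors = FALSE)
  circs$blocks <- lapply(recs, `[[`, "blocks")
  ord <- order(circs$chrom, circs$start, circs$end)
  circs <- circs[ord, , drop = FALSE]
  rownames(circs) <- NULL
  circs
}

empty_circ_table <- function() {
  df <- data.frame(circ_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   circ_class = character(), host_gene = character(),
                   bsj_reads_total = integer(), extra = character(),
                   stringsAsFactors = FALSE)
  df$blocks <- list()
  df
}

#' Write circRNA records as BED12+
#'
#' Inverse of [read_circ_bed()]; emits a canonical, deterministic file
#' (rows sorted by coordinate, fixed column order) so that
#' `write(read(x))` is byte-identical for canonical input.
#'
#' @param circs Data frame as returned by [read_circ_bed()].
#' @param path Output path.
#' @export
write_circ_bed <- function(circs, path) {
  ord <- order(circs$chrom, circs$start, circs$end)
  circs <- circs[ord, , drop = FALSE]
  lines <- vapply(seq_len(nrow(circs)), function(i) {
    b <- circs$blocks[[i]]
    line <- paste(circs$chrom[i], circs$start[i], circs$end[i],
                  circs$circ_id[i], 0L, circs$strand[i],
                  circs$start[i], circs$end[i], 0L, nrow(b),
                  paste(b[, 2L], collapse = ","),
                  paste(b[, 1L] - circs$start[i], collapse = ","),
                  circs$circ_class[i], circs$host_gene[i],
                  circs$bsj_reads_total[i], sep = "\t")
    if (nzchar(circs$extra[i])) line <- paste(line, circs$extra[i], sep = "\t")
    line
  }, "")
  writeLines(lines, path)
}

#' Read a circRNA-by-sample count matrix
#'
#' @param path TSV with a header row of sample IDs; first column holds
#'   circRNA (or gene) identifiers; cells must be non-negative integers.
#' @return Integer matrix, rows named by identifier, columns by sample.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix needs an id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(m)) stop("missing cells in count matrix")
  if (!is.numeric(m)) stop("non-numeric cells in count matrix")
  if (any(m < 0)) stop("negative counts in count matrix")
  if (any(m != floor(m))) stop("non-integer counts in count matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count (or numeric) matrix as TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the identifier column, default `"circ_id"`.
#' @param comment Optional comment lines (without leading `#`) written
#'   before the header.
#' @export
write_count_matrix <- function(m, path, id_col = "circ_id", comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE,
              row.names = TRUE)
}

#' Default cell-type to cell-group mapping
#'
#' Dopamine neurons form their own group; temporal-cortex and motor-cortex
#' pyramidal neurons are pooled as `PY`; blood mononuclear cells and
#' fibroblasts as non-neuronal `NN`.
#' @return Named character vector mapping cell type to group.
#' @export
default_group_map <- function() {
  c(DA = "DA", TCPY = "PY", MCPY = "PY", PBMC = "NN", FB = "NN")
}

#' Read (and validate) a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `cell_type`, `condition`,
#'   `sex`, `age`, `pmi`, `rin`, `library_size`, `rnase_status`, `pair_id`
#'   (and optionally `group`).
#' @param group_map Named vector mapping cell types to cell groups; used to
#'   derive the `group` column when absent. Default [default_group_map()].
#' @return Data frame with a `group` column.
#' @export
read_sample_table <- function(path, group_map = default_group_map()) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  validate_sample_table(df, group_map)
}

validate_sample_table <- function(df, group_map = default_group_map()) {
  need <- c("sample_id", "cell_type", "condition", "library_size",
            "rnase_status", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample table")
  if (any(df$library_size <= 0)) stop("library_size must be > 0")
  if (!"group" %in% names(df)) {
    unknown <- setdiff(unique(df$cell_type), names(group_map))
    if (length(unknown)) stop("cell types without group mapping: ",
                              paste(unknown, collapse = ", "))
    df$group <- unname(group_map[df$cell_type])
  }
  treated <- df[df$rnase_status == "treated", , drop = FALSE]
  mock <- df[df$rnase_status == "mock", , drop = FALSE]
  for (pid in treated$pair_id) {
    if (sum(mock$pair_id == pid) != 1L)
      stop("treated sample with pair_id '", pid,
           "' has no unique mock partner")
  }
  df
}

#' Write a sample table as TSV
#' @param samples Data frame as from [read_sample_table()].
#' @param path Output path.
#' @param comment Optional comment lines written with a leading `#`.
#' @export
write_sample_table <- function(samples, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(samples, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member genes, tab-separated.
#' Duplicate members within a set are removed.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene sets; each element is a character vector of
#'   members with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("GMT line ", i, " has an empty member list", call. = FALSE)
    attr(members, "description") <- f[2L]
    sets[[f[1L]]] <- members
  }
  sets
}

#' Read a disease-gene association table
#'
#' Rows with association score at or below `score_threshold` are dropped
#' (the retention rule is strict `>`).
#'
#' @param path TSV with columns `gene_id`, `disease_id`, `disease_name`,
#'   `gda_score`, `mesh_classes` (semicolon-separated MeSH class codes).
#' @param score_threshold Minimum (exclusive) gene-disease association
#'   score; default 0.1.
#' @return Data frame of retained rows.
#' @export
read_gda <- function(path, score_threshold = 0.1) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("gene_id", "disease_id", "disease_name", "gda_score",
            "mesh_classes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("GDA table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  if (any(df$gda_score < 0 | df$gda_score > 1))
    stop("gda_score outside [0,1]")
  df <- df[df$gda_score > score_threshold, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a SNP position table
#' @param path TSV with columns `chrom`, `pos` (0-based) and `snp_id`.
#' @return Data frame of SNP positions.
#' @export
read_snp_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("chrom", "pos", "snp_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SNP table lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}
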