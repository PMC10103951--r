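#' Expression filter on total back-splice junction support
#'
#' A circRNA counts as expressed when its unique BSJ reads summed over all
#' samples reach `min_total_reads` (default 2).
#'
#' @param counts circRNA-by-sample integer count matrix.
#' @param min_total_reads Minimum summed read support, default 2.
#' @return Character vector of retained circRNA ids.
#' @export
filter_expressed <- function(counts, min_total_reads = 2L) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) == 0L) return(character())
  rownames(counts)[rowSums(counts) >= min_total_reads]
}

#' RNase-R validation of circRNA candidates
#'
#' A candidate is validated when at least one treated/mock pair shows both
#' (i) at least `min_treated_reads` raw reads in the RNase-R treated
#' library and (ii) at least `min_fold` enrichment of treated over mock
#' after per-million library-size scaling. With zero mock reads the fold
#' is `+Inf` when the treated count is positive (complete digestion of the
#' linear background) and 0 when both are zero.
#'
#' @param counts circRNA-by-sample count matrix holding the treated and
#'   mock libraries.
#' @param pairs Data frame with columns `sample_id`, `rnase_status`
#'   (`treated`/`mock`), `pair_id` and `library_size`.
#' @param min_treated_reads Raw read floor in the treated library,
#'   default 20.
#' @param min_fold Minimum scaled treated/mock fold, default 2.
#' @return Data frame with one row per circRNA: `circ_id`, `validated`,
#'   `n_pairs_pass`, `max_fold` (largest scaled fold over pairs) and
#'   `max_treated_reads`. Per-pair fold and read matrices are attached as
#'   attributes `fold` and `treated_reads`.
#' @export
rnase_validate <- function(counts, pairs, min_treated_reads = 20L,
                           min_fold = 2.0) {
  treated <- pairs[pairs$rnase_status == "treated", , drop = FALSE]
  mock <- pairs[pairs$rnase_status == "mock", , drop = FALSE]
  if (nrow(treated) == 0L) stop("no treated samples in pair metadata")
  for (pid in treated$pair_id)
    if (sum(mock$pair_id == pid) != 1L)
      stop("treated sample with pair_id '", pid, "' lacks a unique mock")
  miss <- setdiff(c(treated$sample_id, mock$sample_id), colnames(counts))
  if (length(miss)) stop("samples absent from count matrix: ",
                         paste(miss, collapse = ", "))
  pair_ids <- treated$pair_id
  fold <- matrix(NA_real_, nrow(counts), length(pair_ids),
                 dimnames = list(rownames(counts), pair_ids))
  tr_reads <- matrix(NA_integer_, nrow(counts), length(pair_ids),
                     dimnames = list(rownames(counts), pair_ids))
  for (j in seq_along(pair_ids)) {
    t_row <- treated[j, ]
    m_row <- mock[mock$pair_id == pair_ids[j], ]
    t_cnt <- counts[, t_row$sample_id]
    m_cnt <- counts[, m_row$sample_id]
    t_rpm <- t_cnt / t_row$library_size * 1e6
    m_rpm <- m_cnt / m_row$library_size * 1e6
    f <- ifelse(m_cnt == 0, ifelse(t_cnt > 0, Inf, 0), t_rpm / m_rpm)
    fold[, j] <- f
    tr_reads[, j] <- t_cnt
  }
  pass <- (tr_reads >= min_treated_reads) & (fold >= min_fold)
  res <- data.frame(
    circ_id = rownames(counts),
    validated = rowSums(pass) > 0,
    n_pairs_pass = rowSums(pass),
    max_fold = apply(fold, 1L, max),
    max_treated_reads = apply(tr_reads, 1L, max),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "fold") <- fold
  attr(res, "treated_reads") <- tr_reads
  res
}

#' Validation (or coverage) rate as a percentage
#'
#' @param validated Number of items passing.
#' @param candidates Total number of items; must be positive.
#' @param digits Decimal places to round to; default 1.
#' @return `100 * validated / candidates`, rounded.
#' @export
validation_rate <- function(validated, candidates, digits = 1L) {
  if (candidates <= 0) stop("candidates must be > 0")
  if (validated < 0 || validated > candidates)
    stop("validated must lie in [0, candidates]")
  round(100 * validated / candidates, digits)
}
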