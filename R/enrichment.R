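#' Fisher's exact over-representation test against gene sets
#'
#' For each set, the 2x2 table is (k, K-k; n-k, N-K-n+k) with k the query
#' genes inside the set, K the set size within the universe, n the query
#' size and N the universe size. The reported p-value is the one-sided
#' upper hypergeometric tail P(X >= k).
#'
#' @param query_genes Character vector of query gene ids (subset of the
#'   universe).
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe_genes Character vector defining the gene universe.
#' @return Data frame sorted by p with columns `set_id`, `k`, `K`, `n`,
#'   `N`, `odds_ratio`, `p`, `q` (BH) and a list-column `genes` (set
#'   members within the universe).
#' @export
fisher_enrich <- function(query_genes, sets, universe_genes) {
  universe_genes <- unique(universe_genes)
  query_genes <- unique(query_genes)
  bad <- setdiff(query_genes, universe_genes)
  if (length(bad)) stop("query genes outside the universe: ",
                        paste(bad, collapse = ", "))
  N <- length(universe_genes)
  n <- length(query_genes)
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(sets[[sid]], universe_genes)
    K <- length(members)
    k <- length(intersect(query_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    list(set_id = sid, k = k, K = K, n = n, N = N,
         odds_ratio = or, p = p, genes = members)
  })
  out <- data.frame(
    set_id = vapply(rows, `[[`, "", "set_id"),
    k = vapply(rows, `[[`, 0L, "k"),
    K = vapply(rows, `[[`, 0L, "K"),
    n = vapply(rows, `[[`, 0L, "n"),
    N = vapply(rows, `[[`, 0L, "N"),
    odds_ratio = vapply(rows, `[[`, 0, "odds_ratio"),
    p = vapply(rows, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  out$genes <- lapply(rows, `[[`, "genes")
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Slim an enrichment result by greedy Jaccard redundancy removal
#'
#' Rows are visited in order of increasing p (ties broken by `set_id`);
#' a row is dropped when the Jaccard similarity of its member genes with
#' an already-kept row exceeds `jaccard_threshold`.
#'
#' @param rows Enrichment table from [fisher_enrich()] (needs the `genes`
#'   list-column).
#' @param jaccard_threshold Similarity above which a set is redundant,
#'   default 0.7.
#' @return The retained rows, in significance order.
#' @export
slim_terms <- function(rows, jaccard_threshold = 0.7) {
  if (nrow(rows) == 0L) return(rows)
  rows <- rows[order(rows$p, rows$set_id), , drop = FALSE]
  keep <- logical(nrow(rows))
  kept_genes <- list()
  for (i in seq_len(nrow(rows))) {
    gi <- rows$genes[[i]]
    redundant <- any(vapply(kept_genes, function(gk) {
      length(intersect(gi, gk)) / length(union(gi, gk)) > jaccard_threshold
    }, TRUE))
    if (!redundant) {
      keep[i] <- TRUE
      kept_genes[[length(kept_genes) + 1L]] <- gi
    }
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disease enrichment of circRNA host genes per cell group
#'
#' One Fisher's exact test per (disease, cell group) asking whether genes
#' hosting circRNAs in that group are over-represented among genes
#' associated with the disease; BH adjustment is applied across diseases
#' within each group.
#'
#' @param host_genes_by_group Named list: per cell group, the character
#'   vector of circRNA host genes.
#' @param gda Disease-gene table from [read_gda()] (already filtered on
#'   association score).
#' @param universe Character vector of annotated protein-coding genes.
#' @param brain_only When `TRUE`, keep only diseases whose MeSH classes
#'   include C10 (nervous system) or F03 (mental disorders).
#' @return Data frame with `group`, `disease_id`, `disease_name`, the
#'   Fisher columns of [fisher_enrich()] and `q` per group.
#' @export
disease_enrich <- function(host_genes_by_group, gda, universe,
                           brain_only = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  if (brain_only) {
    classes <- strsplit(gda$mesh_classes, ";", fixed = TRUE)
    keep <- vapply(classes, function(cl)
      any(trimws(cl) %in% c("C10", "F03")), TRUE)
    gda <- gda[keep, , drop = FALSE]
  }
  diseases <- unique(gda[, c("disease_id", "disease_name")])
  out <- NULL
  for (grp in names(host_genes_by_group)) {
    query <- intersect(unique(host_genes_by_group[[grp]]), universe)
    sets <- list()
    keep_rows <- logical(nrow(diseases))
    for (i in seq_len(nrow(diseases))) {
      genes <- unique(gda$gene_id[gda$disease_id == diseases$disease_id[i]])
      genes <- intersect(genes, universe)
      if (length(genes) == 0L) next
      keep_rows[i] <- TRUE
      sets[[diseases$disease_id[i]]] <- genes
    }
    if (length(sets) == 0L) next
    fe <- fisher_enrich(query, sets, universe)
    fe$disease_id <- fe$set_id
    fe$disease_name <- diseases$disease_name[
      match(fe$disease_id, diseases$disease_id)]
    fe$group <- grp
    out <- rbind(out, fe[, c("group", "disease_id", "disease_name", "k",
                             "K", "n", "N", "odds_ratio", "p", "q")])
  }
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}
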