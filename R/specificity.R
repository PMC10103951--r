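#' Reads-per-million normalization
#'
#' @param counts circRNA-by-sample count matrix.
#' @param library_sizes Named numeric vector of total mapped reads per
#'   sample; must cover every column of `counts`.
#' @return Numeric matrix of RPM values with the same dimnames.
#' @export
rpm_normalize <- function(counts, library_sizes) {
  miss <- setdiff(colnames(counts), names(library_sizes))
  if (length(miss)) stop("missing library sizes for: ",
                         paste(miss, collapse = ", "))
  ls <- library_sizes[colnames(counts)]
  if (any(ls <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, ls, "/") * 1e6
}

#' Jensen-Shannon distance between two discrete distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the distance lies in \[0, 1\]. Zero-probability terms contribute zero.
#'
#' @param p,q Non-negative vectors of equal length summing to 1.
#' @return The distance, a scalar in \[0, 1\].
#' @export
js_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d2 <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(d2, 0))
}

profile_density <- function(group_means) {
  d <- group_means + 1
  d / sum(d)
}

#' Cell-type specificity score
#'
#' `S = 1 - JSD(p, q_hat)` where `p` is the expression profile across cell
#' groups expressed as a density of (mean RPM + 1) and `q_hat` is the unit
#' vector of perfect expression in the target group.
#'
#' @param group_means Named vector of mean normalized expression (RPM or
#'   FPKM) per cell group; at least two groups.
#' @param target_group Name of the group scored as "perfectly expressed".
#' @return Score in \[0, 1\].
#' @export
specificity_score <- function(group_means, target_group) {
  if (length(group_means) < 2L) stop("need >= 2 groups")
  if (!target_group %in% names(group_means))
    stop("unknown target group '", target_group, "'")
  if (any(group_means < 0)) stop("negative group means")
  q <- as.numeric(names(group_means) == target_group)
  1 - js_distance(profile_density(group_means), q)
}

#' Classify cell-type-specific transcripts
#'
#' A transcript is specific to a group when its specificity score for that
#' group reaches `s_threshold` and its group-mean expression exceeds the
#' across-sample mean plus one (n-1 denominator) standard deviation of its
#' expression over all included samples. A transcript is assigned to at
#' most one group: among qualifying groups the highest score wins, ties
#' broken by the order of `group_levels`.
#'
#' Only control-condition samples enter the calculation by default, so
#' disease-driven expression shifts do not masquerade as cell-type
#' specificity.
#'
#' @param expr Normalized expression matrix (RPM for circRNAs, FPKM for
#'   linear transcripts), rows transcripts, columns samples.
#' @param samples Sample table with `sample_id`, `group` and `condition`.
#' @param s_threshold Minimum specificity score, default 0.5.
#' @param group_levels Group order used for scoring and tie-breaking;
#'   default the groups present, in `DA`, `PY`, `NN` order first.
#' @param control_conditions Conditions retained, default `"HC"`; `NULL`
#'   keeps all samples.
#' @return Long data frame with one row per (transcript, group): `id`,
#'   `group`, `score`, `group_mean`, `overall_mean`, `overall_sd`,
#'   `is_specific`, `assigned_group` (`NA` when not specific anywhere).
#' @export
classify_specific <- function(expr, samples, s_threshold = 0.5,
                              group_levels = NULL,
                              control_conditions = "HC") {
  if (!is.null(control_conditions))
    samples <- samples[samples$condition %in% control_conditions, ,
                       drop = FALSE]
  samples <- samples[samples$sample_id %in% colnames(expr), , drop = FALSE]
  if (is.null(group_levels)) {
    canonical <- c("DA", "PY", "NN")
    present <- unique(samples$group)
    group_levels <- c(intersect(canonical, present),
                      sort(setdiff(present, canonical)))
  }
  for (g in group_levels)
    if (!any(samples$group == g))
      stop("group '", g, "' has no included samples")
  expr <- expr[, samples$sample_id, drop = FALSE]
  grp_idx <- lapply(group_levels, function(g)
    which(samples$group == g))
  names(grp_idx) <- group_levels
  group_means <- vapply(grp_idx, function(idx)
    rowMeans(expr[, idx, drop = FALSE]), numeric(nrow(expr)))
  if (nrow(expr) == 1L) group_means <- matrix(group_means, nrow = 1L,
                                              dimnames = list(rownames(expr),
                                                              group_levels))
  overall_mean <- rowMeans(expr)
  overall_sd <- apply(expr, 1L, sd)
  n <- nrow(expr)
  score <- matrix(NA_real_, n, length(group_levels),
                  dimnames = list(rownames(expr), group_levels))
  for (g in group_levels) {
    q <- as.numeric(group_levels == g)
    for (i in seq_len(n))
      score[i, g] <- 1 - js_distance(profile_density(group_means[i, ]), q)
  }
  qualifies <- score >= s_threshold &
    group_means > overall_mean + overall_sd
  assigned <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ok <- which(qualifies[i, ])
    if (length(ok)) {
      best <- ok[order(-score[i, ok], ok)][1L]
      assigned[i] <- group_levels[best]
    }
  }
  out <- data.frame(
    id = rep(rownames(expr), times = length(group_levels)),
    group = rep(group_levels, each = n),
    score = as.vector(score),
    group_mean = as.vector(group_means),
    overall_mean = rep(overall_mean, times = length(group_levels)),
    overall_sd = rep(overall_sd, times = length(group_levels)),
    stringsAsFactors = FALSE)
  out$is_specific <- !is.na(assigned[match(out$id, rownames(expr))]) &
    out$group == assigned[match(out$id, rownames(expr))]
  out$assigned_group <- assigned[match(out$id, rownames(expr))]
  out
}

#' Specific transcripts from a specificity table
#' @param spec Output of [classify_specific()].
#' @return Data frame with `id` and `assigned_group`, one row per specific
#'   transcript.
#' @export
specific_set <- function(spec) {
  s <- spec[spec$is_specific, c("id", "assigned_group")]
  rownames(s) <- NULL
  s
}

#' Paired comparison of circular versus linear specificity
#'
#' For each circRNA with a linear (host gene) profile, the difference
#' `delta = S_circ - S_linear` is taken at the circRNA's best-scoring
#' group, and a two-sided paired Wilcoxon signed-rank test is run over
#' the pairs.
#'
#' @param spec_circ,spec_linear Outputs of [classify_specific()] for
#'   circRNAs (ids = circ ids) and linear transcripts (ids = gene ids).
#' @param host_map Named character vector mapping circ_id to host gene id.
#' @return List with `pairs` (data frame: circ_id, gene_id, group, s_circ,
#'   s_linear, delta), `p_value`, `median_delta` and `n_excluded` (circRNAs
#'   without a linear profile).
#' @export
compare_circ_vs_linear <- function(spec_circ, spec_linear, host_map) {
  if (length(host_map) == 0L) stop("empty host map")
  circ_ids <- unique(spec_circ$id)
  best <- do.call(rbind, lapply(circ_ids, function(cid) {
    rows <- spec_circ[spec_circ$id == cid, ]
    rows[which.max(rows$score), c("id", "group", "score")]
  }))
  best$gene_id <- unname(host_map[best$id])
  lin_key <- paste(spec_linear$id, spec_linear$group)
  idx <- match(paste(best$gene_id, best$group), lin_key)
  excluded <- is.na(idx)
  if (any(excluded))
    warning(sum(excluded), " circRNA(s) without a host linear profile excluded")
  pairs <- data.frame(circ_id = best$id[!excluded],
                      gene_id = best$gene_id[!excluded],
                      group = best$group[!excluded],
                      s_circ = best$score[!excluded],
                      s_linear = spec_linear$score[idx[!excluded]],
                      stringsAsFactors = FALSE)
  pairs$delta <- pairs$s_circ - pairs$s_linear
  if (nrow(pairs) == 0L) stop("no matched circ/linear pairs")
  p <- if (all(pairs$delta == 0)) 1
       else suppressWarnings(
         stats::wilcox.test(pairs$s_circ, pairs$s_linear,
                            paired = TRUE)$p.value)
  list(pairs = pairs, p_value = p, median_delta = median(pairs$delta),
       n_excluded = sum(excluded))
}
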