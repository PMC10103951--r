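#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact by exhaustive enumeration of all group labelings when both
#' groups have at most `exact_max` observations (ties handled naturally);
#' otherwise the normal approximation with tie correction (no continuity
#' correction). The two-sided exact p-value is the fraction of labelings
#' whose U statistic deviates from its null mean at least as much as the
#' observed one.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Largest per-group size for the exact branch, default 8.
#' @return List with `U` (statistic for `x`), `p_value` and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    labelings <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(U - mu)
    devs <- apply(labelings, 2L, function(idx)
      abs(u_stat(pool[idx], pool[-idx]) - mu))
    p <- mean(devs >= dev_obs - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Classify host loci by the cell groups of their specific circRNAs
#'
#' A locus whose specific circRNAs all belong to one group is an
#' exclusive producer for that group; a locus with specific circRNAs in
#' two or more groups is a super-host that tailors distinct back-spliced
#' variants to different cell types; a locus with circRNAs but none
#' specific is `none`.
#'
#' @param spec Specificity table from [classify_specific()].
#' @param host_map Named character vector mapping circ_id to host gene.
#' @return Data frame with `gene_id`, one `n_specific_<group>` column per
#'   group, and `architecture` (`exclusive-<group>`, `super-host` or
#'   `none`).
#' @export
classify_loci <- function(spec, host_map) {
  groups <- unique(spec$group)
  sp <- specific_set(spec)
  if (anyDuplicated(sp$id))
    stop("circRNA specific to more than one group: upstream contract violated")
  miss <- setdiff(sp$id, names(host_map))
  if (length(miss)) stop("specific circRNAs without host gene: ",
                         paste(miss, collapse = ", "))
  genes <- sort(unique(unname(host_map)))
  cnt <- matrix(0L, length(genes), length(groups),
                dimnames = list(genes, groups))
  if (nrow(sp)) {
    tab <- table(factor(unname(host_map[sp$id]), levels = genes),
                 factor(sp$assigned_group, levels = groups))
    cnt <- cnt + unclass(tab)
  }
  n_groups_hit <- rowSums(cnt > 0)
  arch <- rep("none", length(genes))
  arch[n_groups_hit >= 2] <- "super-host"
  one <- which(n_groups_hit == 1)
  if (length(one))
    arch[one] <- paste0("exclusive-",
                        groups[apply(cnt[one, , drop = FALSE] > 0, 1L,
                                     which)])
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (g in groups) out[[paste0("n_specific_", g)]] <- cnt[, g]
  out$architecture <- arch
  rownames(out) <- NULL
  out
}

#' Circular-to-linear expression ratio at the back-splice site
#'
#' Linear abundance is the arithmetic mean of donor-spanning and
#' acceptor-spanning linear junction reads; a pseudocount in the
#' denominator bounds the ratio and avoids division by zero.
#'
#' @param circ_reads Back-splice junction reads (vectorized).
#' @param donor_linear,acceptor_linear Linear junction reads at the donor
#'   and acceptor splice site.
#' @param pseudocount Added to the linear mean, default 1.
#' @return Numeric ratio(s), >= 0.
#' @export
circ_linear_ratio <- function(circ_reads, donor_linear, acceptor_linear,
                              pseudocount = 1) {
  if (any(circ_reads < 0) || any(donor_linear < 0) || any(acceptor_linear < 0))
    stop("counts must be non-negative")
  circ_reads / ((donor_linear + acceptor_linear) / 2 + pseudocount)
}

#' Compare circular-to-linear ratios between neurons and non-neurons
#'
#' @param ratios Numeric vector of per-circRNA ratios.
#' @param groups Cell group of each ratio (same length).
#' @param neuron_groups Groups counted as neuronal, default `DA` and `PY`.
#' @return [rank_sum_test()] result plus group medians.
#' @export
compare_ratio_groups <- function(ratios, groups,
                                 neuron_groups = c("DA", "PY")) {
  stopifnot(length(ratios) == length(groups))
  is_neu <- groups %in% neuron_groups
  if (!any(is_neu) || all(is_neu))
    stop("both neuronal and non-neuronal groups must be non-empty")
  res <- rank_sum_test(ratios[is_neu], ratios[!is_neu])
  res$median_neuron <- median(ratios[is_neu])
  res$median_non_neuron <- median(ratios[!is_neu])
  res
}
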