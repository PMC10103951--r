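# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Jensen-Shannon distance via the entropy formulation
# JS(p,q) = H((p+q)/2) - (H(p)+H(q))/2, base-2 logs.
oracle_js_distance <- function(p, q) {
  H <- function(v) {
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  m <- (p + q) / 2
  sqrt(max(H(m) - (H(p) + H(q)) / 2, 0))
}

# Brute-force RNase validation: per circRNA, loop over pairs explicitly.
oracle_rnase_validate <- function(counts, pairs, min_treated_reads,
                                  min_fold) {
  treated <- pairs[pairs$rnase_status == "treated", ]
  mock <- pairs[pairs$rnase_status == "mock", ]
  vapply(rownames(counts), function(cid) {
    for (i in seq_len(nrow(treated))) {
      m <- mock[mock$pair_id == treated$pair_id[i], ]
      tc <- counts[cid, treated$sample_id[i]]
      mc <- counts[cid, m$sample_id]
      f <- if (mc == 0) {
        if (tc > 0) Inf else 0
      } else {
        (tc / treated$library_size[i]) / (mc / m$library_size)
      }
      if (tc >= min_treated_reads && f >= min_fold) return(TRUE)
    }
    FALSE
  }, TRUE)
}

# Exhaustive hypergeometric upper tail by enumerating all n-subsets of a
# universe whose first K elements form the set.
oracle_hyper_upper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Brute-force two-sided Mann-Whitney via direct pair counting over all
# labelings.
oracle_mw_exact <- function(x, y) {
  u_of <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n1 <- length(x)
  pool <- c(x, y)
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(x, y) - mu)
  labelings <- utils::combn(length(pool), n1)
  devs <- apply(labelings, 2, function(idx)
    abs(u_of(pool[idx], pool[-idx]) - mu))
  mean(devs >= obs - 1e-12)
}

# Brute-force interval overlap count under half-open semantics.
oracle_overlap <- function(qs, qe, track) {
  sum(track$start < qe & track$end > qs)
}

# Minimal sample table builder for specificity tests.
make_sample_table <- function(groups, condition = "HC",
                              library_size = 1e6) {
  n <- length(groups)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             cell_type = groups, group = groups,
             condition = rep_len(condition, n),
             sex = rep_len(c("M", "F"), n),
             age = 70, pmi = 10, rin = 7.5,
             library_size = rep_len(library_size, n),
             rnase_status = "none", pair_id = "",
             stringsAsFactors = FALSE)
}

# Shared small simulated dataset (built once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 303L))
    cache
  }
})
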