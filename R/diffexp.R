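#' Aggregate circRNA counts to host genes
#'
#' @param circ_counts circRNA-by-sample count matrix.
#' @param host_map Named character vector mapping circ_id to host gene.
#' @param lenient Drop unmapped circRNAs (with an attribute recording how
#'   many) instead of erroring.
#' @return Gene-by-sample integer matrix; gene counts are the per-sample
#'   sums over the gene's circRNAs.
#' @export
aggregate_to_gene <- function(circ_counts, host_map, lenient = FALSE) {
  unmapped <- setdiff(rownames(circ_counts), names(host_map))
  if (length(unmapped)) {
    if (!lenient) stop("circRNAs without host gene: ",
                       paste(utils::head(unmapped, 5), collapse = ", "))
    circ_counts <- circ_counts[setdiff(rownames(circ_counts), unmapped), ,
                               drop = FALSE]
  }
  genes <- unname(host_map[rownames(circ_counts)])
  out <- rowsum(circ_counts, group = genes, reorder = TRUE)
  storage.mode(out) <- "integer"
  if (length(unmapped) && lenient) attr(out, "n_dropped") <- length(unmapped)
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio between the
#' sample's count and the gene's geometric mean across samples, using
#' genes with nonzero counts in every sample.
#'
#' @param gene_counts Gene-by-sample count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(gene_counts) {
  log_geo <- rowMeans(log(gene_counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no gene with nonzero counts in all samples; ",
         "consider a pseudo-reference on filtered genes")
  sf <- apply(gene_counts, 2L, function(cnt)
    exp(median(log(cnt[usable]) - log_geo[usable])))
  sf
}

estimate_dispersion_mom <- function(y, mu) {
  # plain method-of-moments: Var = mu + a mu^2
  a <- sum((y - mu)^2 - mu) / sum(mu^2)
  max(a, 1e-8)
}

estimate_dispersion_pearson <- function(y, mu, n_coef) {
  # Degrees-of-freedom-corrected Pearson chi-square estimator: solve
  # sum((y-mu)^2 / (mu + a mu^2)) = n - p for a. The uncorrected per-gene
  # ML estimate is biased low at these sample sizes, which would inflate
  # the Wald test; this estimator restores calibration.
  df <- length(y) - n_coef
  fa <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - df
  if (fa(1e-8) < 0) return(1e-8)
  if (fa(100) > 0) return(100)
  stats::uniroot(fa, c(1e-8, 100), tol = 1e-10)$root
}

#' Negative-binomial Wald differential expression per gene
#'
#' Fits, per gene, an NB GLM with log link on raw counts with
#' log(size factor) offsets and the design
#' `condition + sex + age + pmi + rin` (continuous covariates are
#' standardized; covariate terms absent from `samples` are dropped).
#' Dispersion is estimated per gene by maximum likelihood with a
#' method-of-moments fallback; no shrinkage across genes is applied. The
#' Wald statistic is the condition coefficient over its standard error,
#' with a two-sided normal p-value and BH adjustment across genes.
#'
#' @param gene_counts Gene-by-sample count matrix.
#' @param samples Sample table with `sample_id`, `condition` and the
#'   covariate columns; rows matched to the matrix columns.
#' @param case_level,control_level Condition levels contrasted (case vs
#'   control), e.g. `"ILB"` vs `"HC"`.
#' @param covariates Covariate columns to adjust for, default
#'   `c("sex", "age", "pmi", "rin")` intersected with `samples`.
#' @param sf Optional precomputed size factors; default [size_factors()].
#' @param dispersion Optional fixed dispersion shared by all genes
#'   (0 gives a Poisson fit); default `NULL` estimates per gene.
#' @return Data frame per gene: `gene_id`, `base_mean`,
#'   `log2_fold_change`, `se` (log2 scale), `wald_stat`, `p`, `q`,
#'   `dispersion_hat`, `converged`, `flag` (`ok`, `all_zero` or
#'   `mom_fallback`).
#' @export
nb_wald <- function(gene_counts, samples, case_level, control_level,
                    covariates = c("sex", "age", "pmi", "rin"),
                    sf = NULL, dispersion = NULL) {
  samples <- samples[match(colnames(gene_counts), samples$sample_id), ,
                     drop = FALSE]
  if (anyNA(samples$sample_id)) stop("samples missing for some columns")
  keep <- samples$condition %in% c(case_level, control_level)
  samples <- samples[keep, , drop = FALSE]
  gene_counts <- gene_counts[, samples$sample_id, drop = FALSE]
  if (sum(samples$condition == case_level) < 2L ||
      sum(samples$condition == control_level) < 2L)
    stop("need >= 2 samples per condition level")
  covariates <- intersect(covariates, names(samples))
  dat <- data.frame(condition = factor(samples$condition,
                                       levels = c(control_level, case_level)))
  for (cv in covariates) {
    v <- samples[[cv]]
    dat[[cv]] <- if (is.numeric(v)) as.numeric(scale(v)) else factor(v)
  }
  form <- stats::as.formula(paste("y ~",
    paste(c("condition", covariates), collapse = " + ")))
  X <- stats::model.matrix(stats::as.formula(paste("~",
    paste(c("condition", covariates), collapse = " + "))), dat)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  if (is.null(sf)) sf <- size_factors(gene_counts)
  off <- log(sf)
  coef_name <- paste0("condition", case_level)
  full_form <- stats::update(form, . ~ . + offset(off))
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit_one <- function(y) {
    if (all(y == 0))
      return(c(NA, NA, NA, NA, NA, NA, 2))  # all_zero
    d <- dat; d$y <- y; d$off <- off
    flag <- 0
    fit <- suppressWarnings(stats::glm(full_form, data = d,
                                       family = stats::poisson(),
                                       control = ctrl))
    disp <- 1e-8
    if (!is.null(dispersion)) {
      disp <- dispersion
      if (dispersion > 0)
        fit <- suppressWarnings(stats::glm(full_form, data = d,
          family = MASS::negative.binomial(theta = 1 / dispersion),
          control = ctrl))
    } else for (it in 1:3) {
      mu <- stats::fitted(fit)
      disp <- tryCatch(estimate_dispersion_pearson(y, mu, ncol(X)),
                       error = function(e) NA)
      if (is.na(disp)) {
        disp <- estimate_dispersion_mom(y, mu)
        flag <- 1  # mom_fallback
      }
      refit <- tryCatch(
        suppressWarnings(stats::glm(full_form, data = d,
          family = MASS::negative.binomial(theta = 1 / disp),
          control = ctrl)),
        error = function(e) NULL)
      if (is.null(refit)) { flag <- 1; break }
      fit <- refit
    }
    sm <- summary(fit)$coefficients
    if (!coef_name %in% rownames(sm))
      return(c(NA, NA, NA, NA, NA, disp, 2))
    b <- sm[coef_name, 1L]; se <- sm[coef_name, 2L]
    z <- b / se
    c(b / log(2), se / log(2), z, 2 * stats::pnorm(-abs(z)),
      as.numeric(isTRUE(fit$converged)), disp, flag)
  }
  res <- t(apply(gene_counts, 1L, fit_one))
  norm_counts <- sweep(gene_counts, 2L, sf, "/")
  out <- data.frame(
    gene_id = rownames(gene_counts),
    base_mean = rowMeans(norm_counts),
    log2_fold_change = res[, 1L],
    se = res[, 2L],
    wald_stat = res[, 3L],
    p = res[, 4L],
    dispersion_hat = res[, 6L],
    converged = res[, 5L] == 1,
    flag = c("ok", "mom_fallback", "all_zero")[res[, 7L] + 1L],
    stringsAsFactors = FALSE)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}
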