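test_that("simulated annotation respects its structural contracts", {
  cfg <- sim_config(seed = 11L)
  ann <- simulate_annotation(cfg)
  expect_gt(nrow(ann$circs), 0L)
  for (i in seq_len(nrow(ann$circs))) {
    circ <- ann$circs[i, ]
    ex <- ann$models[[circ$host_gene]]$transcripts$t1
    b <- circ$blocks[[1]]
    expect_true(circ$start < circ$end)
    if (circ$circ_class == "exonic") {
      # each block is exactly one host exon; the run is contiguous
      idx <- match(b[, 1], ex[, "start"])
      expect_false(anyNA(idx))
      expect_equal(idx, seq(idx[1], idx[length(idx)]))
      expect_equal(b[, 1] + b[, 2], ex[idx, "end"], ignore_attr = TRUE)
    } else {
      expect_equal(nrow(b), 1L)
      expect_equal(unname(b[1, 1]), circ$start)
      expect_equal(unname(b[1, 1] + b[1, 2]), circ$end)
    }
  }
  # empty config
  empty <- simulate_annotation(sim_config(n_genes = 0L))
  expect_equal(length(empty$models), 0L)
  expect_equal(nrow(empty$circs), 0L)
  expect_error(sim_config(exons_per_gene_range = c(0L, 5L)), "lower bound")
})

test_that("circRNAs per gene scale with exon count by construction", {
  cfg <- sim_config(n_genes = 500L, seed = 21L)
  ann <- simulate_annotation(cfg)
  df <- circ_per_gene_vs_exons(ann$circs, ann$models)
  expect_gt(attr(df, "pearson_r"), 0.5)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 60L, seed = 9L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$circs, b$circs)
  expect_identical(a$rnase, b$rnase)
  expect_identical(a$disease, b$disease)
  expect_identical(a$tracks, b$tracks)
  c_ <- simulate_dataset(sim_config(n_genes = 60L, seed = 10L))
  expect_false(identical(a$counts, c_$counts))
})

test_that("simulated counts match negative-binomial moments", {
  n <- 10000
  mu <- 50; a <- 0.2
  withr::with_seed(77, y <- circtype:::rnbinom_disp(n, mu, a))
  expect_lt(abs(mean(y) - mu) / mu, 0.05)
  expect_lt(abs(var(y) - (mu + a * mu^2)) / (mu + a * mu^2), 0.05)
  # Poisson limit: variance/mean ratio -> 1
  withr::with_seed(78, y0 <- circtype:::rnbinom_disp(n, mu, 0))
  expect_lt(abs(var(y0) / mean(y0) - 1), 0.1)
})

test_that("designed group means are realized in the count matrix", {
  ds <- shared_sim()
  truth <- ds$truth$circ
  des <- truth$designed_specific_group[match(rownames(ds$counts),
                                             truth$circ_id)]
  rpm_scale <- ds$samples$library_size / mean(ds$config$library_size_range)
  norm <- sweep(ds$counts, 2, rpm_scale, "/")
  for (g in c("DA", "PY", "NN")) {
    rows <- which(!is.na(des) & des == g)
    cols <- ds$samples$group == g
    mu <- ds$config$baseline_mean_bsj * ds$config$specific_fold
    expect_lt(abs(mean(norm[rows, cols]) - mu) / mu, 0.2)
    expect_lt(abs(mean(norm[rows, !cols]) - ds$config$baseline_mean_bsj) /
                ds$config$baseline_mean_bsj, 0.2)
  }
})

test_that("a null generator yields almost no specific calls", {
  cfg <- sim_config(seed = 31L,
                    frac_specific = c(DA = 0, PY = 0, NN = 0))
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(ann, cfg)
  rpm <- rpm_normalize(cnt$counts,
                       setNames(cnt$samples$library_size,
                                cnt$samples$sample_id))
  spec <- classify_specific(rpm, cnt$samples)
  fp <- nrow(specific_set(spec)) / nrow(rpm)
  expect_lte(fp, 0.01)
})

test_that("RNase pairs enrich true circles and deplete artifacts", {
  ds <- shared_sim()
  v <- rnase_validate(ds$rnase$counts, ds$rnase$pairs)
  truth <- ds$truth$circ
  is_true <- truth$is_true_circle[match(v$circ_id, truth$circ_id)]
  expect_gte(mean(v$validated[is_true]), 0.95)
  expect_lte(mean(v$validated[!is_true]), 0.05)
  expect_error(simulate_rnase_pairs(simulate_annotation(sim_config()),
                                    sim_config(rnase_pairs = 0L)),
               ">= 1")
  expect_true(all(ds$rnase$counts >= 0))
  expect_true(all(ds$rnase$counts == floor(ds$rnase$counts)))
})

test_that("disease effect scales affected case means as designed", {
  ds <- shared_sim()
  tg <- ds$truth$gene
  lfc <- tg$designed_disease_lfc[match(ds$circs$host_gene, tg$gene_id)]
  aff <- lfc != 0
  samp <- ds$disease$samples
  sc <- samp$library_size / mean(ds$config$library_size_range)
  norm <- sweep(ds$disease$counts, 2, sc, "/")
  case <- samp$condition == "ILB"
  obs_lfc <- log2(mean(norm[aff, case]) / mean(norm[aff, !case]))
  expect_lt(abs(obs_lfc - ds$config$disease$log2_fold), 0.15)
  null_lfc <- log2(mean(norm[!aff, case]) / mean(norm[!aff, !case]))
  expect_lt(abs(null_lfc), 0.1)
  # zero effect size: equal in expectation
  cfg0 <- sim_config(n_genes = 80L, seed = 13L,
                     disease = list(frac_affected_genes = 0.5,
                                    log2_fold = 0, n_case = 20L,
                                    n_control = 20L))
  d0 <- simulate_disease_effect(simulate_annotation(cfg0), cfg0)
  sc0 <- d0$samples$library_size / mean(cfg0$library_size_range)
  n0 <- sweep(d0$counts, 2, sc0, "/")
  expect_lt(abs(log2(mean(n0[, d0$samples$condition == "ILB"]) /
                     mean(n0[, d0$samples$condition == "HC"]))), 0.1)
})
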