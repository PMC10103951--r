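four_exon_gene <- function(strand = "+") {
  ex <- cbind(start = c(100L, 300L, 500L, 700L),
              end = c(200L, 400L, 600L, 800L))
  list(G1 = circtype:::new_gene_model("G1", "chr1", strand, list(t1 = ex)))
}

circ_on <- function(start, end, blocks, strand = "+") {
  list(chrom = "chr1", start = start, end = end, strand = strand,
       circ_class = "exonic", host_gene = "G1",
       blocks = blocks)
}

test_that("flanking introns are the gaps around the circularized run", {
  models <- four_exon_gene()
  circ <- circ_on(300L, 600L, cbind(c(300L, 500L), c(100L, 100L)))
  fl <- flanking_introns(circ, models)
  expect_equal(fl$upstream, c(200, 300))
  expect_equal(fl$downstream, c(600, 700))
  expect_true(fl$boundary_exact)

  # first exon: no upstream intron
  first <- circ_on(100L, 200L, cbind(100L, 100L))
  fl2 <- flanking_introns(first, models)
  expect_null(fl2$upstream)
  expect_equal(fl2$downstream, c(200, 300))

  # minus strand swaps the labels
  models_m <- four_exon_gene("-")
  fl3 <- flanking_introns(circ_on(300L, 600L,
                                  cbind(c(300L, 500L), c(100L, 100L)),
                                  strand = "-"),
                          models_m)
  expect_equal(fl3$upstream, c(600, 700))
  expect_equal(fl3$downstream, c(200, 300))

  # strict mode rejects a mid-exon boundary
  mid <- circ_on(350L, 600L, cbind(c(350L, 500L), c(50L, 100L)))
  expect_error(flanking_introns(mid, models), "exon border")
  fl4 <- flanking_introns(mid, models, strict = FALSE)
  expect_false(fl4$boundary_exact)
  expect_equal(fl4$upstream, c(200, 300))

  bad <- circ_on(300L, 600L, cbind(300L, 300L))
  bad$host_gene <- "nope"
  expect_error(flanking_introns(bad, models), "absent")
})

test_that("flanking introns ignore exon input order", {
  ex <- cbind(start = c(700L, 100L, 500L, 300L),
              end = c(800L, 200L, 600L, 400L))
  models <- list(G1 = circtype:::new_gene_model("G1", "chr1", "+",
                                                list(t1 = ex)))
  circ <- circ_on(300L, 600L, cbind(c(300L, 500L), c(100L, 100L)))
  fl <- flanking_introns(circ, models)
  expect_equal(fl$upstream, c(200, 300))
  expect_equal(fl$downstream, c(600, 700))
})

test_that("overlap counting uses half-open semantics", {
  track <- data.frame(chrom = "chr1", start = c(10L, 30L),
                      end = c(20L, 40L))
  q <- data.frame(chrom = "chr1", start = 15L, end = 35L)
  expect_equal(overlap_count(q, track), 2L)
  # touching endpoints do not overlap
  expect_equal(overlap_count(data.frame(chrom = "chr1", start = 20L,
                                        end = 25L), track), 0L)
  expect_equal(overlap_count(q, track[0, ]), 0L)

  withr::with_seed(88, {
    big <- data.frame(chrom = "chr1",
                      start = sample(0:5000, 800, replace = TRUE))
    big$end <- big$start + sample(1:200, 800, replace = TRUE)
    qs <- sample(0:5000, 40); qe <- qs + sample(1:300, 40)
    got <- overlap_count(data.frame(chrom = "chr1", start = qs, end = qe),
                         big)
    want <- vapply(seq_along(qs), function(i)
      oracle_overlap(qs[i], qe[i], big), 0)
    expect_equal(got, as.integer(want))
  })
})

test_that("feature comparison delegates to the shared rank test", {
  res <- compare_feature(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$median_a, 2)
  expect_error(compare_feature(numeric(), 1), "non-empty")
})

test_that("circRNAs-per-gene correlation handles degenerate inputs", {
  mk <- function(n_ex) {
    ex <- cbind(start = seq(0, by = 200L, length.out = n_ex),
                end = seq(100L, by = 200L, length.out = n_ex))
    circtype:::new_gene_model(paste0("g", n_ex), "chr1", "+",
                              list(t1 = ex))
  }
  models <- list(g2 = mk(2), g4 = mk(4), g8 = mk(8))
  circs <- data.frame(host_gene = c("g2", rep("g4", 2), rep("g8", 4)))
  df <- circ_per_gene_vs_exons(circs, models)
  expect_equal(attr(df, "pearson_r"), 1.0)

  const <- data.frame(host_gene = c("g2", "g4", "g8"))
  df2 <- circ_per_gene_vs_exons(const, models)
  expect_equal(attr(df2, "pearson_r"), 0)
  expect_false(attr(df2, "r_defined"))

  expect_error(circ_per_gene_vs_exons(circs, models[1:2]), ">= 3 genes")
})

test_that("SNP proximity counts distance to the nearest circRNA edge", {
  circs <- data.frame(chrom = "chr1", start = 1000000L, end = 1010000L)
  snps <- data.frame(chrom = "chr1", pos = c(1500000L, 3000000L),
                     snp_id = c("rs1", "rs2"))
  expect_equal(snp_proximity_fraction(snps, circs, 1e6), 0.5)
  expect_equal(snp_proximity_fraction(snps, circs[0, ]), 0)
  # window 0: only SNPs inside an interval count
  inside <- data.frame(chrom = "chr1",
                       pos = c(1000000L, 1009999L, 1010000L, 999999L),
                       snp_id = paste0("r", 1:4))
  expect_equal(snp_proximity_fraction(inside, circs, 0), 0.5)
  expect_error(snp_proximity_fraction(snps[0, ], circs), "empty SNP")
  # monotone non-decreasing in the window
  withr::with_seed(17, {
    sn <- data.frame(chrom = "chr1",
                     pos = sample(0:5e6, 100), snp_id = paste0("s", 1:100))
    cc <- data.frame(chrom = "chr1", start = sample(0:5e6, 10))
    cc$end <- cc$start + 1000L
  })
  fr <- vapply(c(0, 1e4, 1e5, 1e6, 5e6), function(w)
    snp_proximity_fraction(sn, cc, w), 0)
  expect_true(all(diff(fr) >= 0))
})
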