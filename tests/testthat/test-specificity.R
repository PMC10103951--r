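test_that("RPM normalization is per-million library scaling", {
  m <- matrix(c(50, 0, 25), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  rpm <- rpm_normalize(m, c(s1 = 2.5e7))
  expect_equal(unname(rpm[, 1]), c(2, 0, 1))
  expect_equal(rpm_normalize(m, c(s1 = 1e6)), m, ignore_attr = TRUE)
  expect_error(rpm_normalize(m, c(other = 1e6)), "missing library")
})

test_that("specificity score matches frozen closed-form values", {
  expect_equal(specificity_score(c(DA = 10, PY = 0, NN = 0), "DA"),
               0.7144261, tolerance = 1e-6)
  expect_equal(specificity_score(c(DA = 5, PY = 5, NN = 5), "DA"),
               0.3223955, tolerance = 1e-6)
  expect_gt(specificity_score(c(DA = 1e6, PY = 0, NN = 0), "DA"), 0.99)
  expect_error(specificity_score(c(DA = 1, PY = 1), "XX"), "unknown")
})

test_that("score agrees with an independent numeric JSD oracle", {
  withr::with_seed(123, {
    for (i in 1:50) {
      k <- sample(2:6, 1)
      means <- runif(k, 0, 50)
      names(means) <- paste0("g", 1:k)
      tgt <- sample(names(means), 1)
      p <- (means + 1) / sum(means + 1)
      q <- as.numeric(names(means) == tgt)
      expect_equal(specificity_score(means, tgt),
                   1 - oracle_js_distance(p, q), tolerance = 1e-12)
      expect_true(specificity_score(means, tgt) >= 0)
      expect_true(specificity_score(means, tgt) <= 1)
    }
  })
})

test_that("score is equivariant under group permutation and maximal at argmax", {
  withr::with_seed(321, {
    for (i in 1:20) {
      means <- setNames(runif(4, 0, 100), c("A", "B", "C", "D"))
      s <- vapply(names(means), function(g) specificity_score(means, g), 0)
      expect_equal(names(which.max(s)), names(which.max(means)))
      perm <- sample(names(means))
      s_perm <- vapply(perm, function(g)
        specificity_score(means[perm], g), 0)
      expect_equal(unname(s_perm), unname(s[perm]), tolerance = 1e-12)
    }
  })
})

test_that("adding a constant pulls the score toward the uniform value", {
  means <- c(DA = 40, PY = 2, NN = 1)
  uniform_s <- specificity_score(c(DA = 1, PY = 1, NN = 1), "DA")
  shifts <- c(0, 5, 20, 100, 1000)
  s <- vapply(shifts, function(d) specificity_score(means + d, "DA"), 0)
  expect_true(all(diff(s) < 0))
  expect_gt(min(s), uniform_s)
})

test_that("classification combines score and mean+sd thresholds", {
  samples <- make_sample_table(rep(c("DA", "PY", "NN"), each = 2))
  rpm <- matrix(c(10, 10, 0, 0, 0, 0), 1, 6,
                dimnames = list("c1", samples$sample_id))
  spec <- classify_specific(rpm, samples)
  da <- spec[spec$group == "DA", ]
  expect_equal(da$overall_mean, 10 / 3, tolerance = 1e-6)
  expect_equal(da$overall_sd, 5.163978, tolerance = 1e-6)
  expect_equal(da$score, 0.7144261, tolerance = 1e-6)
  expect_true(da$is_specific)
  expect_equal(da$assigned_group, "DA")
  expect_false(any(spec$is_specific[spec$group != "DA"]))

  # constant profile: no group beats mean + sd
  flat <- matrix(5, 1, 6, dimnames = list("c1", samples$sample_id))
  expect_false(any(classify_specific(flat, samples)$is_specific))
  # all-zero: uniform density, not specific
  zero <- flat * 0
  spec0 <- classify_specific(zero, samples)
  expect_false(any(spec0$is_specific))
  expect_equal(spec0$score, rep(0.3223955, 3), tolerance = 1e-6)

  expect_error(classify_specific(rpm, samples[samples$group != "NN", ],
                                 group_levels = c("DA", "PY", "NN")),
               "no included samples")
})

test_that("disease-condition samples are excluded from classification", {
  samples <- make_sample_table(rep(c("DA", "PY", "NN"), each = 2))
  samples$condition[1] <- "PD"
  rpm <- matrix(c(1000, 10, 0, 0, 0, 0), 1, 6,
                dimnames = list("c1", samples$sample_id))
  spec <- classify_specific(rpm, samples)
  # only the second DA sample (RPM 10) is used for the DA mean
  expect_equal(spec$group_mean[spec$group == "DA"], 10)
})

test_that("circ vs linear comparison pairs loci and tests deltas", {
  samples <- make_sample_table(rep(c("DA", "PY", "NN"), each = 3))
  withr::with_seed(55, {
    n <- 60
    rpm_circ <- matrix(rpois(n * 9, 5), n, 9,
                       dimnames = list(sprintf("c%02d", 1:n),
                                       samples$sample_id))
    rpm_circ[1:30, samples$group == "DA"] <- rpois(30 * 3, 120)
    fpkm <- matrix(rpois(n * 9, 50), n, 9,
                   dimnames = list(sprintf("g%02d", 1:n),
                                   samples$sample_id))
  })
  host <- setNames(sprintf("g%02d", 1:n), sprintf("c%02d", 1:n))
  sc <- classify_specific(rpm_circ, samples)
  sl <- classify_specific(fpkm, samples)
  cmp <- compare_circ_vs_linear(sc, sl, host)
  expect_gt(cmp$median_delta, 0)
  expect_lt(cmp$p_value, 0.01)

  # identical profiles: all deltas zero, p = 1
  cmp0 <- compare_circ_vs_linear(sc, sc, setNames(names(host), names(host)))
  expect_true(all(cmp0$pairs$delta == 0))
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_circ_vs_linear(sc, sl, character()), "empty host")
})
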