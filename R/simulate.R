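#' Configuration for the synthetic circRNA dataset generator
#'
#' Defaults emulate the design of a laser-capture brain study: three cell
#' groups with 20 dopamine-neuron, 20 pyramidal-neuron and 7 non-neuronal
#' control libraries, a 20-fold expression ratio for designed cell-type-
#' specific circRNAs, six paired RNase-R treated/mock libraries with
#' five-fold enrichment of true circles and ten-fold depletion of linear
#' artifacts, and a prodromal-disease contrast of 27 cases versus 59
#' controls with a log2 fold change of -1 on 10% of genes.
#'
#' @param ... Overrides for any default field.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 300L,
    exons_per_gene_range = c(2L, 20L),
    n_circ_per_gene_range = c(0L, 6L),
    samples_per_group = c(DA = 20L, PY = 20L, NN = 7L),
    frac_specific = c(DA = 0.1, PY = 0.1, NN = 0.1),
    specific_fold = 20,
    baseline_mean_bsj = 20,
    nb_dispersion = 0.1,
    library_size_range = c(20e6, 60e6),
    rnase_pairs = 6L,
    rnase_enrich_true = 5,
    rnase_deplete_artifact = 0.1,
    frac_artifact = 0.3,
    frac_cirna = 0.05,
    linear_mean = 200,
    nonneuron_linear_scale = 3,
    disease = list(frac_affected_genes = 0.1, log2_fold = -1,
                   n_case = 27L, n_control = 59L),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  fr <- c(cfg$frac_specific, cfg$frac_artifact, cfg$frac_cirna,
          cfg$disease$frac_affected_genes)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (sum(cfg$frac_specific) > 1) stop("frac_specific must sum to <= 1")
  if (cfg$specific_fold <= 0 || cfg$rnase_enrich_true <= 0 ||
      cfg$rnase_deplete_artifact <= 0) stop("folds must be > 0")
  if (cfg$nb_dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$exons_per_gene_range[1L] < 1L)
    stop("exons_per_gene_range lower bound must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

child_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 7919L + stage * 104729L
}

rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion < 1e-8) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a gene annotation with circRNA candidates
#'
#' Genes are laid out on five chromosomes with one transcript each; the
#' expected number of circRNA candidates per gene is proportional to its
#' exon count, so the circRNAs-per-gene versus exon-count correlation
#' holds by construction. Exonic circRNAs cover a contiguous run of host
#' exons; ciRNAs are single-intron records. Truth labels record, per
#' circRNA, whether it is a true circle (versus a linear artifact that
#' RNase R will deplete) and its designed specific group, and, per gene,
#' the designed disease log2 fold change.
#'
#' @param config A [sim_config()].
#' @return List with `models` (gene models), `circs` (circRNA table) and
#'   `truth` (list with `circ` and `gene` data frames).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, 1L), {
    n <- config$n_genes
    if (n == 0L)
      return(list(models = list(),
                  circs = empty_circ_table(),
                  truth = list(circ = data.frame(), gene = data.frame())))
    er <- config$exons_per_gene_range
    gene_ids <- sprintf("G%04d", seq_len(n))
    chroms <- paste0("chr", ((seq_len(n) - 1L) %% 5L) + 1L)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    n_ex <- sample(seq(er[1L], er[2L]), n, replace = TRUE)
    cursor <- stats::setNames(rep(10000L, 5L), paste0("chr", 1:5))
    models <- vector("list", n)
    for (g in seq_len(n)) {
      sizes <- sample(100:500, n_ex[g], replace = TRUE)
      gaps <- sample(500:5000, n_ex[g] - 1L + 1L, replace = TRUE)
      starts <- cursor[chroms[g]] + cumsum(c(0L, sizes[-n_ex[g]] + gaps[-1L]))
      ex <- cbind(start = as.integer(starts),
                  end = as.integer(starts + sizes))
      cursor[chroms[g]] <- ex[n_ex[g], 2L] + 50000L
      models[[g]] <- new_gene_model(gene_ids[g], chroms[g], strands[g],
                                    list(t1 = ex))
    }
    names(models) <- gene_ids
    cr <- config$n_circ_per_gene_range
    lambda <- cr[2L] * (n_ex - er[1L] + 1L) / (er[2L] - er[1L] + 1L)
    n_circ <- pmax(cr[1L], pmin(cr[2L], stats::rpois(n, lambda)))
    recs <- list()
    for (g in seq_len(n)) {
      if (n_circ[g] == 0L) next
      ex <- models[[g]]$transcripts$t1
      seen <- character()
      for (k in seq_len(n_circ[g])) {
        is_ci <- stats::runif(1) < config$frac_cirna && nrow(ex) >= 2L
        if (is_ci) {
          i <- sample(nrow(ex) - 1L, 1L)
          s <- ex[i, 2L]; e <- ex[i + 1L, 1L]
          blocks <- cbind(start = s, size = e - s)
          cls <- "ciRNA"
        } else {
          i <- sample(nrow(ex), 1L)
          j <- i + sample.int(nrow(ex) - i + 1L, 1L) - 1L
          s <- ex[i, 1L]; e <- ex[j, 2L]
          blocks <- cbind(start = ex[i:j, 1L],
                          size = ex[i:j, 2L] - ex[i:j, 1L])
          cls <- "exonic"
        }
        cid <- circ_id_of(chroms[g], s, e, strands[g])
        if (cid %in% seen) next
        seen <- c(seen, cid)
        recs[[length(recs) + 1L]] <- list(
          circ_id = cid, chrom = chroms[g], start = s, end = e,
          strand = strands[g], circ_class = cls,
          host_gene = gene_ids[g], blocks = blocks)
      }
    }
    circs <- data.frame(
      circ_id = vapply(recs, `[[`, "", "circ_id"),
      chrom = vapply(recs, `[[`, "", "chrom"),
      start = vapply(recs, function(r) as.integer(r$start), 0L),
      end = vapply(recs, function(r) as.integer(r$end), 0L),
      strand = vapply(recs, `[[`, "", "strand"),
      circ_class = vapply(recs, `[[`, "", "circ_class"),
      host_gene = vapply(recs, `[[`, "", "host_gene"),
      bsj_reads_total = 0L,
      extra = "",
      stringsAsFactors = FALSE)
    circs$blocks <- lapply(recs, `[[`, "blocks")
    ord <- order(circs$chrom, circs$start, circs$end)
    circs <- circs[ord, , drop = FALSE]
    rownames(circs) <- NULL
    nc <- nrow(circs)
    groups <- names(config$frac_specific)
    probs <- c(1 - sum(config$frac_specific), config$frac_specific)
    designed <- sample(c(NA_character_, groups), nc, replace = TRUE,
                       prob = probs)
    truth_circ <- data.frame(
      circ_id = circs$circ_id,
      is_true_circle = stats::runif(nc) >= config$frac_artifact,
      designed_specific_group = designed,
      stringsAsFactors = FALSE)
    affected <- stats::runif(n) < config$disease$frac_affected_genes
    truth_gene <- data.frame(
      gene_id = gene_ids,
      designed_disease_lfc = ifelse(affected, config$disease$log2_fold, 0),
      stringsAsFactors = FALSE)
    list(models = models, circs = circs,
         truth = list(circ = truth_circ, gene = truth_gene))
  })
}

make_samples <- function(prefix, groups, config, condition = "HC",
                         rnase_status = "none", pair_id = "") {
  n <- length(groups)
  cell_type <- ifelse(groups == "DA", "DA",
               ifelse(groups == "PY", "TCPY", "PBMC"))
  nn <- which(groups == "NN")
  if (length(nn) > 1L)
    cell_type[nn[seq_along(nn) %% 2L == 0L]] <- "FB"
  data.frame(
    sample_id = sprintf("%s%03d", prefix, seq_len(n)),
    cell_type = cell_type,
    group = groups,
    condition = rep_len(condition, n),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(stats::rnorm(n, 75, 8), 1),
    pmi = round(pmax(1, stats::rnorm(n, 10, 5)), 1),
    rin = round(pmin(10, pmax(5, stats::rnorm(n, 7.5, 0.8))), 1),
    library_size = round(stats::runif(n, config$library_size_range[1L],
                                      config$library_size_range[2L])),
    rnase_status = rep_len(rnase_status, n),
    pair_id = rep_len(pair_id, n),
    stringsAsFactors = FALSE)
}

#' Simulate BSJ counts, linear junction counts, samples and FPKM
#'
#' BSJ counts are negative binomial with a common dispersion; the mean of
#' a designed-specific circRNA is `specific_fold` times the baseline in
#' its designed group. Means scale with library size relative to the mid
#' of `library_size_range`. Linear junction counts at the donor and
#' acceptor sites are drawn independently with a higher mean in
#' non-neuronal samples, so circular-to-linear ratios are elevated in
#' neurons by construction. Linear gene expression (FPKM) is flat across
#' groups.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `counts` (circ x sample), `linear` (list of `donor`
#'   and `acceptor` matrices), `samples`, `fpkm` (gene x sample) and the
#'   updated `circs` table (total BSJ reads filled in).
#' @export
simulate_counts <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, 2L), {
    spg <- config$samples_per_group
    groups <- rep(names(spg), spg)
    samples <- make_samples("S", groups, config)
    circs <- annotation$circs
    truth <- annotation$truth$circ
    nc <- nrow(circs); ns <- nrow(samples)
    lbar <- mean(config$library_size_range)
    lib_scale <- samples$library_size / lbar
    base <- matrix(config$baseline_mean_bsj, nc, ns)
    des <- truth$designed_specific_group[match(circs$circ_id, truth$circ_id)]
    for (g in names(spg)) {
      rows <- which(!is.na(des) & des == g)
      cols <- which(samples$group == g)
      base[rows, cols] <- config$baseline_mean_bsj * config$specific_fold
    }
    mu <- sweep(base, 2L, lib_scale, "*")
    counts <- matrix(rnbinom_disp(nc * ns, as.vector(mu),
                                  config$nb_dispersion),
                     nc, ns, dimnames = list(circs$circ_id,
                                             samples$sample_id))
    lin_scale <- ifelse(samples$group == "NN",
                        config$nonneuron_linear_scale, 1)
    lin_mu <- config$linear_mean * outer(rep(1, nc), lin_scale * lib_scale)
    donor <- matrix(rnbinom_disp(nc * ns, as.vector(lin_mu),
                                 config$nb_dispersion),
                    nc, ns, dimnames = dimnames(counts))
    acceptor <- matrix(rnbinom_disp(nc * ns, as.vector(lin_mu),
                                    config$nb_dispersion),
                       nc, ns, dimnames = dimnames(counts))
    gene_ids <- names(annotation$models)
    gene_base <- exp(stats::rnorm(length(gene_ids), log(50), 1))
    fpkm <- matrix(gene_base, length(gene_ids), ns) *
      matrix(exp(stats::rnorm(length(gene_ids) * ns, 0, 0.2)),
             length(gene_ids), ns)
    dimnames(fpkm) <- list(gene_ids, samples$sample_id)
    circs$bsj_reads_total <- as.integer(rowSums(counts))
    list(counts = counts, linear = list(donor = donor, acceptor = acceptor),
         samples = samples, fpkm = round(fpkm, 4), circs = circs)
  })
}

#' Simulate paired RNase-R treated and mock libraries
#'
#' The expected mock count per circRNA is the baseline BSJ mean; the
#' expected treated count is the mock mean multiplied by
#' `rnase_enrich_true` for true circles and by `rnase_deplete_artifact`
#' for linear artifacts, acting on expected counts before NB sampling.
#' Treated and mock libraries get independent library sizes.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `counts` (circ x (2 x pairs) matrix) and `pairs`
#'   (sample metadata with `rnase_status` and `pair_id`).
#' @export
simulate_rnase_pairs <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$rnase_pairs < 1L) stop("need >= 1 RNase pair")
  withr::with_seed(child_seed(config$seed, 3L), {
    circs <- annotation$circs
    truth <- annotation$truth$circ
    np <- config$rnase_pairs
    nc <- nrow(circs)
    meta <- make_samples("R", rep("NN", 2L * np), config,
                         rnase_status = rep(c("treated", "mock"), np),
                         pair_id = rep(sprintf("P%02d", seq_len(np)),
                                       each = 2L))
    meta$cell_type <- "FB"
    lbar <- mean(config$library_size_range)
    is_true <- truth$is_true_circle[match(circs$circ_id, truth$circ_id)]
    enrich <- ifelse(is_true, config$rnase_enrich_true,
                     config$rnase_deplete_artifact)
    counts <- matrix(0L, nc, nrow(meta),
                     dimnames = list(circs$circ_id, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      m <- config$baseline_mean_bsj * meta$library_size[j] / lbar
      if (meta$rnase_status[j] == "treated") m <- m * enrich
      counts[, j] <- rnbinom_disp(nc, m, config$nb_dispersion)
    }
    list(counts = counts, pairs = meta)
  })
}

#' Simulate a case/control disease contrast on circRNA counts
#'
#' Draws a fresh set of dopamine-neuron case (prodromal disease) and
#' control samples with recorded covariates; circRNAs of affected genes
#' (per the truth labels) have their case-group expected counts scaled by
#' `2^log2_fold`. Covariates are drawn independently of condition so the
#' Wald test's calibration is testable.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `counts` (circ x sample) and `samples` (condition
#'   `ILB` for cases, `HC` for controls, plus sex/age/pmi/rin).
#' @export
simulate_disease_effect <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$disease
  if (d$n_case < 2L || d$n_control < 2L)
    stop("need >= 2 cases and >= 2 controls")
  withr::with_seed(child_seed(config$seed, 4L), {
    circs <- annotation$circs
    tg <- annotation$truth$gene
    n <- d$n_case + d$n_control
    samples <- make_samples("D", rep("DA", n), config,
                            condition = rep(c("ILB", "HC"),
                                            c(d$n_case, d$n_control)))
    samples$cell_type <- "DA"
    lbar <- mean(config$library_size_range)
    lfc <- tg$designed_disease_lfc[match(circs$host_gene, tg$gene_id)]
    nc <- nrow(circs)
    mu <- matrix(config$baseline_mean_bsj, nc, n)
    case_cols <- which(samples$condition == "ILB")
    mu[, case_cols] <- mu[, case_cols] * 2^lfc
    mu <- sweep(mu, 2L, samples$library_size / lbar, "*")
    counts <- matrix(rnbinom_disp(nc * n, as.vector(mu),
                                  config$nb_dispersion),
                     nc, n, dimnames = list(circs$circ_id,
                                            samples$sample_id))
    list(counts = counts, samples = samples)
  })
}

#' Simulate external annotation tracks
#'
#' Generates the auxiliary inputs the characterization and enrichment
#' stages consume: a GMT gene-set collection (two sets deliberately
#' enriched in hosts of designed DA-specific circRNAs, the rest random),
#' a disease-gene association table with MeSH classes (one brain disease
#' seeded with hosts of designed-specific circRNAs), a GWAS-style SNP
#' table (half the positions within 1 Mb of a circRNA, half far), and
#' repeat / RBP-peak interval tracks.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `gene_sets`, `gda`, `snps`, `repeats`, `eclip`.
#' @export
simulate_tracks <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(child_seed(config$seed, 5L), {
    genes <- names(annotation$models)
    circs <- annotation$circs
    truth <- annotation$truth$circ
    des <- truth$designed_specific_group[match(circs$circ_id, truth$circ_id)]
    da_hosts <- unique(circs$host_gene[!is.na(des) & des == "DA"])
    sets <- list()
    for (i in 1:18) {
      members <- sample(genes, sample(10:30, 1L))
      attr(members, "description") <- paste("random set", i)
      sets[[sprintf("SET_RAND_%02d", i)]] <- members
    }
    for (i in 1:2) {
      members <- unique(c(da_hosts,
                          sample(genes, max(3L, length(da_hosts) %/% 4L))))
      attr(members, "description") <- paste("DA-host-enriched set", i)
      sets[[sprintf("SET_DAHOST_%02d", i)]] <- members
    }
    spec_hosts <- unique(circs$host_gene[!is.na(des)])
    gda_rows <- list()
    mesh_pool <- c("C10", "F03", "C14", "C04")
    for (i in 1:10) {
      seeded <- i == 1L
      dg <- if (seeded) unique(c(spec_hosts, sample(genes, 10L)))
            else sample(genes, sample(10:40, 1L))
      mesh <- if (seeded) "C10" else
        paste(sample(mesh_pool, sample(1:2, 1L)), collapse = ";")
      gda_rows[[i]] <- data.frame(
        gene_id = dg,
        disease_id = sprintf("D%03d", i),
        disease_name = if (seeded) "synthetic brain disorder"
                       else paste("synthetic disease", i),
        gda_score = round(stats::runif(length(dg), 0.02, 0.9), 3),
        mesh_classes = mesh,
        stringsAsFactors = FALSE)
    }
    gda <- do.call(rbind, gda_rows)
    n_snp <- 200L
    near <- sample(nrow(circs), n_snp %/% 2L, replace = TRUE)
    snps_near <- data.frame(
      chrom = circs$chrom[near],
      pos = circs$start[near] +
        sample(-500000:500000, length(near), replace = TRUE),
      stringsAsFactors = FALSE)
    far_chrom <- sample(paste0("chr", 1:5), n_snp - length(near),
                        replace = TRUE)
    max_pos <- vapply(split(circs$end, circs$chrom), max, 0)
    snps_far <- data.frame(
      chrom = far_chrom,
      pos = as.integer(max_pos[far_chrom] + 2e6 +
                         sample(0:1000000, length(far_chrom),
                                replace = TRUE)),
      stringsAsFactors = FALSE)
    snps <- rbind(snps_near, snps_far)
    snps$pos <- pmax(0L, as.integer(snps$pos))
    snps$snp_id <- sprintf("rs%06d", seq_len(nrow(snps)))
    mk_track <- function(n) {
      chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
      start <- as.integer(sample(0:2000000, n, replace = TRUE))
      data.frame(chrom = chrom, start = start,
                 end = start + sample(50:500, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    list(gene_sets = sets, gda = gda, snps = snps,
         repeats = mk_track(400L), eclip = mk_track(400L))
  })
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(sid) {
    paste(c(sid, attr(sets[[sid]], "description"),
            as.character(sets[[sid]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

write_track <- function(track, path) {
  write.table(track[order(track$chrom, track$start, track$end),
                    c("chrom", "start", "end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Simulate a complete dataset and (optionally) write it to disk
#'
#' Runs all generator stages under one master seed. When `outdir` is
#' given, every table is written in the formats the readers accept:
#' BED12+ circRNA calls, GTF gene models, TSV count/linear/FPKM matrices,
#' sample and pair metadata, disease contrast, and truth labels.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if needed).
#' @return List with `config`, `models`, `circs`, `truth`, `counts`,
#'   `linear`, `samples`, `fpkm`, `rnase` and `disease`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  ann <- simulate_annotation(config)
  cnt <- simulate_counts(ann, config)
  rns <- simulate_rnase_pairs(ann, config)
  dis <- simulate_disease_effect(ann, config)
  trk <- simulate_tracks(ann, config)
  ds <- list(config = config, models = ann$models, circs = cnt$circs,
             truth = ann$truth, counts = cnt$counts, linear = cnt$linear,
             samples = cnt$samples, fpkm = cnt$fpkm, rnase = rns,
             disease = dis, tracks = trk)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_circ_bed(ds$circs, fp("circ_calls.bed"))
    write_gtf_models(ds$models, fp("genes.gtf"))
    write_count_matrix(ds$counts, fp("bsj_counts.tsv"))
    write_count_matrix(ds$linear$donor, fp("linear_donor.tsv"))
    write_count_matrix(ds$linear$acceptor, fp("linear_acceptor.tsv"))
    write_count_matrix(ds$fpkm, fp("fpkm.tsv"), id_col = "gene_id")
    write_sample_table(ds$samples, fp("samples.tsv"))
    write_count_matrix(ds$rnase$counts, fp("rnase_counts.tsv"))
    write_sample_table(ds$rnase$pairs, fp("rnase_pairs.tsv"))
    write_count_matrix(ds$disease$counts, fp("disease_counts.tsv"))
    write_sample_table(ds$disease$samples, fp("disease_samples.tsv"))
    write.table(ds$truth$circ, fp("truth_circ.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ds$truth$gene, fp("truth_gene.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gmt(ds$tracks$gene_sets, fp("gene_sets.gmt"))
    write.table(ds$tracks$gda, fp("gda.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(ds$tracks$snps, fp("snps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_track(ds$tracks$repeats, fp("repeats.bed"))
    write_track(ds$tracks$eclip, fp("eclip.bed"))
  }
  ds
}
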