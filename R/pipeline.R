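#' Read a 3-column interval track (BED)
#' @param path Path to a BED file.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   sorted per chromosome.
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Pipeline configuration
#'
#' Collects every input path and threshold in one validated object. All
#' input files default to the canonical names written by
#' [simulate_dataset()] under `indir`.
#'
#' @param indir Directory holding the input files.
#' @param min_total_reads Expression filter threshold, default 2.
#' @param min_treated_reads RNase-R raw read floor, default 20.
#' @param min_fold RNase-R scaled fold threshold, default 2.
#' @param s_threshold Specificity score threshold, default 0.5.
#' @param gda_threshold GDA score threshold (strict), default 0.1.
#' @param jaccard_threshold Term-slimming similarity, default 0.7.
#' @param snp_window SNP proximity window in bp, default 1e6.
#' @param group_map Cell-type to group mapping, default
#'   [default_group_map()].
#' @param seed Seed recorded in output headers.
#' @param stages Stages to run, in dependency order; subset of
#'   `filter`, `specificity`, `loci`, `features`, `enrich`, `diffexp`.
#' @param ... Overrides for individual input paths (`circ_bed`, `counts`,
#'   `samples`, `gtf`, `linear_donor`, `linear_acceptor`, `fpkm`,
#'   `rnase_counts`, `rnase_pairs`, `disease_counts`, `disease_samples`,
#'   `gmt`, `gda`, `snps`, `repeats`, `eclip`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(indir,
                            min_total_reads = 2L,
                            min_treated_reads = 20L,
                            min_fold = 2.0,
                            s_threshold = 0.5,
                            gda_threshold = 0.1,
                            jaccard_threshold = 0.7,
                            snp_window = 1e6,
                            group_map = default_group_map(),
                            seed = 1L,
                            stages = c("filter", "specificity", "loci",
                                       "features", "enrich", "diffexp"),
                            ...) {
  paths <- list(circ_bed = "circ_calls.bed", counts = "bsj_counts.tsv",
                samples = "samples.tsv", gtf = "genes.gtf",
                linear_donor = "linear_donor.tsv",
                linear_acceptor = "linear_acceptor.tsv",
                fpkm = "fpkm.tsv", rnase_counts = "rnase_counts.tsv",
                rnase_pairs = "rnase_pairs.tsv",
                disease_counts = "disease_counts.tsv",
                disease_samples = "disease_samples.tsv",
                gmt = "gene_sets.gmt", gda = "gda.tsv", snps = "snps.tsv",
                repeats = "repeats.bed", eclip = "eclip.bed")
  paths <- lapply(paths, function(p) file.path(indir, p))
  over <- list(...)
  unknown <- setdiff(names(over), names(paths))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  paths[names(over)] <- over
  bad_stage <- setdiff(stages, c("filter", "specificity", "loci",
                                 "features", "enrich", "diffexp"))
  if (length(bad_stage)) stop("unknown stages: ",
                              paste(bad_stage, collapse = ", "))
  if (min_total_reads < 0 || min_treated_reads < 0 || min_fold < 0 ||
      s_threshold < 0 || s_threshold > 1 || gda_threshold < 0 ||
      gda_threshold > 1 || jaccard_threshold < 0 || jaccard_threshold > 1 ||
      snp_window < 0)
    stop("threshold outside its documented range")
  cfg <- c(paths, list(min_total_reads = min_total_reads,
                       min_treated_reads = min_treated_reads,
                       min_fold = min_fold, s_threshold = s_threshold,
                       gda_threshold = gda_threshold,
                       jaccard_threshold = jaccard_threshold,
                       snp_window = snp_window, group_map = group_map,
                       seed = seed, stages = stages))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  # hash the effective settings; input paths enter as basenames so the
  # same configuration hashes identically wherever the tree lives
  cfg <- unclass(config)
  is_path <- vapply(cfg, is.character, TRUE) &
    names(cfg) != "stages" & lengths(cfg) == 1L &
    !names(cfg) %in% c("seed")
  cfg[is_path] <- lapply(cfg[is_path], basename)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config) {
  sprintf("circtype %s; config=%s; seed=%s",
          as.character(utils::packageVersion("circtype")),
          config_hash(config), config$seed)
}

read_fpkm_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

group_summed_ratios <- function(counts, donor, acceptor, samples,
                                pseudocount = 1) {
  groups <- unique(samples$group)
  out <- NULL
  for (g in groups) {
    cols <- samples$sample_id[samples$group == g]
    cc <- rowSums(counts[, cols, drop = FALSE])
    dd <- rowSums(donor[, cols, drop = FALSE])
    aa <- rowSums(acceptor[, cols, drop = FALSE])
    out <- rbind(out, data.frame(
      circ_id = rownames(counts), group = g,
      circ_reads = cc, donor_linear = dd, acceptor_linear = aa,
      ratio = circ_linear_ratio(cc, dd, aa, pseudocount),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", output_header(config)), con)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full downstream circRNA pipeline
#'
#' Executes the configured stages in dependency order (filter ->
#' specificity -> loci -> features -> enrich -> diffexp), writes one TSV
#' per stage plus a summary table under `outdir`, and returns all results
#' in memory. Every output carries a header comment with the package
#' version, a hash of the effective configuration and the seed, and
#' re-running with identical inputs reproduces byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with per-stage results and `summary`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  needed <- c("counts", "samples")
  for (p in needed)
    if (!file.exists(config[[p]]))
      stop("input file missing before any stage ran: ", config[[p]])
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  summary_rows <- list()
  note <- function(stage, metric, value)
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, metric = metric, value = value,
                 stringsAsFactors = FALSE)

  counts <- read_count_matrix(config$counts)
  samples <- read_sample_table(config$samples, config$group_map)
  circs <- if (file.exists(config$circ_bed)) read_circ_bed(config$circ_bed)
           else NULL
  host_map <- if (!is.null(circs))
    stats::setNames(circs$host_gene, circs$circ_id) else NULL
  run <- function(stage) stage %in% config$stages
  validated_ids <- rownames(counts)

  if (run("filter")) {
    expressed <- filter_expressed(counts, config$min_total_reads)
    rn_counts <- read_count_matrix(config$rnase_counts)
    rn_pairs <- read_sample_table(config$rnase_pairs, config$group_map)
    vres <- rnase_validate(rn_counts, rn_pairs,
                           config$min_treated_reads, config$min_fold)
    vres$expressed <- vres$circ_id %in% expressed
    vres$validated <- vres$validated & vres$expressed
    validated_ids <- vres$circ_id[vres$validated]
    note("filter", "candidates", nrow(counts))
    note("filter", "expressed", length(expressed))
    note("filter", "validated", length(validated_ids))
    note("filter", "validation_rate_pct",
         validation_rate(length(validated_ids), nrow(counts)))
    if (!is.null(circs)) {
      for (cls in c("exonic", "ciRNA")) {
        ids <- circs$circ_id[circs$circ_class == cls]
        ids <- intersect(ids, vres$circ_id)
        if (length(ids))
          note("filter", paste0("validation_rate_", cls, "_pct"),
               validation_rate(sum(validated_ids %in% ids), length(ids),
                               digits = 2L))
      }
    }
    res$filter <- vres
    write_stage_tsv(vres, file.path(outdir, "validation.tsv"), config)
  }

  if (run("specificity")) {
    lib <- stats::setNames(samples$library_size, samples$sample_id)
    rpm <- rpm_normalize(counts[validated_ids, , drop = FALSE], lib)
    spec <- classify_specific(rpm, samples, config$s_threshold)
    res$specificity <- spec
    write_stage_tsv(spec, file.path(outdir, "specificity.tsv"), config)
    for (g in unique(spec$group))
      note("specificity", paste0("specific_", g),
           sum(spec$is_specific & spec$group == g))
    if (file.exists(config$fpkm) && !is.null(host_map)) {
      fpkm <- read_fpkm_matrix(config$fpkm)
      spec_lin <- classify_specific(fpkm, samples, config$s_threshold)
      cmp <- compare_circ_vs_linear(spec, spec_lin, host_map)
      res$circ_vs_linear <- cmp
      note("specificity", "circ_vs_linear_median_delta",
           round(cmp$median_delta, 4))
      note("specificity", "circ_vs_linear_p", signif(cmp$p_value, 4))
    }
  }

  if (run("loci")) {
    if (is.null(res$specificity)) stop("stage 'loci' needs 'specificity'")
    loci <- classify_loci(res$specificity, host_map)
    res$loci <- loci
    write_stage_tsv(loci, file.path(outdir, "loci.tsv"), config)
    note("loci", "loci_with_specific_circ",
         sum(loci$architecture != "none"))
    note("loci", "super_host", sum(loci$architecture == "super-host"))
    for (g in unique(res$specificity$group))
      note("loci", paste0("exclusive_", g),
           sum(loci$architecture == paste0("exclusive-", g)))
    donor <- read_count_matrix(config$linear_donor)
    acceptor <- read_count_matrix(config$linear_acceptor)
    hc <- samples[samples$condition == "HC", , drop = FALSE]
    ratios <- group_summed_ratios(counts[validated_ids, , drop = FALSE],
                                  donor[validated_ids, , drop = FALSE],
                                  acceptor[validated_ids, , drop = FALSE],
                                  hc)
    res$ratios <- ratios
    write_stage_tsv(ratios, file.path(outdir, "circ_linear_ratios.tsv"),
                    config)
    cmpr <- compare_ratio_groups(ratios$ratio, ratios$group)
    res$ratio_test <- cmpr
    note("loci", "ratio_neuron_vs_nonneuron_p", signif(cmpr$p_value, 4))
  }

  if (run("features")) {
    models <- read_gtf_models(config$gtf)
    vcircs <- circs[circs$circ_id %in% validated_ids, , drop = FALSE]
    cpe <- circ_per_gene_vs_exons(circs, models)
    res$circ_per_gene <- cpe
    note("features", "circ_vs_exon_pearson_r",
         round(attr(cpe, "pearson_r"), 4))
    feats <- data.frame(circ_id = vcircs$circ_id,
                        exon_len_total = vapply(vcircs$blocks,
                                                function(b) sum(b[, 2L]), 0),
                        stringsAsFactors = FALSE)
    fl <- lapply(seq_len(nrow(vcircs)), function(i)
      flanking_introns(c(as.list(vcircs[i, setdiff(names(vcircs), "blocks")]),
                         list(blocks = vcircs$blocks[[i]])),
                       models, strict = FALSE))
    feats$upstream_intron_len <- vapply(fl, function(f)
      if (is.null(f$upstream)) NA_real_ else diff(f$upstream), 0)
    feats$downstream_intron_len <- vapply(fl, function(f)
      if (is.null(f$downstream)) NA_real_ else diff(f$downstream), 0)
    if (file.exists(config$eclip)) {
      eclip <- read_track(config$eclip)
      feats$rbp_peaks <- overlap_count(vcircs, eclip)
    }
    if (file.exists(config$repeats)) {
      reps <- read_track(config$repeats)
      up_ok <- !is.na(feats$upstream_intron_len)
      feats$upstream_repeats <- NA_integer_
      if (any(up_ok)) {
        up_iv <- do.call(rbind, lapply(fl[up_ok], `[[`, "upstream"))
        feats$upstream_repeats[up_ok] <- overlap_count(
          data.frame(chrom = vcircs$chrom[up_ok], start = up_iv[, 1L],
                     end = up_iv[, 2L]), reps)
      }
    }
    res$features <- feats
    write_stage_tsv(feats, file.path(outdir, "features.tsv"), config)
    if (file.exists(config$snps)) {
      snps <- read_snp_table(config$snps)
      frac <- snp_proximity_fraction(snps, vcircs, config$snp_window)
      note("features", "snp_proximity_pct", round(100 * frac, 1))
    }
  }

  if (run("enrich")) {
    if (is.null(res$specificity)) stop("stage 'enrich' needs 'specificity'")
    models <- read_gtf_models(config$gtf)
    universe <- names(models)
    sp <- specific_set(res$specificity)
    hosts_by_group <- lapply(split(sp$id, sp$assigned_group),
                             function(ids) unique(unname(host_map[ids])))
    if (file.exists(config$gmt)) {
      sets <- read_gmt(config$gmt)
      enr <- NULL
      for (g in names(hosts_by_group)) {
        fe <- fisher_enrich(hosts_by_group[[g]], sets, universe)
        fe <- slim_terms(fe, config$jaccard_threshold)
        fe$group <- g
        enr <- rbind(enr, fe[, c("group", "set_id", "k", "K", "n", "N",
                                 "odds_ratio", "p", "q")])
      }
      res$enrichment <- enr
      write_stage_tsv(enr, file.path(outdir, "enrichment.tsv"), config)
      note("enrich", "enriched_terms_q05", sum(enr$q < 0.05))
    }
    if (file.exists(config$gda)) {
      gda <- read_gda(config$gda, config$gda_threshold)
      dis <- disease_enrich(hosts_by_group, gda, universe,
                            brain_only = FALSE)
      res$disease_enrichment <- dis
      write_stage_tsv(dis, file.path(outdir, "disease_enrichment.tsv"),
                      config)
      note("enrich", "enriched_diseases_q05", sum(dis$q < 0.05))
    }
  }

  if (run("diffexp")) {
    dcounts <- read_count_matrix(config$disease_counts)
    dsamples <- read_sample_table(config$disease_samples, config$group_map)
    gene_counts <- aggregate_to_gene(dcounts, host_map)
    de <- nb_wald(gene_counts, dsamples, "ILB", "HC")
    res$diffexp <- de
    volcano <- data.frame(gene_id = de$gene_id,
                          log2_fold_change = de$log2_fold_change,
                          neg_log10_p = -log10(de$p),
                          stringsAsFactors = FALSE)
    write_stage_tsv(de, file.path(outdir, "diffexp.tsv"), config)
    write_stage_tsv(volcano, file.path(outdir, "volcano.tsv"), config)
    note("diffexp", "de_genes_q05", sum(de$q < 0.05, na.rm = TRUE))
  }

  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
             else data.frame(stage = character(), metric = character(),
                             value = numeric())
  res$summary <- summary
  write_stage_tsv(summary, file.path(outdir, "summary.tsv"), config)
  invisible(res)
}
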