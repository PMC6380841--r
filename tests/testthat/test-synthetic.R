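# Synthetic-data generators: determinism, structural invariants, and the
# planted-signal construction guarantees downstream stages rely on.

test_that("genome annotation is deterministic and structurally valid", {
  cfg <- sim_config(n_chromosomes = 2L, n_genes = 30L, n_lnc = 20L,
                    chrom_length_bp = 2e6, seed = 7L)
  ann1 <- simulate_genome_annotation(cfg)
  ann2 <- simulate_genome_annotation(cfg)
  expect_identical(ann1, ann2)
  g <- ann1$genes
  expect_equal(nrow(g), 50L)
  expect_true(all(g$start < g$end))
  expect_true(all(g$tss >= g$start & g$tss < g$end))
  for (id in g$gene_id) {
    ex <- ann1$exons[ann1$exons$gene_id == id, ]
    expect_true(all(ex$start < ex$end))
    expect_true(all(ex$start >= g$start[g$gene_id == id]))
    expect_true(all(ex$end <= g$end[g$gene_id == id]))
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
  # genes non-overlapping within a strand (here by construction on both)
  for (st in c("+", "-")) {
    gs <- g[g$strand == st, ]
    gs <- gs[order(gs$chrom, gs$start), ]
    same <- gs$chrom[-1] == gs$chrom[-nrow(gs)]
    expect_true(all(gs$start[-1][same] >= gs$end[-nrow(gs)][same]))
  }
  ann3 <- simulate_genome_annotation(sim_config(n_chromosomes = 2L,
                                                n_genes = 30L, n_lnc = 20L,
                                                chrom_length_bp = 2e6,
                                                seed = 8L))
  expect_false(identical(ann1$genes, ann3$genes))
})

test_that("annotation refuses a chromosome too short for the request", {
  expect_error(
    simulate_genome_annotation(sim_config(n_genes = 500L, n_lnc = 0L,
                                          chrom_length_bp = 1e6)),
    "chromosome too short")
})

test_that("empty gene file round-trips with a valid header", {
  d <- withr::local_tempdir()
  simulate_genome_annotation(sim_config(n_genes = 0L, n_lnc = 0L), out_dir = d)
  expect_identical(readLines(file.path(d, "genes.gtf"))[1], "##format: gtf")
  rt <- read_gtf(file.path(d, "genes.gtf"))
  expect_equal(nrow(rt$genes), 0L)
})

test_that("noiseless time course plants exact fold changes", {
  cfg <- quick_cfg(noise_sd = 0, effect_fold = 4, seed = 3L)
  ann <- simulate_genome_annotation(cfg)
  expr <- simulate_expression_timecourse(cfg, ann)
  tp <- expr$metadata$timepoint
  tp_means <- vapply(unique(tp), function(t)
    rowMeans(expr$fpkm[, tp == t, drop = FALSE]), numeric(nrow(expr$fpkm)))
  fold <- apply(tp_means, 1, max) / apply(tp_means, 1, min)
  planted <- rownames(expr$fpkm) %in% expr$truth$dynamic_lnc_ids
  module_coding <- setdiff(names(expr$truth$module_assignments),
                           expr$truth$dynamic_lnc_ids)
  flat <- !rownames(expr$fpkm) %in% names(expr$truth$module_assignments)
  expect_equal(unname(fold[planted]), rep(4, sum(planted)), tolerance = 1e-12)
  expect_equal(unname(fold[flat]), rep(1, sum(flat)), tolerance = 1e-12)
})

test_that("planted module members are strongly co-expressed at low noise", {
  cfg <- quick_cfg(noise_sd = 0.1, seed = 11L)
  ann <- simulate_genome_annotation(cfg)
  expr <- simulate_expression_timecourse(cfg, ann)
  mods <- expr$truth$module_assignments
  for (m in unique(unlist(mods))) {
    ids <- names(mods)[unlist(mods) == m]
    r <- cor(t(expr$fpkm[ids, ]))
    expect_true(all(r[upper.tri(r)] > 0.5))
  }
})

test_that("RIP construction: replicate-stable planted ratios, unit background", {
  cfg0 <- quick_cfg(noise_sd = 0, seed = 5L)
  ann <- simulate_genome_annotation(cfg0)
  expr <- simulate_expression_timecourse(cfg0, ann)
  lnc <- expr$biotype$gene_id[expr$biotype$biotype == "noncoding"]
  rip <- simulate_rip_assay(cfg0, lnc, expr$truth$chromatin_assoc_ids)
  ratio <- rip$rpkm_h3 / rip$rpkm_igg
  planted <- rip$transcript_id %in% expr$truth$chromatin_assoc_ids
  # noiseless: the ratio is identical across replicates
  for (id in unique(rip$transcript_id)) {
    expect_equal(diff(range(ratio[rip$transcript_id == id])), 0, tolerance = 1e-12)
  }
  expect_true(all(ratio[planted] >= 4))
  expect_equal(unname(ratio[!planted]), rep(1, sum(!planted)), tolerance = 1e-12)
  # noisy: planted ratios still >= 4 in every replicate by construction
  cfg1 <- quick_cfg(noise_sd = 0.1, seed = 5L)
  rip1 <- simulate_rip_assay(cfg1, lnc, expr$truth$chromatin_assoc_ids)
  expect_true(all(rip1$rpkm_h3[rip1$transcript_id %in% expr$truth$chromatin_assoc_ids] /
                    rip1$rpkm_igg[rip1$transcript_id %in% expr$truth$chromatin_assoc_ids] >= 4))
  expect_error(simulate_rip_assay(cfg1, lnc, c("NOT_A_TRANSCRIPT")),
               "subset")
})

test_that("CNV cohort plants the exact focal 2x2 table when background is off", {
  cfg <- quick_cfg(background_cnv_rate = 0, planted_case_hits = 10L, seed = 2L)
  ann <- simulate_genome_annotation(cfg)
  loci <- lnc_loci(ann)
  coding <- ann$genes[ann$genes$biotype == "coding", ]
  sim <- simulate_cnv_cohort(cfg, loci, coding)
  focal <- loci[loci$name == sim$truth$focal_locus_id, ]
  cases <- sim$cnvs[sim$cnvs$cohort == "case", ]
  controls <- sim$cnvs[sim$cnvs$cohort == "control", ]
  expect_equal(count_locus_hits(focal, cases), 10L)
  expect_equal(nrow(controls), 0L)
  # planted CNVs overlap no coding gene
  expect_true(all(classify_focal(cases, focal, coding)))
  # no planting, no background: the locus is silent
  cfg0 <- quick_cfg(background_cnv_rate = 0, planted_case_hits = 0L, seed = 2L)
  sim0 <- simulate_cnv_cohort(cfg0, loci, coding)
  expect_equal(nrow(sim0$cnvs), 0L)
})

test_that("planting fails when the focal locus overlaps a coding gene", {
  cfg <- quick_cfg(seed = 4L)
  ann <- simulate_genome_annotation(cfg)
  coding <- ann$genes[ann$genes$biotype == "coding", ]
  bad_locus <- data.frame(name = "BAD", chrom = coding$chrom[1],
                          start = coding$start[1], end = coding$end[1],
                          stringsAsFactors = FALSE)
  expect_error(simulate_cnv_cohort(cfg, bad_locus, coding, focal_locus = "BAD"),
               "focal")
})

test_that("ChIRP decoys violate exactly their designated criterion", {
  cfg <- sim_config(seed = 9L)
  study <- simulate_study(cfg)
  peaks <- study$chirp$peaks
  hc_all <- high_confidence_filter(peaks, study$chirp$even, study$chirp$odd,
                                   min_neglog10_p = 0, min_corr = -2,
                                   min_cov = -1)
  st <- hc_all[match(peaks$name, hc_all$name), ]
  classes <- unlist(study$truth$decoy_classes)
  planted <- study$truth$planted_peaks
  expect_true(all(st$evenodd_corr[st$name %in% planted] > 0))
  expect_true(all(st$mean_coverage[st$name %in% planted] > 2))
  expect_true(all(st$neglog10_p[st$name %in% planted] >= 100))
  anticorr <- names(classes)[classes == "anticorr"]
  expect_true(all(st$evenodd_corr[st$name %in% anticorr] < 0))
  expect_true(all(st$mean_coverage[st$name %in% anticorr] > 2))
  expect_true(all(st$neglog10_p[st$name %in% anticorr] >= 100))
  low_cov <- names(classes)[classes == "low_cov"]
  expect_true(all(st$mean_coverage[st$name %in% low_cov] <= 2))
  expect_true(all(st$evenodd_corr[st$name %in% low_cov] > 0))
  expect_true(all(st$neglog10_p[st$name %in% low_cov] >= 100))
  low_p <- names(classes)[classes == "low_p"]
  expect_true(all(st$neglog10_p[st$name %in% low_p] < 100))
  expect_true(all(st$evenodd_corr[st$name %in% low_p] > 0))
  expect_true(all(st$mean_coverage[st$name %in% low_p] > 2))
  # RNase control: at most 10% of the even signal in planted peaks, above it
  # in rnase_high decoys
  rnase_mean <- function(pk) {
    sapply(seq_len(nrow(pk)), function(i) {
      r <- study$chirp$rnase
      sel <- r$chrom == pk$chrom[i] & r$start >= pk$start[i] & r$end <= pk$end[i]
      e <- study$chirp$even
      sele <- e$chrom == pk$chrom[i] & e$start >= pk$start[i] & e$end <= pk$end[i]
      mean(r$value[sel]) / mean(e$value[sele])
    })
  }
  expect_true(all(rnase_mean(peaks[peaks$name %in% planted, ]) <= 0.1))
  rn_high <- names(classes)[classes == "rnase_high"]
  expect_true(all(rnase_mean(peaks[peaks$name %in% rn_high, ]) >= 1))
})

test_that("generated files round-trip through the package readers", {
  d <- withr::local_tempdir()
  cfg <- quick_cfg(seed = 21L)
  study <- simulate_study(cfg, out_dir = d)
  rt <- read_gtf(file.path(d, "genes.gtf"))
  g0 <- study$annotation$genes[order(study$annotation$genes$gene_id), ]
  g1 <- rt$genes[order(rt$genes$gene_id), c(names(g0))]
  rownames(g0) <- rownames(g1) <- NULL
  expect_equal(g1, g0)
  ex0 <- study$annotation$exons[order(study$annotation$exons$gene_id,
                                      study$annotation$exons$start), ]
  ex1 <- rt$exons[order(rt$exons$gene_id, rt$exons$start), names(ex0)]
  rownames(ex0) <- rownames(ex1) <- NULL
  expect_equal(ex1, ex0)
  expect_equal(read_chrom_sizes(file.path(d, "chrom.sizes")),
               study$annotation$chrom_sizes)
  m <- read_tsv_matrix(file.path(d, "expression.tsv"))
  expect_equal(m, study$expression$fpkm, tolerance = 1e-9)
  expect_equal(read_bedgraph(file.path(d, "chirp_even.bedGraph")),
               study$chirp$even, ignore_attr = TRUE, tolerance = 1e-9)
  pk <- read_narrowpeak(file.path(d, "chirp_peaks.narrowPeak"))
  expect_equal(pk$neglog10_p, study$chirp$peaks$neglog10_p, tolerance = 1e-9)
  expect_equal(pk$name, study$chirp$peaks$name)
  cn <- read_cnv_tsv(file.path(d, "cnv.tsv"))
  expect_equal(cn, study$cnv$cnvs, ignore_attr = TRUE)
  gs <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_equal(gs, study$expression$gene_sets)
  tr <- read_truth(file.path(d, "study.truth.json"))
  expect_equal(tr$dynamic_lnc_ids, study$truth$dynamic_lnc_ids)
  expect_equal(tr$focal_locus_id, study$truth$focal_locus_id)
})
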