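# Track merging, replicate consensus, the high-confidence filter,
# regulatory domains, peak assignment and annotation.

test_that("even/odd merge is the pointwise minimum, idempotent and commutative", {
  even <- track(c(0, 100, 200), c(100, 200, 300), c(3, 5, 2))
  odd <- track(c(50, 150), c(150, 250), c(5, 1))
  m <- merge_even_odd(even, odd)
  # value at sampled positions equals min of the two inputs
  val_at <- function(tr, pos) {
    v <- rep(0, length(pos))
    for (i in seq_len(nrow(tr))) v[pos >= tr$start[i] & pos < tr$end[i]] <- tr$value[i]
    v
  }
  pos <- 0:299
  expect_equal(val_at(m, pos), pmin(val_at(even, pos), val_at(odd, pos)))
  expect_equal(merge_even_odd(odd, even)[, c("start", "end", "value")],
               m[, c("start", "end", "value")])
  expect_equal(merge_even_odd(even, even), even, ignore_attr = TRUE)
  expect_equal(merge_even_odd(m, m), m)
  # overlapping steps 3.0 vs 5.0 merge to 3.0
  e1 <- track(0, 100, 3); o1 <- track(0, 100, 5)
  expect_equal(merge_even_odd(e1, o1)$value, 3)
  # absorbing zero: disjoint support means empty merged track
  o0 <- track(1000, 1100, 4)
  expect_equal(nrow(merge_even_odd(e1, o0)), 0L)
})

test_that("merge refuses mismatched chromosome sets, naming the difference", {
  e <- track(0, 10, 1, chrom = "chr1")
  o <- track(0, 10, 1, chrom = "chr2")
  expect_error(merge_even_odd(e, o), "chr1")
  expect_error(merge_even_odd(e, o), "chr2")
})

peak_df <- function(start, end, neglog10_p = 150, chrom = "chr1",
                    name = NULL) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), neglog10_p = neglog10_p,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  df
}

test_that("consensus retains reference peaks overlapping every other replicate", {
  ref <- peak_df(c(100, 500, 900), c(200, 600, 1000), c(150, 120, 200))
  same <- list(ref, ref, ref)
  expect_equal(consensus_peaks(same), ref, ignore_attr = TRUE)
  # present in 3 of 4 replicates -> dropped under the all-replicates rule
  rep2 <- peak_df(c(150, 950), c(250, 1050), c(110, 90))
  rep3 <- peak_df(c(120, 520, 920), c(220, 620, 1020), c(300, 300, 300))
  rep4 <- peak_df(c(90, 490, 890), c(210, 610, 1010), c(100, 100, 100))
  out <- consensus_peaks(list(ref, rep2, rep3, rep4))
  expect_equal(out$start, c(100, 900))  # middle peak missing from rep2
  # reference coordinates kept; statistic is the minimum across matches
  expect_equal(out$neglog10_p, c(100, 90))
  expect_error(consensus_peaks(list(ref)), "two replicate")
})

test_that("consensus agrees with a brute-force overlap check on staggered peaks", {
  set.seed(17)
  for (trial in 1:10) {
    mk <- function(n) {
      s <- sort(sample.int(5e4, n))
      peak_df(s, s + sample(100:400, n, replace = TRUE),
              runif(n, 50, 300))
    }
    ref <- mk(15); other <- mk(15)
    out <- consensus_peaks(list(ref, other))
    keep <- vapply(seq_len(nrow(ref)), function(i)
      nrow(brute_overlap(ref[i, ], other)) > 0, logical(1))
    expect_equal(out$start, ref$start[keep])
  }
})

test_that("high-confidence filter honors the printed boundary semantics", {
  # 4-step tracks engineered so correlation and coverage hit exact boundaries
  steps <- function(v, start = 0) track(start + 0:3 * 25, start + 1:4 * 25, v)
  even <- steps(c(1, 2, 3, 4))
  odd_zero_r <- steps(c(2, 4, 1, 3))   # Pearson r exactly 0
  pk <- peak_df(0, 100, 100)
  # -log10 p = 100 is eligible, 99.9 is not (>= as printed)
  expect_equal(nrow(high_confidence_filter(peak_df(0, 100, 100), even,
                                           steps(c(1, 2, 3, 4.2)),
                                           min_cov = 1)), 1L)
  expect_equal(nrow(high_confidence_filter(peak_df(0, 100, 99.9), even,
                                           steps(c(1, 2, 3, 4.2)),
                                           min_cov = 1)), 0L)
  # correlation must strictly exceed 0: r = 0 is dropped
  expect_equal(nrow(high_confidence_filter(pk, even, odd_zero_r, min_cov = 1)), 0L)
  # anti-correlated even/odd is dropped
  expect_equal(nrow(high_confidence_filter(pk, even, steps(c(4, 3, 2, 1)),
                                           min_cov = 0)), 0L)
  # coverage must strictly exceed the threshold: mean exactly 2 is dropped
  ev2 <- steps(c(1.9, 2.1, 1.9, 2.1)); od2 <- steps(c(1.9, 2.1, 1.9, 2.1))
  expect_equal(nrow(high_confidence_filter(pk, ev2, od2, min_cov = 2)), 0L)
  expect_equal(nrow(high_confidence_filter(pk, ev2, od2, min_cov = 1.9)), 1L)
})

test_that("peaks with fewer than two resolved steps are dropped and flagged", {
  even <- track(0, 1000, 5); odd <- track(0, 1000, 5)
  pk <- peak_df(100, 200, 150, name = "p1")
  out <- high_confidence_filter(pk, even, odd, min_cov = 1)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "flagged"), "p1")
})

test_that("high-confidence filter is monotone in each threshold", {
  cfg <- sim_config(seed = 13L)
  study <- simulate_study(cfg)
  pk <- study$chirp$peaks; ev <- study$chirp$even; od <- study$chirp$odd
  for (arg in c("min_neglog10_p", "min_corr", "min_cov")) {
    vals <- switch(arg, min_neglog10_p = c(0, 50, 100, 200),
                   min_corr = c(-1, 0, 0.5, 0.9), min_cov = c(0, 1, 2, 5))
    prev <- NULL
    for (v in vals) {
      args <- list(peaks = pk, even = ev, odd = od)
      args[[arg]] <- v
      ids <- do.call(high_confidence_filter, args)$name
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("regulatory domains reproduce the worked basal-plus-extension cases", {
  cs <- data.frame(chrom = "chr1", length = 3000000L)
  # isolated + strand gene: basal 5 kb up / 1 kb down, +-1000 kb extension
  g <- gene_df("G1", "chr1", "+", 1500000, 1510000)
  d <- build_regulatory_domains(g, cs)
  expect_equal(d$basal_start, 1495000L)
  expect_equal(d$basal_end, 1501000L)
  expect_equal(d$start, 495000L)
  expect_equal(d$end, 2501000L)
  # abutting neighbors stop at each other's basal boundary
  g2 <- rbind(gene_df("A", "chr1", "+", 100000, 120000),
              gene_df("B", "chr1", "+", 150000, 170000))
  d2 <- build_regulatory_domains(g2, cs)
  expect_equal(d2$end[d2$gene_id == "A"], 145000L)   # B's basal start
  expect_equal(d2$start[d2$gene_id == "B"], 101000L) # A's basal end
  # chromosome-edge clipping of the basal window
  g3 <- gene_df("E", "chr1", "+", 2000, 9000)
  d3 <- build_regulatory_domains(g3, cs)
  expect_equal(d3$basal_start, 0L)
  expect_equal(d3$start, 0L)
  # off-chromosome gene fails
  expect_error(build_regulatory_domains(gene_df("X", "chr1", "+", 2999000, 3001000), cs),
               "bounds")
})

test_that("domains never invade a neighbor basal region and contain their own", {
  set.seed(23)
  for (trial in 1:10) {
    n <- sample(5:20, 1)
    tss <- sort(sample.int(480000, n) + 10000)
    g <- gene_df(sprintf("G%02d", 1:n), "chr1", sample(c("+", "-"), n, TRUE),
                 tss, tss + 5000)
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    cs <- data.frame(chrom = "chr1", length = 500000L)
    d <- build_regulatory_domains(g, cs, max_ext = 50000)
    expect_true(all(d$start <= d$basal_start & d$end >= d$basal_end))
    for (i in seq_len(n)) for (j in setdiff(seq_len(n), i)) {
      ov <- min(d$end[i], d$basal_end[j]) - max(d$start[i], d$basal_start[j])
      if (ov > 0) {
        # any invasion of a neighbor basal must already be basal-basal overlap
        bas_ov <- min(d$basal_end[i], d$basal_end[j]) -
          max(d$basal_start[i], d$basal_start[j])
        expect_true(bas_ov >= ov)
      }
    }
  }
})

test_that("peak-to-gene assignment matches brute force and the overlap rule", {
  cs <- data.frame(chrom = "chr1", length = 1000000L)
  g <- rbind(gene_df("A", "chr1", "+", 100000, 120000),
             gene_df("B", "chr1", "+", 150000, 170000))
  d <- build_regulatory_domains(g, cs)
  # peak inside exactly one domain (A's basal; B's extension stops there)
  one <- assign_peaks_to_genes(peak_df(100200, 100700, name = "p1"), d)
  expect_equal(one$map$gene_id, "A")
  # a peak between the basal regions lies in both extensions
  two <- assign_peaks_to_genes(peak_df(120000, 120500, name = "p1b"), d)
  expect_equal(sort(two$genes), c("A", "B"))
  # peak straddling two abutting domains maps to both
  both <- assign_peaks_to_genes(peak_df(144900, 145100, name = "p2"), d)
  expect_equal(sort(both$genes), c("A", "B"))
  # random fixture vs brute force
  set.seed(5)
  n <- 300
  s <- sample.int(990000, n)
  pks <- peak_df(s, s + 500, name = sprintf("p%03d", seq_len(n)))
  tss <- sort(sample.int(950000, 50))
  gg <- gene_df(sprintf("G%02d", 1:50), "chr1", "+", tss, tss + 2000)
  dd <- build_regulatory_domains(gg, cs, max_ext = 20000)
  asg <- assign_peaks_to_genes(pks, dd)
  bf <- brute_overlap(pks, dd)
  expect_equal(nrow(asg$map), nrow(bf))
  expect_setequal(paste(asg$map$peak, asg$map$gene_id),
                  paste(pks$name[bf[, "query"]], dd$gene_id[bf[, "subject"]]))
})

test_that("peak categories follow the strand-aware priority windows", {
  g <- rbind(gene_df("G1", "chr1", "+", 100000, 110000),
             gene_df("G2", "chr1", "-", 300000, 310000))
  ex <- data.frame(gene_id = c("G1", "G1", "G2"),
                   start = c(100000L, 105000L, 300000L),
                   end = c(101000L, 106000L, 310000L))
  cat_of <- function(mid) annotate_peaks(peak_df(mid - 50, mid + 50), g, ex)
  expect_equal(cat_of(100500), "promoter")     # 500 bp downstream of + TSS
  expect_equal(cat_of(94000), "enhancer")      # 6 kb upstream
  expect_equal(cat_of(600000), "intergenic")   # far from any gene
  expect_equal(cat_of(105500), "exon")
  expect_equal(cat_of(103000), "intron")
  expect_equal(cat_of(111000), "gene_tail")    # 1 kb past the + gene end
  # minus-strand gene: TSS at the right end, upstream to the right
  expect_equal(cat_of(309800), "promoter")
  expect_equal(cat_of(315000), "enhancer")
  expect_equal(cat_of(299500), "gene_tail")
})

test_that("nearest gene minimizes TSS distance with lexicographic ties", {
  g <- rbind(gene_df("B", "chr1", "+", 1000, 2000),
             gene_df("A", "chr1", "+", 3000, 4000),
             gene_df("C", "chr2", "-", 5000, 6000))
  # midpoint on a TSS
  expect_equal(nearest_gene(peak_df(950, 1050), g)$gene_id, "B")
  expect_equal(nearest_gene(peak_df(950, 1050), g)$distance, 0)
  # equidistant between B (tss 1000) and A (tss 3000): lexicographic winner
  expect_equal(nearest_gene(peak_df(1950, 2050), g)$gene_id, "A")
  # strand-relative sign: peak left of a minus-strand TSS is downstream (+)
  nm <- nearest_gene(peak_df(5000, 5100, chrom = "chr2"), g)
  expect_equal(nm$gene_id, "C")
  expect_equal(nm$distance, 5999 - 5050)
  # no gene on the chromosome -> unassigned
  expect_true(is.na(nearest_gene(peak_df(10, 20, chrom = "chr9"), g)$gene_id))
  # random fixture vs brute-force scan
  set.seed(3)
  s <- sample.int(9e5, 200)
  pks <- peak_df(s, s + 200)
  tsss <- sample.int(9e5, 40)
  gg <- gene_df(sprintf("G%02d", 1:40), "chr1", "+", tsss, tsss + 1000)
  res <- nearest_gene(pks, gg)
  for (i in seq_len(200)) {
    m <- (pks$start[i] + pks$end[i]) %/% 2
    dmin <- min(abs(m - gg$tss))
    cand <- sort(gg$gene_id[abs(m - gg$tss) == dmin])[1]
    expect_equal(res$gene_id[i], cand)
  }
})
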