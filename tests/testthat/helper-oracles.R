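# Independent oracles and shared fixtures for the suite. Oracles deliberately
# use brute-force or closed-form routes distinct from the implementation.

# O(n*m) interval intersection on 0-based half-open frames; returns index
# pairs (query row, subject row) with >= 1 bp overlap.
brute_overlap <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i])
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("query", "subject")
  out
}

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, summing probabilities no larger than the observed
# table's (with R's standard relative tie tolerance).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Hypergeometric upper-tail p by direct combinatorial summation.
hyper_enum_p <- function(k, set_size, universe_size, draw_size) {
  j <- k:min(set_size, draw_size)
  sum(choose(set_size, j) * choose(universe_size - set_size, draw_size - j)) /
    choose(universe_size, draw_size)
}

# Per-base oracle for basal-plus-extension regulatory domains. For each gene,
# marks every other gene's basal region on the chromosome and walks outward
# from the basal edges: a base belongs to the domain while it is within
# max_ext of the basal edge, inside the chromosome, and no blocked base lies
# between it and the basal edge.
domain_oracle <- function(genes, chrom_len, basal_up = 5000, basal_down = 1000,
                          max_ext = 1e6) {
  bs <- ifelse(genes$strand == "+", genes$tss - basal_up, genes$tss - basal_down + 1)
  be <- ifelse(genes$strand == "+", genes$tss + basal_down, genes$tss + basal_up + 1)
  bs <- pmax(bs, 0); be <- pmin(be, chrom_len)
  res <- genes[, "gene_id", drop = FALSE]
  res$start <- NA_integer_; res$end <- NA_integer_
  for (i in seq_len(nrow(genes))) {
    blocked <- logical(chrom_len)
    for (j in setdiff(seq_len(nrow(genes)), i)) {
      if (genes$chrom[j] != genes$chrom[i]) next
      if (be[j] > bs[j]) blocked[(bs[j] + 1):be[j]] <- TRUE  # 1-based indexing
    }
    lo <- max(bs[i] - max_ext, 0)
    left_slice <- if (bs[i] > lo) !blocked[(lo + 1):bs[i]] else logical(0)
    ok_left <- rev(cumprod(rev(left_slice))) > 0
    dstart <- if (length(ok_left) && ok_left[1]) lo else
      if (any(ok_left)) lo + min(which(ok_left)) - 1 else bs[i]
    hi <- min(be[i] + max_ext, chrom_len)
    right_slice <- if (hi > be[i]) !blocked[(be[i] + 1):hi] else logical(0)
    dend <- be[i] + sum(cumprod(right_slice))
    res$start[i] <- as.integer(dstart)
    res$end[i] <- as.integer(dend)
  }
  res$basal_start <- as.integer(bs)
  res$basal_end <- as.integer(be)
  res
}

# Reduced-scale configuration used where the full default study would be
# slower than the check requires.
quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 70L, n_lnc = 30L, chrom_length_bp = 5e6,
         n_cases = 100L, n_controls = 100L, planted_case_hits = 10L),
    list(...))
  do.call(sim_config, args)
}

# Minimal one-chromosome track builder.
track <- function(start, end, value, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             value = value, stringsAsFactors = FALSE)
}

# Minimal gene-model frame.
gene_df <- function(gene_id, chrom, strand, start, end) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = as.integer(start), end = as.integer(end),
             tss = as.integer(ifelse(strand == "+", start, end - 1)),
             biotype = "coding", stringsAsFactors = FALSE)
}
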