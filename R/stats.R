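# 2x2 exact and chi-square tests, gene-set overlap, and the random-peak
# permutation null with empirical p-values at peak and gene level.

.as_2x2 <- function(t) {
  if (is.matrix(t)) { stopifnot(all(dim(t) == c(2L, 2L))); return(t) }
  stopifnot(length(t) == 4L)
  matrix(as.numeric(t), nrow = 2, byrow = TRUE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Plain Pearson chi-square with 1 df (no continuity correction by default);
#' p from the upper tail. Fails on a zero margin, where the statistic is
#' undefined.
#'
#' @param t 2x2 table (matrix or length-4 vector a,b,c,d by row)
#' @param yates apply Yates continuity correction
#' @return list with `statistic`, `p`
#' @export
chi_square_2x2 <- function(t, yates = FALSE) {
  m <- .as_2x2(t)
  if (any(m < 0) || sum(m) == 0) stop("counts must be non-negative with N > 0")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square statistic undefined: zero margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by the point-probability method (summing the probabilities of
#' all tables with fixed margins no more probable than the observed one),
#' and the sample odds ratio with the Haldane-Anscombe 0.5 correction
#' applied to all cells when any cell is zero.
#'
#' @param t 2x2 table (matrix or length-4 vector a,b,c,d by row)
#' @return list with `p`, `odds_ratio`
#' @export
fisher_exact_2x2 <- function(t) {
  m <- .as_2x2(t)
  if (any(m < 0) || sum(m) == 0) stop("counts must be non-negative with N > 0")
  p <- stats::fisher.test(m)$p.value
  if (any(m == 0)) m <- m + 0.5
  list(p = min(p, 1), odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
}

#' Overlap test between two gene sets
#'
#' Builds the 2x2 table [[|A n B|, |A \ B|], [|B \ A|, |U \ (A u B)|]] and
#' reports both the Pearson chi-square result and the hypergeometric
#' upper-tail p for the overlap.
#'
#' @param setA,setB character vectors, subsets of `universe`
#' @param universe the gene universe
#' @return list with `table`, `chi_square` (list or NULL if undefined),
#'   `hyper_p`
#' @export
gene_set_overlap_test <- function(setA, setB, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  stopifnot(all(setA %in% universe), all(setB %in% universe))
  k <- length(intersect(setA, setB))
  tab <- matrix(c(k, length(setA) - k,
                  length(setB) - k,
                  length(universe) - length(union(setA, setB))),
                nrow = 2, byrow = TRUE)
  chi <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
  hyper_p <- stats::phyper(k - 1, length(setB),
                           length(universe) - length(setB), length(setA),
                           lower.tail = FALSE)
  list(table = tab, chi_square = chi, hyper_p = hyper_p)
}

#' Sample random peaks matched to a template
#'
#' Draws, per chromosome, the same number of peaks with identical widths as
#' the template, at uniform start positions; peaks falling in `exclude` are
#' rejection-resampled. Deterministic for a given (seed, iteration) pair.
#'
#' @param template_peaks peak data.frame (chrom, start, end)
#' @param chrom_sizes chromosome sizes (chrom, length)
#' @param seed integer seed
#' @param iteration iteration index mixed into the seed, so permutation
#'   streams are independent of execution order
#' @param exclude optional interval data.frame; sampled peaks must not
#'   overlap it
#' @param max_tries bound on rejection resampling rounds
#' @return data.frame (chrom, start, end)
#' @export
sample_random_peaks <- function(template_peaks, chrom_sizes, seed,
                                iteration = 0L, exclude = NULL,
                                max_tries = 1000L) {
  len <- setNames(as.numeric(chrom_sizes$length), chrom_sizes$chrom)
  w <- template_peaks$end - template_peaks$start
  if (any(w > len[template_peaks$chrom]))
    stop("template peak wider than its chromosome")
  with_seed(sub_seed(seed, 1000L + iteration), {
    start <- floor(stats::runif(length(w)) * (len[template_peaks$chrom] - w + 1))
    out <- data.frame(chrom = template_peaks$chrom, start = as.integer(start),
                      end = as.integer(start + w), stringsAsFactors = FALSE)
    if (!is.null(exclude) && nrow(exclude)) {
      for (try in seq_len(max_tries)) {
        bad <- unique(overlap_pairs(out, exclude)[, "query"])
        if (!length(bad)) break
        if (try == max_tries)
          stop("exclusion mask leaves no room for random peaks")
        ns <- floor(stats::runif(length(bad)) * (len[out$chrom[bad]] - w[bad] + 1))
        out$start[bad] <- as.integer(ns)
        out$end[bad] <- as.integer(ns + w[bad])
      }
    }
    rownames(out) <- NULL
    out
  })
}

# Distinct genes hit by a set of intervals under a given assignment rule.
.genes_hit <- function(intervals, genes = NULL, domains = NULL,
                       gene_assign = c("nearest", "domain")) {
  gene_assign <- match.arg(gene_assign)
  if (gene_assign == "nearest") {
    ng <- nearest_gene(intervals, genes)
    sort(unique(ng$gene_id[!is.na(ng$gene_id)]))
  } else {
    assign_peaks_to_genes(intervals, domains)$genes
  }
}

#' Permutation enrichment of peak overlap with feature sets
#'
#' For each named feature set, the observed statistic is, at peak level, the
#' number of peaks overlapping the feature set and, at gene level, the number
#' of distinct genes hit by the peaks that are also hit by the features
#' (genes assigned either by nearest TSS or by regulatory-domain overlap).
#' Null distributions come from `n_perm` random peak sets matched in number
#' and width per chromosome; empirical p uses the +1 convention
#' (1 + exceedances) / (1 + n_perm), which never reaches zero.
#'
#' @param peaks peak data.frame (chrom, start, end)
#' @param feature_sets named list of interval data.frames
#' @param chrom_sizes chromosome sizes
#' @param genes gene models (required for gene level with nearest assignment)
#' @param domains regulatory domains (required for gene level with domain
#'   assignment)
#' @param n_perm number of permutations (the study design uses 1000)
#' @param seed integer seed
#' @param level statistic levels to compute: "peak", "gene" or both
#' @param gene_assign gene assignment rule: "nearest" (closest TSS, the
#'   ChIP-style comparison) or "domain" (regulatory-domain overlap)
#' @param exclude optional exclusion mask passed to [sample_random_peaks()]
#' @return data.frame with one row per (feature set, level): observed,
#'   observed_fraction, null_mean, null_sd, z, empirical_p; attribute
#'   `null_values` holds the per-row permutation statistics
#' @export
permutation_overlap_enrichment <- function(peaks, feature_sets, chrom_sizes,
                                           genes = NULL, domains = NULL,
                                           n_perm = 1000L, seed = 1L,
                                           level = c("peak", "gene"),
                                           gene_assign = c("nearest", "domain"),
                                           exclude = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (nrow(peaks) == 0L) stop("peaks must be non-empty")
  level <- match.arg(level, several.ok = TRUE)
  gene_assign <- match.arg(gene_assign)
  if ("gene" %in% level) {
    if (gene_assign == "nearest" && is.null(genes))
      stop("gene-level statistics with nearest assignment require gene models")
    if (gene_assign == "domain" && is.null(domains))
      stop("gene-level statistics with domain assignment require domains")
  }
  feat_merged <- lapply(feature_sets, merge_intervals)
  peak_stat <- function(pk, merged) count_overlapping(pk, merged)
  feat_genes <- if ("gene" %in% level)
    lapply(feature_sets, .genes_hit, genes = genes, domains = domains,
           gene_assign = gene_assign)
  gene_stat <- function(pk, fg) {
    length(intersect(.genes_hit(pk, genes = genes, domains = domains,
                                gene_assign = gene_assign), fg))
  }
  perms <- lapply(seq_len(n_perm), function(it)
    sample_random_peaks(peaks, chrom_sizes, seed, iteration = it,
                        exclude = exclude))
  rows <- list(); nulls <- list()
  for (nm in names(feature_sets)) {
    feats <- feature_sets[[nm]]
    if ("peak" %in% level) {
      obs <- peak_stat(peaks, feat_merged[[nm]])
      null <- vapply(perms, peak_stat, numeric(1), merged = feat_merged[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = nm, level = "peak", observed = obs,
        observed_fraction = obs / nrow(peaks),
        null_mean = mean(null), null_sd = stats::sd(null),
        z = if (stats::sd(null) > 0) (obs - mean(null)) / stats::sd(null) else NA_real_,
        empirical_p = (1 + sum(null >= obs)) / (1 + n_perm),
        stringsAsFactors = FALSE)
      nulls[[length(rows)]] <- null
    }
    if ("gene" %in% level) {
      fg <- feat_genes[[nm]]
      obs <- gene_stat(peaks, fg)
      n_genes_hit <- length(.genes_hit(peaks, genes = genes, domains = domains,
                                       gene_assign = gene_assign))
      null <- vapply(perms, gene_stat, numeric(1), fg = fg)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = nm, level = "gene", observed = obs,
        observed_fraction = if (n_genes_hit > 0) obs / n_genes_hit else NA_real_,
        null_mean = mean(null), null_sd = stats::sd(null),
        z = if (stats::sd(null) > 0) (obs - mean(null)) / stats::sd(null) else NA_real_,
        empirical_p = (1 + sum(null >= obs)) / (1 + n_perm),
        stringsAsFactors = FALSE)
      nulls[[length(rows)]] <- null
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "null_values") <- nulls
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values; monotone in p and bounded by 1.
#'
#' @param p_values numeric vector of p-values in (0, 1]
#' @return q-values in the input order
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
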