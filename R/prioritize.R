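# Candidate lncRNA nomination: dynamic-expression filtering, chromatin
# association from RIP, co-expression binarization, hypergeometric
# enrichment, module clustering, and the final ranked nomination.

.PSEUDOCOUNT <- 0.1

# Welch two-sided t-test that stays defined in the noiseless limit:
# with zero pooled standard error, p is 0 when the means differ and 1
# otherwise.
.welch_p <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / length(x) + v2 / length(y)
  if (!is.finite(se2) || se2 == 0) return(if (isTRUE(all.equal(m1, m2))) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Filter dynamic transcripts from an expression time course
#'
#' Applies the three nomination filters: abundance (mean log2 FPKM across all
#' samples at least `min_mean_log2_fpkm`), fold change (maximum pairwise
#' ratio of pseudocounted timepoint means at least `min_fold`), and
#' significance (two-sided Welch t-test on log2(FPKM + 0.1) between the
#' timepoints attaining the maximal and minimal mean, p below `alpha`).
#' With a single replicate per timepoint the significance branch is disabled
#' (with a flag in the result) and only the abundance and fold filters apply.
#'
#' @param fpkm matrix of FPKM, features x samples
#' @param metadata data.frame with sample_id, timepoint, replicate matching
#'   the columns of `fpkm`
#' @param min_mean_log2_fpkm abundance threshold on mean log2 FPKM
#' @param min_fold minimal fold change between timepoint means
#' @param alpha significance level
#' @return list with `ids` (transcripts passing all filters), `stats`
#'   (per-feature table: mean_log2, fold, p, pass) and `p_disabled` flag
#' @export
filter_dynamic_transcripts <- function(fpkm, metadata, min_mean_log2_fpkm = 1,
                                       min_fold = 2, alpha = 0.05) {
  stopifnot(is.matrix(fpkm), all(colnames(fpkm) %in% metadata$sample_id))
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  tp <- metadata$timepoint[match(colnames(fpkm), metadata$sample_id)]
  tps <- unique(tp)
  if (length(tps) < 2L) stop("at least two timepoints are required")
  reps_per_tp <- table(tp)
  p_disabled <- any(reps_per_tp < 2L)
  if (p_disabled)
    warning("single replicate in some timepoint: significance filter disabled")

  log2p <- log2(fpkm + .PSEUDOCOUNT)
  mean_log2 <- rowMeans(log2p)
  tp_means <- vapply(tps, function(t) rowMeans(fpkm[, tp == t, drop = FALSE]),
                     numeric(nrow(fpkm)))
  if (is.null(dim(tp_means))) tp_means <- matrix(tp_means, nrow = 1)
  hi <- max.col(tp_means, ties.method = "first")
  lo <- max.col(-tp_means, ties.method = "first")
  idx <- seq_len(nrow(fpkm))
  fold <- (tp_means[cbind(idx, hi)] + .PSEUDOCOUNT) /
    (tp_means[cbind(idx, lo)] + .PSEUDOCOUNT)
  p <- rep(NA_real_, nrow(fpkm))
  if (!p_disabled) {
    for (i in idx) {
      if (hi[i] == lo[i]) { p[i] <- 1; next }
      p[i] <- .welch_p(log2p[i, tp == tps[hi[i]]], log2p[i, tp == tps[lo[i]]])
    }
  }
  pass <- mean_log2 >= min_mean_log2_fpkm & fold >= min_fold
  if (!p_disabled) pass <- pass & p < alpha
  stats <- data.frame(feature_id = rownames(fpkm), mean_log2 = mean_log2,
                      fold = fold, p = p, pass = pass,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(ids = rownames(fpkm)[pass], stats = stats, p_disabled = p_disabled)
}

#' Call chromatin association from a histone H3 RIP assay
#'
#' A transcript is chromatin associated when its H3:IgG fold enrichment
#' exceeds `min_fold` in every replicate (the reproducibility clause) and a
#' pooled one-sided z-test of the mean log2(H3/IgG) against zero is
#' significant at `alpha`. The z-test pools the replicate variance of the
#' log-ratio across all transcripts, since per-transcript replicate counts
#' are too small for stable per-transcript variances. Transcripts with zero
#' H3 and zero IgG in some replicate have undefined enrichment and are
#' flagged and called not associated.
#'
#' @param rip data.frame with transcript_id, replicate, rpkm_h3, rpkm_igg
#'   (an rpkm_input column may be present and is ignored by the call)
#' @param min_fold per-replicate fold threshold
#' @param alpha significance level of the pooled z-test
#' @return named logical vector (TRUE = associated) with attributes
#'   `stats` (per-transcript mean log-ratio, min fold, z, p) and `flagged`
#'   (transcripts with undefined enrichment)
#' @export
chromatin_association <- function(rip, min_fold = 2, alpha = 0.05) {
  stopifnot(all(c("transcript_id", "replicate", "rpkm_h3", "rpkm_igg") %in% names(rip)))
  n_rep <- length(unique(rip$replicate))
  if (n_rep < 2L) stop("at least two replicates are required")
  cnt <- table(rip$transcript_id)
  if (any(cnt != n_rep)) stop("every transcript must be present in all replicates")
  undefined <- rip$rpkm_h3 == 0 & rip$rpkm_igg == 0
  lr <- log2((rip$rpkm_h3 + .PSEUDOCOUNT) / (rip$rpkm_igg + .PSEUDOCOUNT))
  fold <- (rip$rpkm_h3 + .PSEUDOCOUNT) / (rip$rpkm_igg + .PSEUDOCOUNT)
  ids <- sort(unique(rip$transcript_id))
  by_id <- split(seq_len(nrow(rip)), rip$transcript_id)[ids]
  mean_lr <- vapply(by_id, function(i) mean(lr[i]), numeric(1))
  min_fold_obs <- vapply(by_id, function(i) min(fold[i]), numeric(1))
  flagged <- vapply(by_id, function(i) any(undefined[i]), logical(1))
  # replicate variance of the log-ratio pooled across all transcripts
  pooled_var <- mean(vapply(by_id, function(i) stats::var(lr[i]), numeric(1)))
  se <- sqrt(pooled_var / n_rep)
  if (!is.finite(se) || se == 0) {
    p <- ifelse(mean_lr > 0, 0, 1)
    z <- ifelse(mean_lr > 0, Inf, ifelse(mean_lr < 0, -Inf, 0))
  } else {
    z <- mean_lr / se
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  assoc <- min_fold_obs > min_fold & p < alpha & !flagged
  out <- setNames(assoc, ids)
  attr(out, "stats") <- data.frame(transcript_id = ids, mean_log2_ratio = mean_lr,
                                   min_fold = min_fold_obs, z = z, p = p,
                                   row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "flagged") <- ids[flagged]
  out
}

#' Correlate lncRNAs with coding genes and binarize
#'
#' Pearson correlation of each noncoding profile against each coding profile
#' across samples, binarized to +1 (r above `pos_thresh`), -1 (r below
#' `neg_thresh`) or 0. Zero-variance features yield undefined correlations,
#' called 0 and flagged.
#'
#' @param fpkm matrix of FPKM, features x samples (at least 3 samples)
#' @param biotype data.frame with gene_id and biotype in {coding, noncoding}
#' @param pos_thresh,neg_thresh binarization thresholds
#' @return integer matrix (lnc x coding) of calls in {-1, 0, 1} with
#'   attributes `r` (the correlation matrix) and `flagged` (zero-variance
#'   feature ids)
#' @export
correlate_and_binarize <- function(fpkm, biotype, pos_thresh = 0.5,
                                   neg_thresh = -0.5) {
  if (ncol(fpkm) < 3L) stop("at least three samples are required")
  bt <- setNames(biotype$biotype, biotype$gene_id)[rownames(fpkm)]
  lnc <- rownames(fpkm)[bt == "noncoding"]
  coding <- rownames(fpkm)[bt == "coding"]
  if (!length(lnc) || !length(coding))
    stop("features must include both coding and noncoding biotypes")
  sds <- apply(fpkm, 1, stats::sd)
  flagged <- rownames(fpkm)[sds == 0]
  r <- suppressWarnings(stats::cor(t(fpkm[lnc, , drop = FALSE]),
                                   t(fpkm[coding, , drop = FALSE])))
  calls <- matrix(0L, nrow = length(lnc), ncol = length(coding),
                  dimnames = list(lnc, coding))
  calls[!is.na(r) & r > pos_thresh] <- 1L
  calls[!is.na(r) & r < neg_thresh] <- -1L
  attr(calls, "r") <- r
  attr(calls, "flagged") <- flagged
  calls
}

#' Gene-set enrichment matrix for lncRNAs
#'
#' For each lncRNA, its positively correlated coding genes are tested against
#' each gene set by the hypergeometric upper tail over the coding universe;
#' cells hold -log10 p, clamped at 300. A lncRNA with no positive partners
#' gets an all-zero row.
#'
#' @param calls binarized correlation matrix from [correlate_and_binarize()]
#' @param gene_sets named list of character vectors
#' @param universe coding gene universe (defaults to the columns of `calls`)
#' @return numeric matrix, lncRNAs x terms, of -log10 hypergeometric p
#' @export
enrichment_matrix <- function(calls, gene_sets, universe = colnames(calls)) {
  sets <- lapply(gene_sets, intersect, universe)
  if (all(lengths(sets) == 0L))
    stop("no gene set intersects the universe")
  out <- matrix(0, nrow = nrow(calls), ncol = length(sets),
                dimnames = list(rownames(calls), names(sets)))
  n_u <- length(universe)
  for (i in seq_len(nrow(calls))) {
    pos <- intersect(colnames(calls)[calls[i, ] == 1L], universe)
    if (!length(pos)) next
    for (j in seq_along(sets)) {
      k <- length(intersect(pos, sets[[j]]))
      m <- length(sets[[j]])
      p <- stats::phyper(k - 1, m, n_u - m, length(pos), lower.tail = FALSE)
      out[i, j] <- min(-log10(p), 300)
    }
  }
  out
}

#' Cluster lncRNAs into modules by enrichment profile
#'
#' Seeded k-means (50 restarts) on rows scaled to unit L2 norm. Module labels
#' are reordered by descending mean enrichment over `order_terms`, so module
#' 1 is the module most enriched for the designated (e.g. neuronal) terms.
#'
#' @param enrich enrichment matrix from [enrichment_matrix()]
#' @param k number of modules
#' @param order_terms term ids used to order the module labels
#' @param seed RNG seed for the restarts
#' @return named integer vector mapping lncRNA id to module label (1..k);
#'   lncRNAs with all-zero profiles get NA
#' @export
cluster_modules <- function(enrich, k = 3, order_terms = colnames(enrich)[1],
                            seed = 1L) {
  nonzero <- rowSums(enrich != 0) > 0
  x <- enrich[nonzero, , drop = FALSE]
  if (nrow(unique(x)) < k)
    stop(sprintf("fewer than k = %d distinct non-zero enrichment profiles", k))
  xn <- x / sqrt(rowSums(x^2))
  km <- with_seed(seed, stats::kmeans(xn, centers = k, nstart = 50, iter.max = 50))
  # order labels by descending mean enrichment of the designated term group
  score <- vapply(seq_len(k), function(cl) {
    mean(x[km$cluster == cl, order_terms, drop = FALSE])
  }, numeric(1))
  relabel <- match(seq_len(k), order(score, decreasing = TRUE))
  modules <- setNames(rep(NA_integer_, nrow(enrich)), rownames(enrich))
  modules[rownames(x)] <- relabel[km$cluster]
  modules
}

#' Nominate candidate lncRNAs
#'
#' Candidates are the noncoding transcripts passing the dynamic-expression
#' filters, annotated with their chromatin-association call and co-expression
#' module, and ranked lexicographically by (neuronal-module membership,
#' association flag, max fold change), all descending.
#'
#' @param dynamic result of [filter_dynamic_transcripts()]
#' @param assoc named logical vector from [chromatin_association()]
#' @param modules named module vector from [cluster_modules()]
#' @param biotype data.frame with gene_id, biotype
#' @param neuronal_module label of the neuronal module (default 1)
#' @return data.frame (id, fold, p, associated, module, rank) sorted by rank
#' @export
nominate_candidates <- function(dynamic, assoc, modules, biotype,
                                neuronal_module = 1L) {
  noncoding <- biotype$gene_id[biotype$biotype == "noncoding"]
  ids <- intersect(dynamic$ids, noncoding)
  if (!length(ids))
    return(data.frame(id = character(0), fold = numeric(0), p = numeric(0),
                      associated = logical(0), module = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  st <- dynamic$stats[match(ids, dynamic$stats$feature_id), ]
  out <- data.frame(id = ids, fold = st$fold, p = st$p,
                    associated = unname(assoc[ids]) %in% TRUE,
                    module = unname(modules[ids]),
                    stringsAsFactors = FALSE)
  neuronal <- !is.na(out$module) & out$module == neuronal_module
  ord <- order(-neuronal, -out$associated, -out$fold, out$id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
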