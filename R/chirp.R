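# ChIRP-seq downstream analysis: even/odd track merging, replicate
# consensus, high-confidence peak filtering, basal-plus-extension regulatory
# domains, peak -> gene assignment, and peak annotation.
#
# Signal tracks are step functions stored as data.frames (chrom, start, end,
# value), 0-based half-open, sorted and non-overlapping; positions not
# covered by a step have value zero.

# Values of a per-chromosome track over a grid of cells given by
# breakpoints; each cell lies entirely inside or outside every track step.
.step_values <- function(track, cell_starts) {
  if (nrow(track) == 0L) return(rep(0, length(cell_starts)))
  idx <- findInterval(cell_starts, track$start)
  val <- rep(0, length(cell_starts))
  ok <- idx > 0L
  ok[ok] <- cell_starts[ok] < track$end[idx[ok]]
  val[ok] <- track$value[idx[ok]]
  val
}

.track_check <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(track$value < 0)) stop("track values must be >= 0")
  track[order(track$chrom, track$start), , drop = FALSE]
}

#' Merge even and odd ChIRP tracks
#'
#' The concordance merge: per-position value is the pointwise minimum of the
#' even and odd probe-set tracks, re-tiled into maximal constant steps
#' (zero-valued steps are left implicit). Both tracks must cover the same
#' chromosome set.
#'
#' @param even,odd signal tracks (chrom, start, end, value)
#' @return merged signal track
#' @export
merge_even_odd <- function(even, odd) {
  even <- .track_check(even); odd <- .track_check(odd)
  ce <- unique(even$chrom); co <- unique(odd$chrom)
  if (!setequal(ce, co))
    stop(sprintf("chromosome sets differ: only in even = {%s}; only in odd = {%s}",
                 paste(setdiff(ce, co), collapse = ","),
                 paste(setdiff(co, ce), collapse = ",")))
  out <- lapply(sort(unique(ce)), function(ch) {
    e <- even[even$chrom == ch, , drop = FALSE]
    o <- odd[odd$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(e$start, e$end, o$start, o$end)))
    if (length(bp) < 2L) return(NULL)
    s <- bp[-length(bp)]; en <- bp[-1L]
    v <- pmin(.step_values(e, s), .step_values(o, s))
    keep <- v > 0
    s <- s[keep]; en <- en[keep]; v <- v[keep]
    if (!length(s)) return(NULL)
    # collapse contiguous equal-valued cells into maximal steps
    new_run <- c(TRUE, s[-1L] != en[-length(en)] | v[-1L] != v[-length(v)])
    run <- cumsum(new_run)
    data.frame(chrom = ch, start = s[!duplicated(run)],
               end = en[rev(!duplicated(rev(run)))], value = v[!duplicated(run)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
  rownames(res) <- NULL
  res
}

#' Consensus peaks across replicates
#'
#' A peak from the designated reference replicate is retained iff it overlaps
#' (>= 1 bp) at least one peak in every other replicate. Retained peaks keep
#' the reference coordinates; `neglog10_p` is taken as the minimum over the
#' reference peak and all overlapping partner peaks (conservative).
#'
#' @param replicate_peak_sets list (length >= 2) of peak data.frames with at
#'   least chrom, start, end, neglog10_p
#' @param reference index of the reference replicate
#' @return the retained reference peaks
#' @export
consensus_peaks <- function(replicate_peak_sets, reference = 1L) {
  if (length(replicate_peak_sets) < 2L)
    stop("at least two replicate peak sets are required")
  ref <- replicate_peak_sets[[reference]]
  others <- replicate_peak_sets[-reference]
  keep <- rep(TRUE, nrow(ref))
  min_p <- ref$neglog10_p
  for (rep_peaks in others) {
    hits <- overlap_pairs(ref, rep_peaks)
    keep <- keep & seq_len(nrow(ref)) %in% hits[, "query"]
    if (nrow(hits)) {
      agg <- tapply(rep_peaks$neglog10_p[hits[, "subject"]], hits[, "query"], min)
      idx <- as.integer(names(agg))
      min_p[idx] <- pmin(min_p[idx], agg)
    }
  }
  out <- ref[keep, , drop = FALSE]
  out$neglog10_p <- min_p[keep]
  rownames(out) <- NULL
  out
}

# Even/odd concordance statistics of each peak: Pearson r of the two tracks
# over the step-resolved grid restricted to the peak, and the mean (bp
# weighted) merged min coverage.
.peak_track_stats <- function(peaks, even, odd) {
  even <- .track_check(even); odd <- .track_check(odd)
  r <- numeric(nrow(peaks)); cov <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]; ps <- peaks$start[i]; pe <- peaks$end[i]
    e <- even[even$chrom == ch, , drop = FALSE]
    o <- odd[odd$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(ps, pe, e$start[e$start > ps & e$start < pe],
                        e$end[e$end > ps & e$end < pe],
                        o$start[o$start > ps & o$start < pe],
                        o$end[o$end > ps & o$end < pe])))
    s <- bp[-length(bp)]; en <- bp[-1L]
    ev <- .step_values(e, s); ov <- .step_values(o, s)
    w <- en - s
    cov[i] <- sum(pmin(ev, ov) * w) / sum(w)
    r[i] <- if (length(s) < 2L) NA_real_ else
      suppressWarnings(stats::cor(ev, ov))
  }
  data.frame(evenodd_corr = r, mean_coverage = cov)
}

#' High-confidence ChIRP peak filter
#'
#' Retains peaks with `neglog10_p >= min_neglog10_p`, even/odd Pearson
#' correlation strictly greater than `min_corr` (computed over the
#' step-resolved values of the two probe-set tracks within the peak), and
#' mean merged (min) coverage strictly greater than `min_cov` (2 for mES-iN
#' tracks, 1 for hNPC). Peaks whose interval resolves to fewer than two
#' steps have undefined correlation and are dropped and flagged.
#'
#' @param peaks peak data.frame with chrom, start, end, neglog10_p
#' @param even,odd probe-set signal tracks
#' @param min_neglog10_p significance threshold (inclusive)
#' @param min_corr correlation threshold (exclusive)
#' @param min_cov coverage threshold (exclusive)
#' @return retained peaks with `evenodd_corr` and `mean_coverage` columns
#'   appended; attribute `flagged` names peaks with undefined correlation
#' @export
high_confidence_filter <- function(peaks, even, odd, min_neglog10_p = 100,
                                   min_corr = 0, min_cov = 2) {
  st <- .peak_track_stats(peaks, even, odd)
  peaks$evenodd_corr <- st$evenodd_corr
  peaks$mean_coverage <- st$mean_coverage
  undefined <- is.na(peaks$evenodd_corr)
  keep <- peaks$neglog10_p >= min_neglog10_p &
    !undefined & peaks$evenodd_corr > min_corr &
    peaks$mean_coverage > min_cov
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- if ("name" %in% names(peaks)) peaks$name[undefined]
    else which(undefined)
  out
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-aware basal window (`basal_up` upstream,
#' `basal_down` downstream of the TSS, regardless of neighbors), extended on
#' each side to the nearest neighboring basal boundary but no farther than
#' `max_ext` beyond its own basal edge, clipped to chromosome bounds.
#' Extensions never invade a neighbor's basal region.
#'
#' @param genes gene models (gene_id, chrom, strand, start, end, tss)
#' @param chrom_sizes chromosome sizes (chrom, length)
#' @param basal_up,basal_down basal window, bp up/downstream of the TSS
#' @param max_ext maximal extension per side beyond the basal edge, bp
#' @return data.frame (gene_id, chrom, start, end, basal_start, basal_end)
#' @export
build_regulatory_domains <- function(genes, chrom_sizes, basal_up = 5000,
                                     basal_down = 1000, max_ext = 1e6) {
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  if (any(!genes$chrom %in% names(len)) ||
      any(genes$start < 0 | genes$end > len[genes$chrom]))
    stop("gene off chromosome bounds")
  bs <- ifelse(genes$strand == "+", genes$tss - basal_up, genes$tss - basal_down + 1)
  be <- ifelse(genes$strand == "+", genes$tss + basal_down, genes$tss + basal_up + 1)
  bs <- pmax(bs, 0)
  be <- pmin(be, len[genes$chrom])
  ds <- numeric(nrow(genes)); de <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    left_blocks <- same[bs[same] < bs[i]]
    ds[i] <- max(c(bs[i] - max_ext, 0, pmin(be[left_blocks], bs[i])))
    right_blocks <- same[be[same] > be[i]]
    de[i] <- min(c(be[i] + max_ext, len[genes$chrom[i]],
                   pmax(bs[right_blocks], be[i])))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(ds), end = as.integer(de),
             basal_start = as.integer(bs), basal_end = as.integer(be),
             stringsAsFactors = FALSE)
}

#' Assign peaks to genes via regulatory domains
#'
#' A peak is assigned to every gene whose regulatory domain it overlaps by
#' at least 1 bp.
#'
#' @param peaks peak data.frame (chrom, start, end; optional name)
#' @param domains regulatory domains from [build_regulatory_domains()]
#' @return list with `map` (data.frame peak, gene_id) and `genes` (sorted
#'   deduplicated associated gene ids)
#' @export
assign_peaks_to_genes <- function(peaks, domains) {
  hits <- overlap_pairs(peaks, domains)
  peak_id <- if ("name" %in% names(peaks)) peaks$name else seq_len(nrow(peaks))
  map <- data.frame(peak = peak_id[hits[, "query"]],
                    gene_id = domains$gene_id[hits[, "subject"]],
                    stringsAsFactors = FALSE)
  map <- map[order(map$peak, map$gene_id), , drop = FALSE]
  rownames(map) <- NULL
  list(map = map, genes = sort(unique(map$gene_id)))
}

#' Annotate peaks by genomic category
#'
#' Assigns each peak midpoint exactly one label using strand-aware windows,
#' in priority order: promoter (-2 kb to +1 kb of a TSS), enhancer (-10 kb to
#' -2 kb upstream), exon, intron, gene tail (0 to 2 kb downstream of a gene
#' end), intergenic.
#'
#' @param peaks peak data.frame (chrom, start, end)
#' @param genes gene models (gene_id, chrom, strand, start, end, tss)
#' @param exons exon table (gene_id, start, end)
#' @return character vector of category labels, one per peak
#' @export
annotate_peaks <- function(peaks, genes, exons) {
  ex <- merge(exons, genes[, c("gene_id", "chrom")], by = "gene_id")
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    m <- (peaks$start[i] + peaks$end[i]) %/% 2
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { out[i] <- "intergenic"; next }
    d <- ifelse(g$strand == "+", m - g$tss, g$tss - m)
    d_tail <- ifelse(g$strand == "+", m - g$end, g$start - m - 1)
    e <- ex[ex$chrom == peaks$chrom[i], , drop = FALSE]
    out[i] <- if (any(d >= -2000 & d < 1000)) "promoter"
      else if (any(d >= -10000 & d < -2000)) "enhancer"
      else if (nrow(e) && any(m >= e$start & m < e$end)) "exon"
      else if (any(m >= g$start & m < g$end)) "intron"
      else if (any(d_tail >= 0 & d_tail < 2000)) "gene_tail"
      else "intergenic"
  }
  out
}

#' Nearest gene of each peak
#'
#' The gene whose TSS is closest to the peak midpoint, on the peak's
#' chromosome; ties are broken by lexicographic gene id. Distance is signed
#' strand-relatively (positive downstream of the TSS). Peaks on chromosomes
#' without genes are left unassigned (NA).
#'
#' @param peaks peak data.frame (chrom, start, end; optional name)
#' @param genes gene models (gene_id, chrom, strand, tss)
#' @return data.frame (peak, gene_id, distance)
#' @export
nearest_gene <- function(peaks, genes) {
  peak_id <- if ("name" %in% names(peaks)) peaks$name else seq_len(nrow(peaks))
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  mid <- (peaks$start + peaks$end) %/% 2
  for (ch in unique(as.character(peaks$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (nrow(g) == 0L) next
    # genes sharing a TSS: the lexicographically smallest id represents them
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    g <- g[!duplicated(g$tss), , drop = FALSE]
    m <- mid[pi]
    j <- findInterval(m, g$tss)               # nearest TSS at or left of m
    left <- pmax(j, 1L); right <- pmin(j + 1L, nrow(g))
    dl <- abs(m - g$tss[left]); dl[j < 1L] <- Inf
    dr <- abs(m - g$tss[right]); dr[j >= nrow(g)] <- Inf
    # ties between the flanking candidates go to the smaller gene id
    use_left <- dl < dr | (dl == dr & g$gene_id[left] <= g$gene_id[right])
    k <- ifelse(use_left, left, right)
    gene_id[pi] <- g$gene_id[k]
    dist[pi] <- ifelse(g$strand[k] == "+", m - g$tss[k], g$tss[k] - m)
  }
  data.frame(peak = peak_id, gene_id = gene_id, distance = dist,
             stringsAsFactors = FALSE)
}
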