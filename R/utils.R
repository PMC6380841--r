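# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators never
#' perturb user code.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded sub-seed from (seed, offset); keeps values < 2^31.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647L)
}

# Intervals are data.frames with columns chrom, start, end (0-based half-open).
# Conversion to GRanges (1-based closed) for overlap machinery.
as_granges0 <- function(df, seqlevels = unique(as.character(df$chrom))) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Overlap hits (>=1 bp) between two 0-based half-open interval frames.
# Returns a two-column matrix of row indices (query, subject). Works
# per chromosome on plain IRanges, which keeps the call cheap enough for
# permutation loops.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(cbind(query = integer(0), subject = integer(0)))
  lv <- intersect(unique(as.character(query$chrom)),
                  unique(as.character(subject$chrom)))
  qs <- split(seq_len(nrow(query)), as.character(query$chrom))
  ss <- split(seq_len(nrow(subject)), as.character(subject$chrom))
  out_q <- integer(0); out_s <- integer(0)
  for (ch in lv) {
    qi <- qs[[ch]]; si <- ss[[ch]]
    h <- IRanges::findOverlaps(
      IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
      IRanges::IRanges(subject$start[si] + 1L, subject$end[si]))
    out_q <- c(out_q, qi[S4Vectors::queryHits(h)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(h)])
  }
  cbind(query = out_q, subject = out_s)
}

# Merge an interval frame into per-chromosome sorted disjoint intervals,
# for repeated membership counting against a fixed feature set.
merge_intervals <- function(df) {
  lapply(split(df[, c("start", "end")], as.character(df$chrom)), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    keep_s <- numeric(0); keep_e <- numeric(0)
    if (nrow(x)) {
      cur_s <- x$start[1]; cur_e <- x$end[1]
      for (i in seq_len(nrow(x))[-1]) {
        if (x$start[i] <= cur_e) cur_e <- max(cur_e, x$end[i])
        else { keep_s <- c(keep_s, cur_s); keep_e <- c(keep_e, cur_e)
               cur_s <- x$start[i]; cur_e <- x$end[i] }
      }
      keep_s <- c(keep_s, cur_s); keep_e <- c(keep_e, cur_e)
    }
    list(start = keep_s, end = keep_e)
  })
}

# Number of query intervals overlapping a merged interval set by >= 1 bp.
count_overlapping <- function(query, merged) {
  n <- 0L
  for (ch in unique(as.character(query$chrom))) {
    m <- merged[[ch]]
    if (is.null(m) || !length(m$start)) next
    qi <- query$chrom == ch
    j <- findInterval(query$start[qi], m$end) + 1L
    ok <- j <= length(m$start) & m$start[pmin(j, length(m$start))] < query$end[qi]
    n <- n + sum(ok)
  }
  n
}

check_intervals <- function(df, what = "interval") {
  if (nrow(df) && any(df$start >= df$end))
    stop(sprintf("invalid %s: start must be < end", what), call. = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
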