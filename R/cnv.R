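# Per-locus case/control CNV burden testing with focality classification.
# Overlap is >= 1 bp on 0-based half-open intervals (standard BED
# semantics); counts are per distinct subject.

#' Count subjects with a CNV at a locus
#'
#' Counts distinct subjects carrying at least one CNV (optionally restricted
#' to one type) overlapping the locus by at least 1 bp.
#'
#' @param locus one-row data.frame (or list) with chrom, start, end
#' @param cnvs CNV table (subject_id, chrom, start, end, type, cohort)
#' @param type_filter optional "DEL" or "DUP"
#' @return integer subject count
#' @export
count_locus_hits <- function(locus, cnvs, type_filter = NULL) {
  if (!is.null(type_filter)) cnvs <- cnvs[cnvs$type == type_filter, , drop = FALSE]
  if (nrow(cnvs) == 0L) return(0L)
  ld <- data.frame(chrom = locus$chrom, start = locus$start, end = locus$end)
  hits <- overlap_pairs(ld, cnvs)
  length(unique(cnvs$subject_id[hits[, "subject"]]))
}

#' Fisher exact burden test for one locus
#'
#' Two-sided Fisher exact p (point-probability method) on the 2x2 table of
#' subjects with/without a CNV at the locus in cases versus controls, with
#' the sample odds ratio; cells get the Haldane-Anscombe 0.5 correction when
#' any cell is zero. Cohort sizes default to the morbidity-map cohorts of
#' 29,085 affected children and 19,584 controls.
#'
#' @param case_hits,control_hits subject counts at the locus
#' @param n_cases,n_controls cohort sizes
#' @return list with `odds_ratio` and `p`
#' @export
fisher_burden <- function(case_hits, control_hits, n_cases = 29085L,
                          n_controls = 19584L) {
  if (n_cases < 1L || n_controls < 1L) stop("cohort sizes must be >= 1")
  if (case_hits > n_cases || control_hits > n_controls)
    stop("hits cannot exceed cohort sizes")
  tab <- matrix(c(case_hits, n_cases - case_hits,
                  control_hits, n_controls - control_hits),
                nrow = 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  list(odds_ratio = res$odds_ratio, p = res$p)
}

#' Classify CNVs as focal at a locus
#'
#' A CNV is focal when it overlaps the locus and overlaps zero coding-gene
#' bodies in the annotation.
#'
#' @param cnvs CNV table (any number of records)
#' @param locus one-row locus (chrom, start, end)
#' @param coding_genes gene models restricted to coding genes (chrom, start,
#'   end)
#' @return logical vector, one element per CNV record
#' @export
classify_focal <- function(cnvs, locus, coding_genes) {
  if (nrow(cnvs) == 0L) return(logical(0))
  ld <- data.frame(chrom = locus$chrom, start = locus$start, end = locus$end)
  at_locus <- rep(FALSE, nrow(cnvs))
  at_locus[overlap_pairs(cnvs, ld)[, "query"]] <- TRUE
  hits_coding <- rep(FALSE, nrow(cnvs))
  if (nrow(coding_genes))
    hits_coding[overlap_pairs(cnvs, coding_genes)[, "query"]] <- TRUE
  at_locus & !hits_coding
}

#' Scan loci for case/control CNV burden
#'
#' One burden test per locus: distinct-subject hit counts in each cohort
#' (jointly over deletions and duplications, with per-type breakdown),
#' two-sided Fisher exact p, sample odds ratio, focal case-subject count,
#' Benjamini-Hochberg q, and rank by ascending p.
#'
#' @param loci loci table (name, chrom, start, end)
#' @param cnvs CNV table with cohort in {case, control}
#' @param coding_genes coding gene models for focality classification
#' @param n_cases,n_controls cohort sizes; by default inferred as the number
#'   of distinct subjects per cohort in `cnvs`
#' @return data.frame sorted by ascending p with columns locus, case_hits,
#'   control_hits, case_del, case_dup, control_del, control_dup,
#'   focal_case_hits, odds_ratio, p, q, rank
#' @export
burden_scan <- function(loci, cnvs, coding_genes, n_cases = NULL,
                        n_controls = NULL) {
  if (nrow(loci) == 0L) stop("loci must be non-empty")
  check_intervals(loci, "locus")
  check_intervals(cnvs, "CNV")
  cases <- cnvs[cnvs$cohort == "case", , drop = FALSE]
  controls <- cnvs[cnvs$cohort == "control", , drop = FALSE]
  n_cases <- n_cases %||% length(unique(cases$subject_id))
  n_controls <- n_controls %||% length(unique(controls$subject_id))
  # one overlap pass per cohort; focality needs the coding overlap per CNV
  case_hits <- overlap_pairs(loci, cases)
  ctrl_hits <- overlap_pairs(loci, controls)
  case_coding <- rep(FALSE, nrow(cases))
  if (nrow(coding_genes) && nrow(cases))
    case_coding[unique(overlap_pairs(cases, coding_genes)[, "query"])] <- TRUE
  n_subj <- function(hits, cohort, sel = TRUE) {
    keep <- sel[hits[, "subject"]]
    counts <- tapply(cohort$subject_id[hits[keep, "subject"]],
                     hits[keep, "query"],
                     function(x) length(unique(x)))
    out <- integer(nrow(loci))
    out[as.integer(names(counts))] <- as.integer(counts)
    out
  }
  ch <- n_subj(case_hits, cases, rep(TRUE, nrow(cases)))
  cth <- n_subj(ctrl_hits, controls, rep(TRUE, nrow(controls)))
  fb <- lapply(seq_len(nrow(loci)), function(i)
    fisher_burden(ch[i], cth[i], n_cases, n_controls))
  out <- data.frame(
    locus = loci$name, case_hits = ch, control_hits = cth,
    case_del = n_subj(case_hits, cases, cases$type == "DEL"),
    case_dup = n_subj(case_hits, cases, cases$type == "DUP"),
    control_del = n_subj(ctrl_hits, controls, controls$type == "DEL"),
    control_dup = n_subj(ctrl_hits, controls, controls$type == "DUP"),
    focal_case_hits = n_subj(case_hits, cases, !case_coding),
    odds_ratio = vapply(fb, `[[`, numeric(1), "odds_ratio"),
    p = vapply(fb, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$locus), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
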