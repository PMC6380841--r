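#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data module. The defaults are the
#' study conditions the whole test suite runs under: a desk-scale genome of
#' two 10-Mb chromosomes carrying 150 coding genes and 120 lncRNA loci, a
#' five-timepoint reprogramming course in triplicate with planted four-fold
#' dynamic lncRNAs, RIP assays with planted chromatin-associated transcripts,
#' a 500 vs 500 CNV cohort with one focally mutated lncRNA locus, and
#' even/odd ChIRP tracks with 10 planted peaks plus 30 single-violation
#' decoys.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length_bp length of each chromosome (bp)
#' @param n_genes number of protein-coding genes
#' @param n_lnc number of lncRNA genes
#' @param n_timepoints timepoints in the expression course
#' @param n_replicates replicates per timepoint (and per RIP antibody)
#' @param effect_fold planted fold change of dynamic transcripts (must be > 1
#'   when dynamic transcripts are requested)
#' @param noise_sd noise standard deviation on the log2-FPKM scale
#' @param n_cases,n_controls CNV cohort sizes
#' @param background_cnv_rate expected background CNV count per subject
#' @param planted_case_hits number of case subjects carrying the focal CNV
#' @param n_planted_peaks,n_decoy_peaks ChIRP peak counts
#' @param seed RNG seed; fixes every generated file bit for bit
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length_bp = 10e6,
                       n_genes = 150L,
                       n_lnc = 120L,
                       n_timepoints = 5L,
                       n_replicates = 3L,
                       effect_fold = 4,
                       noise_sd = 0.1,
                       n_cases = 500L,
                       n_controls = 500L,
                       background_cnv_rate = 1,
                       planted_case_hits = 30L,
                       n_planted_peaks = 10L,
                       n_decoy_peaks = 30L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_genes = as.integer(n_genes),
    n_lnc = as.integer(n_lnc),
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    effect_fold = as.numeric(effect_fold),
    noise_sd = as.numeric(noise_sd),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    background_cnv_rate = as.numeric(background_cnv_rate),
    planted_case_hits = as.integer(planted_case_hits),
    n_planted_peaks = as.integer(n_planted_peaks),
    n_decoy_peaks = as.integer(n_decoy_peaks),
    seed = as.integer(seed)
  )
  if (cfg$n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
  if (cfg$chrom_length_bp <= 0) stop("chrom_length_bp must be > 0")
  if (cfg$n_genes < 0L || cfg$n_lnc < 0L) stop("gene counts must be >= 0")
  if (cfg$n_timepoints < 1L || cfg$n_replicates < 1L)
    stop("n_timepoints and n_replicates must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$effect_fold <= 0) stop("effect_fold must be > 0")
  if (cfg$n_cases < 1L || cfg$n_controls < 1L) stop("cohort sizes must be >= 1")
  if (cfg$background_cnv_rate < 0) stop("background_cnv_rate must be >= 0")
  if (cfg$planted_case_hits < 0L) stop("planted_case_hits must be >= 0")
  if (cfg$planted_case_hits > cfg$n_cases)
    stop("planted_case_hits cannot exceed n_cases")
  if (cfg$n_planted_peaks < 0L || cfg$n_decoy_peaks < 0L)
    stop("peak counts must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %.0f bp; %d coding + %d lncRNA genes\n",
              x$n_chromosomes, x$chrom_length_bp, x$n_genes, x$n_lnc))
  cat(sprintf("  expression: %d timepoints x %d replicates, fold %.1f, noise sd %.2f\n",
              x$n_timepoints, x$n_replicates, x$effect_fold, x$noise_sd))
  cat(sprintf("  CNV: %d cases / %d controls, background rate %.2f, %d planted focal hits\n",
              x$n_cases, x$n_controls, x$background_cnv_rate, x$planted_case_hits))
  cat(sprintf("  ChIRP: %d planted peaks + %d decoys; seed %d\n",
              x$n_planted_peaks, x$n_decoy_peaks, x$seed))
  invisible(x)
}
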