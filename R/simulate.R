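# Synthetic-data generators. Every generator is seeded from cfg$seed through
# a fixed offset so a configuration regenerates each file bit for bit, and
# every planted signal is recorded in a truth sidecar.

# Fixed module structure of the planted co-expression design.
.N_MODULES <- 3L
.LNC_PER_MODULE <- 5L
.CODING_PER_MODULE <- 20L
.N_ASSOC <- 10L
.N_TARGET_GENES <- 10L

#' Simulate a genome annotation
#'
#' Places non-overlapping coding and lncRNA genes on equal-length
#' chromosomes. Each gene gets a strand, a TSS, and 1-3 exons tiling part of
#' its span. Genes are laid out in per-chromosome slots with a 6-kb margin so
#' that basal regulatory windows of neighboring genes never collide.
#'
#' @param cfg a [sim_config()]
#' @param out_dir optional directory; if given, writes `genes.gtf` and
#'   `chrom.sizes`
#' @return list with `genes`, `exons`, `chrom_sizes` data.frames
#' @export
simulate_genome_annotation <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n_total <- cfg$n_genes + cfg$n_lnc
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom_sizes <- data.frame(chrom = chroms,
                            length = as.integer(cfg$chrom_length_bp),
                            stringsAsFactors = FALSE)
  gene_len_max <- 8000L
  margin <- 6000L
  genes <- NULL
  exons <- NULL
  if (n_total > 0L) {
    per_chrom <- rep(n_total %/% cfg$n_chromosomes, cfg$n_chromosomes)
    extra <- n_total %% cfg$n_chromosomes
    if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    slot <- floor(cfg$chrom_length_bp / pmax(per_chrom, 1L))
    need <- gene_len_max + 2L * margin
    if (any(per_chrom > 0L & slot < need))
      stop(sprintf(paste0("chromosome too short: placing %d genes on a %.0f bp ",
                          "chromosome leaves %.0f bp per gene but %d bp are ",
                          "needed (max gene length %d + 2 x %d bp margin)"),
                   max(per_chrom), cfg$chrom_length_bp, min(slot[per_chrom > 0]),
                   need, gene_len_max, margin))
    genes <- with_seed(sub_seed(cfg$seed, 1L), {
      biotype_idx <- sample.int(n_total, cfg$n_lnc)
      biotype <- rep("coding", n_total)
      biotype[biotype_idx] <- "noncoding"
      rows <- vector("list", n_total)
      k <- 0L
      n_pcg <- 0L; n_lnc <- 0L
      for (ci in seq_len(cfg$n_chromosomes)) {
        for (gi in seq_len(per_chrom[ci])) {
          k <- k + 1L
          len <- sample(2000:gene_len_max, 1L)
          lo <- (gi - 1L) * slot[ci] + margin
          hi <- gi * slot[ci] - margin - len
          start <- as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
          strand <- sample(c("+", "-"), 1L)
          bt <- biotype[k]
          if (bt == "coding") { n_pcg <- n_pcg + 1L; id <- sprintf("PCG%04d", n_pcg) }
          else { n_lnc <- n_lnc + 1L; id <- sprintf("LNC%04d", n_lnc) }
          rows[[k]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                  strand = strand, start = start,
                                  end = start + len,
                                  tss = if (strand == "+") start else start + len - 1L,
                                  biotype = bt, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    exons <- with_seed(sub_seed(cfg$seed, 2L), {
      ex <- vector("list", nrow(genes))
      for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        n_ex <- sample(1:3, 1L)
        if (n_ex == 1L) {
          ex[[i]] <- data.frame(gene_id = g$gene_id, start = g$start,
                                end = g$end, stringsAsFactors = FALSE)
        } else {
          cuts <- sort(sample((g$start + 1L):(g$end - 1L), 2L * (n_ex - 1L)))
          bounds <- c(g$start, cuts, g$end)
          starts <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
          ends <- bounds[seq(2L, length(bounds), by = 2L)]
          ex[[i]] <- data.frame(gene_id = g$gene_id, start = as.integer(starts),
                                end = as.integer(ends), stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, ex)
    })
  } else {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), tss = integer(0),
                        biotype = character(0), stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  }
  out <- list(genes = genes, exons = exons, chrom_sizes = chrom_sizes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(genes, exons, file.path(out_dir, "genes.gtf"))
    write_chrom_sizes(chrom_sizes, file.path(out_dir, "chrom.sizes"))
  }
  out
}

# Latent module profiles on the log2 scale; each spans exactly
# log2(effect_fold) between its extreme timepoints. The three profiles are
# indicators of two-timepoint index sets with pairwise intersection one,
# which bounds the between-module Pearson correlation at (T-4)/(2T-4) < 0.5
# for every T >= 3, so co-expression binarization at |r| = 0.5 separates the
# modules even in the noiseless limit.
.module_profiles <- function(n_timepoints, effect_fold) {
  if (n_timepoints < 3L)
    stop("n_timepoints must be >= 3 for the planted module design")
  a <- log2(effect_fold)
  t <- seq_len(n_timepoints)
  T <- n_timepoints
  list(
    module1 = a * (t %in% c(T - 1L, T)),   # late induction (neuronal)
    module2 = a * (t %in% c(1L, T - 1L)),  # early + pre-terminal transient
    module3 = a * (t %in% c(1L, T))        # early induction with terminal return
  )
}

#' Simulate a reprogramming expression time course
#'
#' Generates a log-normal FPKM matrix over `n_timepoints` x `n_replicates`
#' samples. Three planted co-expression modules each tie a group of lncRNAs
#' to a group of coding genes through a shared latent log2 profile whose
#' dynamic range is exactly `log2(effect_fold)`; module 1 is the designated
#' neuronal module and contributes the ChIRP target gene set. All other
#' transcripts are flat. Noise is Gaussian on the log2-FPKM scale.
#'
#' @param cfg a [sim_config()]; requires `effect_fold > 1` when dynamic
#'   transcripts are requested
#' @param annotation output of [simulate_genome_annotation()]
#' @param out_dir optional directory; writes `expression.tsv`,
#'   `sample_metadata.tsv`, `biotype.tsv`, `gene_sets.gmt`
#' @return list with `fpkm` (matrix), `metadata`, `biotype`, `gene_sets`,
#'   and `truth` (dynamic_lnc_ids, chromatin_assoc_ids, module_assignments,
#'   target_gene_set, neuronal_terms)
#' @export
simulate_expression_timecourse <- function(cfg, annotation, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- annotation$genes
  lnc_ids <- genes$gene_id[genes$biotype == "noncoding"]
  coding_ids <- genes$gene_id[genes$biotype == "coding"]
  n_dyn <- .N_MODULES * .LNC_PER_MODULE
  if (cfg$effect_fold <= 1 && n_dyn > 0L && length(lnc_ids) >= n_dyn)
    stop("effect_fold must be > 1 when dynamic transcripts are requested")
  if (length(lnc_ids) < n_dyn || length(coding_ids) < .N_MODULES * .CODING_PER_MODULE)
    stop(sprintf("annotation too small for the planted module design (%d lncRNAs and %d coding genes required)",
                 n_dyn, .N_MODULES * .CODING_PER_MODULE))

  profiles <- .module_profiles(cfg$n_timepoints, cfg$effect_fold)
  res <- with_seed(sub_seed(cfg$seed, 3L), {
    mod_lnc <- split(sample(lnc_ids, n_dyn),
                     rep(seq_len(.N_MODULES), each = .LNC_PER_MODULE))
    mod_coding <- split(sample(coding_ids, .N_MODULES * .CODING_PER_MODULE),
                        rep(seq_len(.N_MODULES), each = .CODING_PER_MODULE))
    all_ids <- genes$gene_id
    module_of <- setNames(rep(NA_character_, length(all_ids)), all_ids)
    for (m in seq_len(.N_MODULES)) {
      module_of[mod_lnc[[m]]] <- sprintf("module%d", m)
      module_of[mod_coding[[m]]] <- sprintf("module%d", m)
    }
    base <- setNames(numeric(length(all_ids)), all_ids)
    is_lnc <- all_ids %in% lnc_ids
    base[is_lnc] <- stats::rnorm(sum(is_lnc), 2, 1)
    base[!is_lnc] <- stats::rnorm(sum(!is_lnc), 3, 1)
    members <- !is.na(module_of)
    base[members] <- stats::runif(sum(members), 2.5, 4)

    sample_tp <- rep(seq_len(cfg$n_timepoints), each = cfg$n_replicates)
    sample_ids <- sprintf("T%02d_R%d", sample_tp,
                          rep(seq_len(cfg$n_replicates), cfg$n_timepoints))
    log2fpkm <- matrix(rep(base, length(sample_ids)),
                       nrow = length(all_ids), ncol = length(sample_ids),
                       dimnames = list(all_ids, sample_ids))
    for (m in seq_len(.N_MODULES)) {
      ids <- c(mod_lnc[[m]], mod_coding[[m]])
      prof <- profiles[[m]][sample_tp]
      log2fpkm[ids, ] <- log2fpkm[ids, ] + rep(prof, each = length(ids))
    }
    if (cfg$noise_sd > 0)
      log2fpkm <- log2fpkm + matrix(stats::rnorm(length(log2fpkm), 0, cfg$noise_sd),
                                    nrow = nrow(log2fpkm))
    gene_sets <- list(
      NEURONAL_SYSTEM = sort(mod_coding[[1]]),
      CELL_CYCLE_PROCESS = sort(mod_coding[[2]]),
      METABOLIC_PROCESS = sort(mod_coding[[3]])
    )
    for (r in 1:5)
      gene_sets[[sprintf("RANDOM_SET_%d", r)]] <-
        sort(sample(coding_ids, .CODING_PER_MODULE))
    assoc <- unname(sort(unlist(mod_lnc)))[seq_len(min(.N_ASSOC, n_dyn))]
    list(
      fpkm = 2^log2fpkm,
      metadata = data.frame(sample_id = sample_ids,
                            timepoint = sprintf("T%02d", sample_tp),
                            replicate = rep(seq_len(cfg$n_replicates),
                                            cfg$n_timepoints),
                            stringsAsFactors = FALSE),
      biotype = data.frame(gene_id = all_ids,
                           biotype = ifelse(is_lnc, "noncoding", "coding"),
                           stringsAsFactors = FALSE),
      gene_sets = gene_sets,
      truth = list(
        dynamic_lnc_ids = unname(sort(unlist(mod_lnc))),
        chromatin_assoc_ids = assoc,
        module_assignments = as.list(module_of[!is.na(module_of)]),
        target_gene_set = sort(mod_coding[[1]])[seq_len(.N_TARGET_GENES)],
        neuronal_terms = "NEURONAL_SYSTEM"
      )
    )
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_matrix(res$fpkm, file.path(out_dir, "expression.tsv"))
    utils::write.table(res$metadata, file.path(out_dir, "sample_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$biotype, file.path(out_dir, "biotype.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(res$gene_sets, file.path(out_dir, "gene_sets.gmt"))
  }
  res
}

#' Simulate a histone H3 RIP assay
#'
#' Emits per-replicate H3, IgG and input RPKMs for every lncRNA. Planted
#' chromatin-associated transcripts have an H3:IgG ratio of at least 4 in
#' every replicate (log2 ratio 2 plus a folded-normal excursion); background
#' transcripts have ratios centered at 1.
#'
#' @param cfg a [sim_config()]
#' @param lnc_ids transcript ids assayed
#' @param assoc_ids planted chromatin-associated subset (must be contained in
#'   `lnc_ids`)
#' @param out_dir optional directory; writes `rip.tsv`
#' @return data.frame with columns transcript_id, replicate, rpkm_h3,
#'   rpkm_igg, rpkm_input
#' @export
simulate_rip_assay <- function(cfg, lnc_ids, assoc_ids, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(assoc_ids %in% lnc_ids))
    stop("assoc_ids must be a subset of lnc_ids")
  rip <- with_seed(sub_seed(cfg$seed, 4L), {
    input <- 2^stats::rnorm(length(lnc_ids), 3, 1)
    rows <- vector("list", cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
      igg <- input * 0.1 * 2^stats::rnorm(length(lnc_ids), 0, cfg$noise_sd)
      lr <- stats::rnorm(length(lnc_ids), 0, cfg$noise_sd)
      planted <- lnc_ids %in% assoc_ids
      lr[planted] <- 2 + abs(stats::rnorm(sum(planted), 0, cfg$noise_sd))
      rows[[r]] <- data.frame(transcript_id = lnc_ids, replicate = r,
                              rpkm_h3 = igg * 2^lr, rpkm_igg = igg,
                              rpkm_input = input, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  rip <- rip[order(rip$transcript_id, rip$replicate), , drop = FALSE]
  rownames(rip) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rip, file.path(out_dir, "rip.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  rip
}

#' Candidate loci from an annotation
#'
#' The lncRNA gene spans, as a loci table suitable for [burden_scan()].
#' @param annotation output of [simulate_genome_annotation()]
#' @return data.frame with columns name, chrom, start, end
#' @export
lnc_loci <- function(annotation) {
  g <- annotation$genes
  g <- g[g$biotype == "noncoding", , drop = FALSE]
  data.frame(name = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
             stringsAsFactors = FALSE)
}

#' Simulate a case/control CNV cohort
#'
#' Background CNVs are placed uniformly per subject with a Poisson count of
#' mean `background_cnv_rate` and log-uniform lengths in [10 kb, 2 Mb] in
#' both cohorts. Exactly `planted_case_hits` case subjects additionally carry
#' a CNV overlapping the focal locus and no coding-gene body (a focal
#' event by construction).
#'
#' @param cfg a [sim_config()]
#' @param loci loci table (name, chrom, start, end)
#' @param coding_genes coding gene models (gene_id, chrom, start, end)
#' @param focal_locus name of the planted locus; defaults to the first locus
#'   free of coding-gene overlap. Errors if the chosen locus overlaps a
#'   coding gene.
#' @param out_dir optional directory; writes `cnv.tsv` and `loci.bed`
#' @return list with `cnvs` (subject_id, chrom, start, end, type, cohort)
#'   and `truth` (focal_locus_id, planted_subjects)
#' @export
simulate_cnv_cohort <- function(cfg, loci, coding_genes, focal_locus = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(loci) == 0L) stop("loci must be non-empty")
  check_intervals(loci, "locus")
  cg <- coding_genes[, c("chrom", "start", "end"), drop = FALSE]
  locus_coding <- overlap_pairs(loci, cg)
  clean <- setdiff(seq_len(nrow(loci)), unique(locus_coding[, "query"]))
  if (is.null(focal_locus)) {
    if (cfg$planted_case_hits > 0L && length(clean) == 0L)
      stop("cannot plant a focal event: every locus overlaps a coding gene")
    focal_locus <- loci$name[if (length(clean)) clean[1] else 1L]
  }
  fi <- match(focal_locus, loci$name)
  if (is.na(fi)) stop("focal_locus not found in loci")
  if (cfg$planted_case_hits > 0L && !(fi %in% clean))
    stop(sprintf("cannot plant a focal event: locus %s overlaps a coding gene",
                 focal_locus))
  chrom_levels <- unique(c(loci$chrom, cg$chrom))
  chrom_len <- cfg$chrom_length_bp

  cnvs <- with_seed(sub_seed(cfg$seed, 5L), {
    gen_background <- function(subjects, cohort) {
      k <- stats::rpois(length(subjects), cfg$background_cnv_rate)
      n <- sum(k)
      if (n == 0L) return(NULL)
      len <- pmin(round(exp(stats::runif(n, log(1e4), log(2e6)))), chrom_len - 1)
      chrom <- sample(sprintf("chr%d", seq_len(cfg$n_chromosomes)), n, replace = TRUE)
      start <- floor(stats::runif(n, 0, chrom_len - len))
      data.frame(subject_id = rep(subjects, k), chrom = chrom,
                 start = as.integer(start), end = as.integer(start + len),
                 type = sample(c("DEL", "DUP"), n, replace = TRUE),
                 cohort = cohort, stringsAsFactors = FALSE)
    }
    cases <- sprintf("case_%04d", seq_len(cfg$n_cases))
    controls <- sprintf("control_%04d", seq_len(cfg$n_controls))
    bg <- rbind(gen_background(cases, "case"),
                gen_background(controls, "control"))
    planted <- NULL
    if (cfg$planted_case_hits > 0L) {
      lc <- loci[fi, ]
      same <- cg[cg$chrom == lc$chrom, , drop = FALSE]
      left <- max(c(0, same$end[same$end <= lc$start]))
      right <- min(c(chrom_len, same$start[same$start >= lc$end]))
      starts <- as.integer(floor(stats::runif(cfg$planted_case_hits, left, lc$end - 1)))
      ends <- as.integer(ceiling(stats::runif(cfg$planted_case_hits,
                                              pmax(starts + 1, lc$start + 1), right)))
      planted <- data.frame(subject_id = cases[seq_len(cfg$planted_case_hits)],
                            chrom = lc$chrom, start = starts, end = ends,
                            type = sample(c("DEL", "DUP"), cfg$planted_case_hits,
                                          replace = TRUE),
                            cohort = "case", stringsAsFactors = FALSE)
    }
    out <- rbind(bg, planted)
    if (is.null(out))
      out <- data.frame(subject_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        type = character(0), cohort = character(0),
                        stringsAsFactors = FALSE)
    out[order(out$subject_id, out$chrom, out$start), , drop = FALSE]
  })
  rownames(cnvs) <- NULL
  truth <- list(focal_locus_id = focal_locus,
                planted_subjects = if (cfg$planted_case_hits > 0L)
                  sprintf("case_%04d", seq_len(cfg$planted_case_hits))
                else character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cnv_tsv(cnvs, file.path(out_dir, "cnv.tsv"))
    write_bed(loci, file.path(out_dir, "loci.bed"))
  }
  list(cnvs = cnvs, truth = truth)
}

# Step-profile builders for ChIRP peaks (10 steps per peak).
.peak_steps <- 10L
.peak_width <- 600L

#' Simulate even/odd ChIRP-seq tracks with planted and decoy peaks
#'
#' Planted peaks sit inside the basal regulatory window of the target genes
#' with concordant even/odd signal (shared step profile), -log10 p >= 100
#' and merged coverage well above threshold; the RNase control stays at 5%
#' of the even signal. Decoy peaks each violate exactly one confidence
#' criterion: `low_p` (weak MACS significance), `anticorr` (even and odd
#' profiles reversed, negative Pearson r), `low_cov` (signal amplitude below
#' the coverage threshold) and `rnase_high` (RNase signal exceeding the even
#' track, which manifests as a weak call because peaks are called against
#' the RNase control).
#'
#' @param cfg a [sim_config()]
#' @param domains regulatory domains from [build_regulatory_domains()]
#' @param target_gene_set gene ids whose domains receive planted peaks
#' @param chrom_sizes chromosome sizes table
#' @param out_dir optional directory; writes `chirp_even.bedGraph`,
#'   `chirp_odd.bedGraph`, `chirp_rnase.bedGraph`, `chirp_peaks.narrowPeak`
#' @return list with `even`, `odd`, `rnase` tracks, `peaks` (narrowPeak
#'   data.frame) and `truth` (planted peak names/intervals, decoy classes,
#'   target gene set)
#' @export
simulate_chirp_tracks <- function(cfg, domains, target_gene_set, chrom_sizes,
                                  out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(domains) == 0L) stop("domains must be non-empty")
  if (!all(target_gene_set %in% domains$gene_id))
    stop("target_gene_set must be contained in the domain gene ids")
  classes <- c("low_p", "anticorr", "low_cov", "rnase_high")

  res <- with_seed(sub_seed(cfg$seed, 6L), {
    tri <- pmin(seq_len(.peak_steps), rev(seq_len(.peak_steps)))
    tri <- tri / max(tri)
    ramp <- seq(0.2, 1, length.out = .peak_steps)
    occupied <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
    place_random <- function() {
      for (try in 1:100) {
        chrom <- sample(chrom_sizes$chrom, 1L)
        start <- sample.int(chrom_sizes$length[chrom_sizes$chrom == chrom] -
                              .peak_width, 1L) - 1L
        cand <- data.frame(chrom = chrom, start = start,
                           end = start + .peak_width)
        if (nrow(overlap_pairs(cand, occupied)) == 0L) return(cand)
      }
      stop("could not place a non-overlapping decoy peak")
    }
    peak_rows <- list(); even_rows <- list(); odd_rows <- list()
    rnase_rows <- list(); truth_planted <- list(); decoy_class <- character(0)

    emit_steps <- function(chrom, start, even_v, odd_v, rnase_v) {
      step_w <- .peak_width %/% .peak_steps
      s <- start + (seq_len(.peak_steps) - 1L) * step_w
      e <- s + step_w
      list(even = data.frame(chrom = chrom, start = s, end = e, value = even_v),
           odd = data.frame(chrom = chrom, start = s, end = e, value = odd_v),
           rnase = data.frame(chrom = chrom, start = s, end = e, value = rnase_v))
    }

    k <- 0L
    for (i in seq_len(cfg$n_planted_peaks)) {
      gene <- target_gene_set[(i - 1L) %% length(target_gene_set) + 1L]
      d <- domains[domains$gene_id == gene, ][1, ]
      span <- d$basal_end - d$basal_start
      off <- sample.int(max(span - .peak_width - 200L, 1L), 1L) + 100L
      start <- as.integer(d$basal_start + off)
      cand <- data.frame(chrom = d$chrom, start = start, end = start + .peak_width)
      occupied <- rbind(occupied, cand)
      amp <- stats::runif(1, 6, 10)
      even_v <- amp * tri * 2^stats::rnorm(.peak_steps, 0, 0.05)
      odd_v <- even_v * 2^stats::rnorm(.peak_steps, 0, 0.05)
      tr <- emit_steps(d$chrom, start, even_v, odd_v, 0.05 * even_v)
      k <- k + 1L
      nm <- sprintf("peak_%04d", k)
      peak_rows[[k]] <- data.frame(chrom = d$chrom, start = start,
                                   end = start + .peak_width, name = nm,
                                   score = 1000L, strand = ".",
                                   signal = mean(even_v),
                                   neglog10_p = stats::runif(1, 120, 300),
                                   neglog10_q = stats::runif(1, 100, 250),
                                   summit = .peak_width %/% 2L,
                                   stringsAsFactors = FALSE)
      even_rows[[k]] <- tr$even; odd_rows[[k]] <- tr$odd; rnase_rows[[k]] <- tr$rnase
      truth_planted[[length(truth_planted) + 1L]] <-
        data.frame(name = nm, chrom = d$chrom, start = start,
                   end = start + .peak_width, gene_id = gene,
                   stringsAsFactors = FALSE)
    }
    for (i in seq_len(cfg$n_decoy_peaks)) {
      cls <- classes[(i - 1L) %% length(classes) + 1L]
      cand <- place_random()
      occupied <- rbind(occupied, cand)
      amp <- stats::runif(1, 6, 10)
      neglog10_p <- stats::runif(1, 120, 300)
      rnase_scale <- 0.05
      if (cls == "low_p") {
        even_v <- amp * tri * 2^stats::rnorm(.peak_steps, 0, 0.05)
        odd_v <- even_v * 2^stats::rnorm(.peak_steps, 0, 0.05)
        neglog10_p <- stats::runif(1, 10, 90)
      } else if (cls == "anticorr") {
        even_v <- amp * ramp * 2^stats::rnorm(.peak_steps, 0, 0.05)
        odd_v <- amp * rev(ramp) * 2^stats::rnorm(.peak_steps, 0, 0.05)
      } else if (cls == "low_cov") {
        amp <- stats::runif(1, 0.2, 0.5)
        even_v <- amp * tri * 2^stats::rnorm(.peak_steps, 0, 0.05)
        odd_v <- even_v * 2^stats::rnorm(.peak_steps, 0, 0.05)
      } else { # rnase_high: called against the RNase control, so weak call
        even_v <- amp * tri * 2^stats::rnorm(.peak_steps, 0, 0.05)
        odd_v <- even_v * 2^stats::rnorm(.peak_steps, 0, 0.05)
        rnase_scale <- 1.3
        neglog10_p <- stats::runif(1, 5, 40)
      }
      tr <- emit_steps(cand$chrom, cand$start, even_v, odd_v, rnase_scale * even_v)
      k <- k + 1L
      nm <- sprintf("peak_%04d", k)
      peak_rows[[k]] <- data.frame(chrom = cand$chrom, start = cand$start,
                                   end = cand$end, name = nm,
                                   score = as.integer(min(1000, round(neglog10_p * 5))),
                                   strand = ".", signal = mean(even_v),
                                   neglog10_p = neglog10_p,
                                   neglog10_q = neglog10_p * 0.8,
                                   summit = .peak_width %/% 2L,
                                   stringsAsFactors = FALSE)
      even_rows[[k]] <- tr$even; odd_rows[[k]] <- tr$odd; rnase_rows[[k]] <- tr$rnase
      decoy_class[nm] <- cls
    }
    tidy_track <- function(rows) {
      tr <- do.call(rbind, rows)
      tr[order(tr$chrom, tr$start), , drop = FALSE]
    }
    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    list(even = tidy_track(even_rows), odd = tidy_track(odd_rows),
         rnase = tidy_track(rnase_rows), peaks = peaks,
         truth = list(
           planted_peaks = do.call(rbind, truth_planted),
           decoy_classes = as.list(decoy_class),
           target_gene_set = sort(unique(target_gene_set))
         ))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bedgraph(res$even, file.path(out_dir, "chirp_even.bedGraph"))
    write_bedgraph(res$odd, file.path(out_dir, "chirp_odd.bedGraph"))
    write_bedgraph(res$rnase, file.path(out_dir, "chirp_rnase.bedGraph"))
    write_narrowpeak(res$peaks, file.path(out_dir, "chirp_peaks.narrowPeak"))
  }
  res
}

#' Simulate a complete synthetic study
#'
#' Runs every generator under one configuration: genome annotation,
#' expression time course (with gene sets and biotypes), RIP assay, CNV
#' cohort over the lncRNA loci, regulatory domains, and ChIRP tracks/peaks.
#' When `out_dir` is given, all standard-format files plus a single
#' `study.truth.json` sidecar are written.
#'
#' @param cfg a [sim_config()]
#' @param out_dir optional output directory
#' @return list with all component outputs and the merged `truth`
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  ann <- simulate_genome_annotation(cfg, out_dir)
  expr <- simulate_expression_timecourse(cfg, ann, out_dir)
  rip <- simulate_rip_assay(cfg, expr$biotype$gene_id[expr$biotype$biotype == "noncoding"],
                            expr$truth$chromatin_assoc_ids, out_dir)
  loci <- lnc_loci(ann)
  coding <- ann$genes[ann$genes$biotype == "coding", , drop = FALSE]
  cnv <- simulate_cnv_cohort(cfg, loci, coding,
                             focal_locus = expr$truth$chromatin_assoc_ids[1],
                             out_dir = out_dir)
  domains <- build_regulatory_domains(ann$genes, ann$chrom_sizes)
  chirp <- simulate_chirp_tracks(cfg, domains, expr$truth$target_gene_set,
                                 ann$chrom_sizes, out_dir)
  truth <- c(expr$truth,
             list(focal_locus_id = cnv$truth$focal_locus_id,
                  planted_subjects = cnv$truth$planted_subjects,
                  planted_peaks = chirp$truth$planted_peaks$name,
                  planted_peak_intervals = chirp$truth$planted_peaks[,
                    c("chrom", "start", "end")],
                  decoy_classes = chirp$truth$decoy_classes))
  if (!is.null(out_dir))
    write_truth(truth, file.path(out_dir, "study.truth.json"))
  list(annotation = ann, expression = expr, rip = rip, loci = loci,
       cnv = cnv, domains = domains, chirp = chirp, truth = truth)
}
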