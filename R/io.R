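# Readers and writers for the plain-text formats the pipeline exchanges.
# All interval containers are 0-based half-open in memory; GTF (1-based,
# closed) is converted on read/write. Writers emit deterministic text so a
# fixed simulation seed regenerates files byte for byte.

#' Write gene models as GTF
#'
#' Emits one `gene` record plus one `exon` record per exon, with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes. Internal 0-based half-open
#' coordinates are converted to GTF's 1-based closed convention.
#'
#' @param genes data.frame with columns gene_id, chrom, strand, start, end,
#'   tss, biotype
#' @param exons data.frame with columns gene_id, start, end
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gtf <- function(genes, exons, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##format: gtf", con, sep = "\n")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                        g$gene_id, g$gene_id, g$biotype)
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, g$start + 1L, g$end, g$strand, attr_str),
               con, sep = "\n")
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex)) {
      ex <- ex[order(ex$start), , drop = FALSE]
      for (j in seq_len(nrow(ex))) {
        writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                           g$chrom, ex$start[j] + 1L, ex$end[j], g$strand, attr_str),
                   con, sep = "\n")
      }
    }
  }
  invisible(path)
}

#' Read gene models from GTF
#'
#' Parses via \code{rtracklayer::import} and converts to the package's
#' 0-based half-open representation.
#'
#' @param path GTF file
#' @return list with `genes` (gene_id, chrom, strand, start, end, tss,
#'   biotype) and `exons` (gene_id, start, end)
#' @export
read_gtf <- function(path) {
  empty <- !any(!grepl("^#", readLines(path)))
  df <- if (empty) data.frame() else
    as.data.frame(rtracklayer::import(path, format = "gtf"))
  if (nrow(df) == 0L) {
    return(list(
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0), biotype = character(0),
                         tss = integer(0), stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)))
  }
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  exon_rows <- df[df$type == "exon", , drop = FALSE]
  genes <- data.frame(
    gene_id = gene_rows$gene_id,
    chrom = as.character(gene_rows$seqnames),
    strand = as.character(gene_rows$strand),
    start = gene_rows$start - 1L,
    end = gene_rows$end,
    biotype = gene_rows$gene_biotype,
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  exons <- data.frame(
    gene_id = exon_rows$gene_id,
    start = exon_rows$start - 1L,
    end = exon_rows$end,
    stringsAsFactors = FALSE
  )
  ord <- order(genes$chrom, genes$start)
  list(genes = genes[ord, , drop = FALSE], exons = exons)
}

#' @rdname chrom_sizes
#' @param sizes data.frame with columns chrom, length
#' @param path file path
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", sizes$chrom, sizes$length), path)
  invisible(path)
}

#' Read or write a two-column chrom.sizes table
#' @name chrom_sizes
#' @return a data.frame with columns chrom, length
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  df
}

#' @rdname bedgraph
#' @param track data.frame with columns chrom, start, end, value
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     formatC(track$value, format = "g", digits = 10)), path)
  invisible(path)
}

#' Read or write a bedGraph signal track
#'
#' Tracks are step functions: sorted, non-overlapping 0-based half-open
#' intervals with a numeric value; uncovered positions are implicitly zero.
#' @name bedgraph
#' @param path file path
#' @return a data.frame with columns chrom, start, end, value
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' @rdname narrowpeak
#' @param peaks data.frame with columns chrom, start, end, name, score,
#'   strand, signal, neglog10_p, neglog10_q, summit
#' @export
write_narrowpeak <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                     peaks$chrom, peaks$start, peaks$end, peaks$name,
                     peaks$score, peaks$strand,
                     formatC(peaks$signal, format = "g", digits = 10),
                     formatC(peaks$neglog10_p, format = "g", digits = 10),
                     formatC(peaks$neglog10_q, format = "g", digits = 10),
                     peaks$summit), path)
  invisible(path)
}

#' Read or write ENCODE narrowPeak (BED6+4)
#'
#' Column 8 carries the MACS-style -log10 p-value, per the narrowPeak
#' specification.
#' @name narrowpeak
#' @param path file path
#' @return a data.frame of peaks
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score",
                                        "strand", "signal", "neglog10_p",
                                        "neglog10_q", "summit"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "numeric", "numeric", "numeric", "integer"))
  df
}

#' @rdname bed
#' @param intervals data.frame with columns chrom, start, end and optionally
#'   name
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else
    sprintf("region_%d", seq_len(nrow(intervals)))
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start,
                     intervals$end, nm), path)
  invisible(path)
}

#' Read or write 4-column BED
#' @name bed
#' @param path file path
#' @return a data.frame with columns chrom, start, end, name
#' @export
read_bed <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name"),
                    colClasses = c("character", "integer", "integer", "character"))
}

#' @rdname tsv_matrix
#' @param mat numeric matrix with row and column names
#' @param id_col header label for the feature-id column
#' @export
write_tsv_matrix <- function(mat, path, id_col = "feature_id") {
  lines <- c(paste(c(id_col, colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(rownames(mat)[i],
                       formatC(mat[i, ], format = "g", digits = 12)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a feature-by-sample numeric matrix as TSV
#'
#' First column holds feature ids; the header row holds sample ids.
#' @name tsv_matrix
#' @param path file path
#' @return a numeric matrix with feature ids as rownames
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname cnv_tsv
#' @param cnvs CNV data.frame
#' @export
write_cnv_tsv <- function(cnvs, path) {
  lines <- c("subject_id\tchrom\tstart\tend\ttype\tcohort",
             sprintf("%s\t%s\t%d\t%d\t%s\t%s", cnvs$subject_id, cnvs$chrom,
                     cnvs$start, cnvs$end, cnvs$type, cnvs$cohort))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a CNV cohort table
#'
#' Schema: subject_id, chrom, start, end (0-based half-open),
#' type in {DEL, DUP}, cohort in {case, control}.
#' @name cnv_tsv
#' @param path file path
#' @return a data.frame of CNV records
#' @export
read_cnv_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "integer", "character", "character"))
}

#' @rdname gmt
#' @param sets named list of character vectors
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read or write gene sets in GMT format
#' @name gmt
#' @param path file path
#' @return a named list of character vectors
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname truth_sidecar
#' @param truth list of planted-truth fields
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read or write the planted-truth sidecar
#'
#' The synthetic-data module records every planted signal (dynamic lncRNAs,
#' chromatin-associated transcripts, module memberships, the focal CNV locus,
#' the ChIRP target gene set and planted peak intervals) in a structured JSON
#' sidecar named `<prefix>.truth.json` so tests can compare pipeline output
#' against ground truth programmatically.
#' @name truth_sidecar
#' @param path file path
#' @return a list
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
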