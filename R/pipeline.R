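# Convenience wrapper chaining the prioritization stages.

#' Run the full candidate-prioritization pipeline
#'
#' Chains dynamic-expression filtering, chromatin-association calling,
#' co-expression binarization, gene-set enrichment, module clustering and
#' candidate nomination on matched inputs.
#'
#' @param fpkm expression matrix (features x samples)
#' @param metadata sample metadata (sample_id, timepoint, replicate)
#' @param biotype feature biotypes (gene_id, biotype)
#' @param rip RIP assay table
#' @param gene_sets named list of gene sets
#' @param min_fold,alpha filter thresholds shared by the expression and RIP
#'   stages
#' @param k number of co-expression modules
#' @param order_terms terms defining the neuronal module ordering
#' @param seed seed for module clustering
#' @return list with `dynamic`, `assoc`, `calls`, `enrich`, `modules`,
#'   `candidates`
#' @export
prioritize_candidates <- function(fpkm, metadata, biotype, rip, gene_sets,
                                  min_fold = 2, alpha = 0.05, k = 3,
                                  order_terms = NULL, seed = 1L) {
  dynamic <- filter_dynamic_transcripts(fpkm, metadata, min_fold = min_fold,
                                        alpha = alpha)
  assoc <- chromatin_association(rip, min_fold = min_fold, alpha = alpha)
  calls <- correlate_and_binarize(fpkm, biotype)
  universe <- biotype$gene_id[biotype$biotype == "coding"]
  enrich <- enrichment_matrix(calls, gene_sets, universe)
  if (is.null(order_terms)) order_terms <- colnames(enrich)[1]
  modules <- cluster_modules(enrich, k = k, order_terms = order_terms,
                             seed = seed)
  candidates <- nominate_candidates(dynamic, assoc, modules, biotype)
  list(dynamic = dynamic, assoc = assoc, calls = calls, enrich = enrich,
       modules = modules, candidates = candidates)
}
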