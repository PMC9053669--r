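.chrom_style_check <- function(cnv_chroms, gene_chroms) {
  cnv_prefixed <- grepl("^chr", cnv_chroms)
  gene_prefixed <- grepl("^chr", gene_chroms)
  if (length(cnv_chroms) && length(gene_chroms) &&
      !any(cnv_chroms %in% gene_chroms) &&
      (all(cnv_prefixed) != all(gene_prefixed)))
    stop("chromosome naming styles differ between CNVs and annotation ",
         "(e.g. 'chr1' vs '1'); harmonise via the input dialect")
}

#' Compute CNV-gene overlaps
#'
#' A (sample, gene, dosage) triple is recorded iff the interval intersection
#' is >= 1 bp under 0-based half-open arithmetic (adjacent intervals do not
#' overlap).  Only protein-coding genes enter; a gene hit by several CNVs of
#' one individual appears once per dosage.
#'
#' @param cnvs data frame from [read_cnvs()] (0-based half-open).
#' @param genes annotation from [read_gene_annotation()].
#' @return An `overlap_matrix`: data frame `sample_id`, `gene_id`, `dosage`,
#'   plus the CNV coordinates of one supporting call.
#' @export
overlap_genes <- function(cnvs, genes) {
  genes <- protein_coding(genes)
  .chrom_style_check(unique(cnvs$chrom), unique(genes$chrom))
  empty <- data.frame(sample_id = character(0), gene_id = character(0),
                      dosage = factor(character(0), levels = c("DEL", "DUP")),
                      chrom = character(0), cnv_start = integer(0),
                      cnv_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(cnvs) == 0 || nrow(genes) == 0)
    return(structure(empty, class = c("overlap_matrix", "data.frame")))
  # half-open [start, end) -> 1-based closed [start+1, end] for IRanges
  gr_cnv <- GenomicRanges::GRanges(cnvs$chrom,
                                   IRanges::IRanges(cnvs$start + 1L, cnvs$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_cnv, gr_gene))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(sample_id = cnvs$sample_id[qi],
                    gene_id = genes$gene_id[si],
                    dosage = cnvs$dosage[qi],
                    chrom = cnvs$chrom[qi],
                    cnv_start = cnvs$start[qi],
                    cnv_end = cnvs$end[qi],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("sample_id", "gene_id", "dosage")]), , drop = FALSE]
  out <- out[order(out$sample_id, out$gene_id, out$dosage), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("overlap_matrix", "data.frame"))
}

#' Attach per-individual CNV covariates to a cohort
#'
#' Adds the logistic-model covariates: summed rare-CNV length in bp and the
#' number of distinct protein-coding genes overlapped.
#'
#' @param cohort a `cnv_cohort`.
#' @param cnvs CNV calls for the cohort.
#' @param overlaps output of [overlap_genes()].
#' @return The cohort with `total_cnv_bp` and `n_genes_overlapped` columns.
#' @export
cohort_covariates <- function(cohort, cnvs, overlaps) {
  bp <- tapply(cnvs$length_bp, cnvs$sample_id, sum)
  ng <- tapply(overlaps$gene_id, overlaps$sample_id,
               function(g) length(unique(g)))
  cohort$total_cnv_bp <- as.integer(ifelse(is.na(bp[cohort$sample_id]), 0,
                                           bp[cohort$sample_id]))
  cohort$n_genes_overlapped <- as.integer(ifelse(is.na(ng[cohort$sample_id]), 0,
                                                 ng[cohort$sample_id]))
  cohort
}

.apply_dosage_filter <- function(overlaps, dosage_filter) {
  switch(dosage_filter,
         ALL = overlaps,
         DEL_ONLY = overlaps[overlaps$dosage == "DEL", , drop = FALSE],
         DUP_ONLY = overlaps[overlaps$dosage == "DUP", , drop = FALSE])
}

#' Carrier status with respect to a target catalog
#'
#' TRUE iff the individual has >= 1 catalog gene overlapped by a CNV passing
#' the dosage filter.
#'
#' @param overlaps an `overlap_matrix`.
#' @param catalog a `target_catalog` (or character vector of gene ids).
#' @param samples character vector of all sample ids (carriers and
#'   non-carriers alike appear in the result).
#' @param dosage_filter `"ALL"`, `"DEL_ONLY"` or `"DUP_ONLY"` for the
#'   deletion/duplication secondary analyses.
#' @return Named logical vector over `samples`.
#' @export
carrier_indicator <- function(overlaps, catalog, samples,
                              dosage_filter = c("ALL", "DEL_ONLY", "DUP_ONLY")) {
  dosage_filter <- match.arg(dosage_filter)
  genes <- if (inherits(catalog, "target_catalog")) catalog$genes else catalog
  ov <- .apply_dosage_filter(overlaps, dosage_filter)
  hit <- unique(ov$sample_id[ov$gene_id %in% genes])
  stats::setNames(samples %in% hit, samples)
}

#' Carrier status restricted to a gene set
#'
#' As [carrier_indicator()] with the catalog intersected with `gene_set`.
#'
#' @inheritParams carrier_indicator
#' @param gene_set character vector of gene ids.
#' @export
carrier_indicator_geneset <- function(overlaps, catalog, gene_set, samples,
                                      dosage_filter = c("ALL", "DEL_ONLY", "DUP_ONLY")) {
  genes <- if (inherits(catalog, "target_catalog")) catalog$genes else catalog
  carrier_indicator(overlaps, intersect(genes, gene_set), samples,
                    match.arg(dosage_filter))
}

#' Carrier status with respect to one miRNA's targets
#'
#' TRUE iff the individual overlaps >= 1 catalog gene supported by the named
#' miRNA.
#'
#' @inheritParams carrier_indicator
#' @param mirna mature miRNA name.
#' @export
carrier_indicator_mirna <- function(overlaps, catalog, mirna, samples,
                                    dosage_filter = c("ALL", "DEL_ONLY", "DUP_ONLY")) {
  stopifnot(inherits(catalog, "target_catalog"))
  targets <- names(catalog$gene_to_mirnas)[vapply(
    catalog$gene_to_mirnas,
    function(ms) .norm_mirna_name(mirna) %in% .norm_mirna_name(ms), logical(1))]
  carrier_indicator(overlaps, targets, samples, match.arg(dosage_filter))
}
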