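#' Default experiment-method classification
#'
#' Maps interaction-database method names to evidence classes.  Low-throughput
#' assays validate one interaction at a time (luciferase reporter, western
#' blot, qPCR); high-throughput assays survey many (CLIP-seq variants,
#' microarray, proteomics, degradome).  Shipped as an editable table because
#' interaction-table dialects vary.
#'
#' @return Named character vector: method name -> `"LOW_THROUGHPUT"` or
#'   `"HIGH_THROUGHPUT"`.
#' @export
method_class_map <- function() {
  c("luciferase reporter assay" = "LOW_THROUGHPUT",
    "luciferase" = "LOW_THROUGHPUT",
    "western blot" = "LOW_THROUGHPUT",
    "qpcr" = "LOW_THROUGHPUT",
    "northern blot" = "LOW_THROUGHPUT",
    "clip-seq" = "HIGH_THROUGHPUT",
    "hits-clip" = "HIGH_THROUGHPUT",
    "par-clip" = "HIGH_THROUGHPUT",
    "clash" = "HIGH_THROUGHPUT",
    "microarray" = "HIGH_THROUGHPUT",
    "rna-seq" = "HIGH_THROUGHPUT",
    "proteomics" = "HIGH_THROUGHPUT",
    "degradome sequencing" = "HIGH_THROUGHPUT")
}

#' Filter miRNA-gene interaction records for high-confidence support
#'
#' A (miRNA, gene) pair survives iff, among its human, downregulation-direction
#' records, it has at least one low-throughput experiment or at least two
#' high-throughput experiments with distinct method names.  Records with a
#' method absent from `method_map` are reported and excluded conservatively.
#'
#' @param records data frame with columns `mirna`, `gene_id`, `species`,
#'   `method`, `direction` (`DOWN`/`UP`/other; case-insensitive), optionally
#'   `gene_symbol`.
#' @param method_map named vector as from [method_class_map()].
#' @return List with `records` (surviving rows), `pairs` (surviving
#'   (mirna, gene_id) pairs), `provenance` (per-criterion rejection counts)
#'   and `unclassified_methods`.
#' @export
filter_interactions <- function(records, method_map = method_class_map()) {
  stopifnot(all(c("mirna", "gene_id", "species", "method", "direction") %in%
                names(records)))
  records <- unique(records)
  n0 <- nrow(records)
  key <- paste(records$mirna, records$gene_id, sep = "\r")
  pairs0 <- unique(key)

  human <- tolower(records$species) %in% c("human", "hsa", "homo sapiens")
  down <- toupper(records$direction) == "DOWN"
  cls <- unname(method_map[tolower(records$method)])
  unclassified <- unique(records$method[is.na(cls)])
  if (length(unclassified))
    message("unclassified method(s), excluded conservatively: ",
            paste(unclassified, collapse = ", "))

  ok <- human & down & !is.na(cls)
  rec <- records[ok, , drop = FALSE]
  reckey <- key[ok]
  reccls <- cls[ok]

  keep_pair <- vapply(split(seq_along(reckey), reckey), function(i) {
    low <- any(reccls[i] == "LOW_THROUGHPUT")
    n_high <- length(unique(tolower(rec$method[i][reccls[i] == "HIGH_THROUGHPUT"])))
    low || n_high >= 2
  }, logical(1))
  surviving <- names(keep_pair)[keep_pair]
  out <- rec[reckey %in% surviving, , drop = FALSE]
  rownames(out) <- NULL

  prov <- list(
    n_records_in = n0,
    n_pairs_in = length(pairs0),
    n_records_nonhuman = sum(!human),
    n_records_not_down = sum(human & !down),
    n_records_unclassified_method = sum(human & down & is.na(cls)),
    n_pairs_insufficient_evidence = sum(!keep_pair),
    n_pairs_out = length(surviving))
  list(records = out,
       pairs = unique(out[, c("mirna", "gene_id")]),
       provenance = prov,
       unclassified_methods = unclassified)
}

#' Restrict filtered interactions to conserved target genes
#'
#' Intersects the filtered target genes with a conserved-target list
#' (TargetScan-style) and builds the target catalog.  The restriction is
#' applied per gene by default; `per_pair = TRUE` additionally requires each
#' (miRNA, gene) pair's gene to be conserved, which for a gene-level list is
#' equivalent — the option exists for pair-level conservation inputs.
#'
#' @param filtered output of [filter_interactions()].
#' @param conserved_genes character vector of conserved gene ids.
#' @param per_pair apply the restriction per (miRNA, gene) pair.
#' @return A `target_catalog`: list with `genes`, `gene_to_mirnas` (named list
#'   gene id -> miRNA names) and `provenance`.
#' @export
restrict_to_conserved <- function(filtered, conserved_genes, per_pair = FALSE) {
  pairs <- filtered$pairs
  genes_in <- unique(pairs$gene_id)
  keep <- intersect(genes_in, conserved_genes)
  if (length(keep) == 0 && length(genes_in) > 0)
    warning("no filtered target gene is in the conserved list; empty catalog")
  pairs <- pairs[pairs$gene_id %in% keep, , drop = FALSE]
  g2m <- lapply(split(pairs$mirna, pairs$gene_id), function(x) sort(unique(x)))
  prov <- c(filtered$provenance,
            list(n_genes_filtered = length(genes_in),
                 n_conserved_list = length(unique(conserved_genes)),
                 n_genes_catalog = length(keep),
                 conserved_restriction = if (per_pair) "per_pair" else "per_gene"))
  structure(list(genes = sort(keep), gene_to_mirnas = g2m, provenance = prov),
            class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  cat(sprintf("target_catalog: %d genes, %d miRNAs\n",
              length(x$genes), length(unique(unlist(x$gene_to_mirnas)))))
  invisible(x)
}

#' All miRNAs supporting at least one catalog gene
#' @param catalog a `target_catalog`.
#' @export
catalog_mirnas <- function(catalog) sort(unique(unlist(catalog$gene_to_mirnas)))

#' Build a mature miRNA reference table
#'
#' Computes the arm (from the `-5p`/`-3p` name suffix) and the 6-mer seed
#' (nucleotides 2-7 of the mature sequence, the TargetScan convention) for
#' each record.  Mature miRNAs that are different arms of the same precursor
#' are distinct records.
#'
#' @param df data frame with columns `name`, `accession`, `sequence`
#'   (RNA alphabet A/C/G/U).
#' @param seed_from,seed_to 1-based seed window bounds (defaults 2 and 7).
#' @return The input with added `species_prefix`, `arm`, `seed6` columns.
#' @export
mirna_reference <- function(df, seed_from = 2L, seed_to = 7L) {
  stopifnot(all(c("name", "sequence") %in% names(df)))
  bad <- grepl("[^ACGU]", toupper(df$sequence))
  if (any(bad)) stop("non-RNA character in mature sequence of: ",
                     paste(df$name[bad], collapse = ", "))
  df$species_prefix <- sub("-.*$", "", df$name)
  df$arm <- ifelse(grepl("-5p$", df$name), "FIVE_P",
                   ifelse(grepl("-3p$", df$name), "THREE_P", "UNSPECIFIED"))
  df$seed6 <- substr(toupper(df$sequence), seed_from, seed_to)
  df
}

.norm_mirna_name <- function(x) {
  # Lowercase the miR infix for matching only; display names keep casing.
  tolower(x)
}

#' Harmonise miRNA names against a reference nomenclature
#'
#' Converts raw (possibly deprecated) miRNA names to current reference
#' records, retaining one-to-many mappings in full.  Matching is
#' case-insensitive on the `miR`/`mir` infix; unresolvable names are reported,
#' never errors.
#'
#' @param raw_names character vector of names as found in source lists.
#' @param reference a [mirna_reference()] table.
#' @param alias_table optional data frame `old_name`, `new_name` (one row per
#'   mapping; a deprecated name may map to several current names).
#' @return List with `map` (named list raw name -> character vector of
#'   reference names) and `unmapped` (raw names resolving to nothing).
#' @export
harmonize_names <- function(raw_names, reference, alias_table = NULL) {
  ref_lookup <- split(reference$name, .norm_mirna_name(reference$name))
  alias_lookup <- if (!is.null(alias_table))
    split(alias_table$new_name, .norm_mirna_name(alias_table$old_name)) else list()
  map <- lapply(raw_names, function(raw) {
    k <- .norm_mirna_name(raw)
    hits <- ref_lookup[[k]]
    if (is.null(hits)) {
      via <- alias_lookup[[k]]
      if (!is.null(via))
        hits <- unlist(ref_lookup[.norm_mirna_name(via)], use.names = FALSE)
    }
    if (is.null(hits)) character(0) else sort(unique(hits))
  })
  names(map) <- raw_names
  unmapped <- raw_names[lengths(map) == 0]
  if (length(unmapped))
    message("unmapped miRNA name(s): ", paste(unique(unmapped), collapse = ", "))
  list(map = map, unmapped = unique(unmapped))
}

#' Map mouse miRNAs to human counterparts with identical seeds
#'
#' For each `mmu-` miRNA, the `hsa-` record with the same number-and-arm name
#' is located in the reference; the human record is kept iff the two 6-mer
#' seeds are identical.  Mouse miRNAs without a human counterpart are
#' excluded and reported.
#'
#' @param mmu_names character vector of mouse mature miRNA names.
#' @param reference a [mirna_reference()] containing both species.
#' @return Character vector of retained human miRNA names (deduplicated,
#'   sorted), with attributes `excluded_seed_mismatch` and
#'   `excluded_no_counterpart`.
#' @export
seed_filter_mouse <- function(mmu_names, reference) {
  stopifnot("seed6" %in% names(reference))
  norm <- .norm_mirna_name(reference$name)
  kept <- character(0); mism <- character(0); nocp <- character(0)
  for (mm in unique(mmu_names)) {
    if (!grepl("^mmu-", mm, ignore.case = TRUE)) next
    hs <- sub("^mmu-", "hsa-", mm, ignore.case = TRUE)
    i_m <- which(norm == .norm_mirna_name(mm))
    i_h <- which(norm == .norm_mirna_name(hs))
    if (!length(i_m) || !length(i_h)) { nocp <- c(nocp, mm); next }
    if (reference$seed6[i_m[1]] == reference$seed6[i_h[1]])
      kept <- c(kept, reference$name[i_h[1]])
    else mism <- c(mism, mm)
  }
  if (length(nocp)) message("no human counterpart for: ", paste(nocp, collapse = ", "))
  structure(sort(unique(kept)),
            excluded_seed_mismatch = mism, excluded_no_counterpart = nocp)
}

#' Restrict a catalog to targets of differentially expressed miRNAs
#'
#' Keeps exactly the catalog genes supported by at least one miRNA on the
#' (harmonised, seed-filtered) differential-expression list.
#'
#' @param catalog a `target_catalog`.
#' @param de_mirnas character vector of miRNA names (human nomenclature), or
#'   a data frame with a `mirna` column.
#' @return A `target_catalog` that is a subset of the input.
#' @export
build_de_subcatalog <- function(catalog, de_mirnas) {
  if (is.data.frame(de_mirnas)) de_mirnas <- de_mirnas$mirna
  de <- .norm_mirna_name(unique(de_mirnas))
  keep <- vapply(catalog$gene_to_mirnas,
                 function(ms) any(.norm_mirna_name(ms) %in% de), logical(1))
  genes <- intersect(catalog$genes, names(keep)[keep])
  g2m <- catalog$gene_to_mirnas[genes]
  prov <- c(catalog$provenance,
            list(n_de_mirnas = length(de), n_genes_de_subcatalog = length(genes)))
  structure(list(genes = sort(genes), gene_to_mirnas = g2m, provenance = prov),
            class = "target_catalog")
}

#' Cross-study convergence of differentially expressed miRNAs
#'
#' Summarises, per miRNA, in how many studies it was reported and in which
#' directions; miRNAs reported both up- and down-regulated (in different
#' studies) are tagged discordant.
#'
#' @param de_list data frame `mirna`, `study`, `direction` (`UP`/`DOWN`),
#'   already harmonised.
#' @return List with `per_mirna` (data frame `mirna`, `n_studies`,
#'   `direction` in DOWN/UP/discordant) and `overall` (totals by direction
#'   plus the single-study count).
#' @export
study_convergence <- function(de_list) {
  stopifnot(all(c("mirna", "study", "direction") %in% names(de_list)))
  de_list <- unique(de_list[, c("mirna", "study", "direction")])
  sp <- split(de_list, de_list$mirna)
  per <- do.call(rbind, lapply(sp, function(r) {
    dirs <- unique(toupper(r$direction))
    data.frame(mirna = r$mirna[1],
               n_studies = length(unique(r$study)),
               direction = if (length(dirs) > 1) "discordant" else dirs,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per <- per[order(-per$n_studies, per$mirna), , drop = FALSE]
  overall <- list(n_mirnas = nrow(per),
                  n_down = sum(per$direction == "DOWN"),
                  n_up = sum(per$direction == "UP"),
                  n_discordant = sum(per$direction == "discordant"),
                  n_single_study = sum(per$n_studies == 1))
  list(per_mirna = per, overall = overall)
}
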