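#' Column and vocabulary dialect for the phenotype table
#'
#' @param sample,group,sex column names in the TSV.
#' @param case_labels,control_labels tokens mapped to the CASE / CONTROL
#'   groups (case-insensitive).
#' @param male_labels,female_labels tokens mapped to MALE / FEMALE.
#' @return A named list understood by [read_phenotypes()].
#' @export
phenotype_dialect <- function(sample = "sample", group = "group", sex = "sex",
                              case_labels = c("CASE", "schizophrenia", "SCZ"),
                              control_labels = c("CONTROL", "non-psychotic", "NP"),
                              male_labels = c("MALE", "M"),
                              female_labels = c("FEMALE", "F")) {
  list(sample = sample, group = group, sex = sex,
       case_labels = tolower(case_labels), control_labels = tolower(control_labels),
       male_labels = tolower(male_labels), female_labels = tolower(female_labels))
}

.map_tokens <- function(x, levels_list, what) {
  out <- rep(NA_character_, length(x))
  for (lev in names(levels_list)) out[tolower(x) %in% levels_list[[lev]]] <- lev
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop(sprintf("unknown %s value(s): %s", what, paste(bad, collapse = ", ")))
  }
  out
}

#' Read a phenotype table
#'
#' One row per individual: sample id, group (case/control), sex.  Sex is
#' required because it enters the logistic burden model as a covariate;
#' missing-sex rows are rejected rather than imputed.
#'
#' @param path TSV file with a header row.
#' @param dialect a [phenotype_dialect()].
#' @return A `cnv_cohort` data frame with columns `sample_id`, `group`
#'   (factor CASE/CONTROL) and `sex` (factor FEMALE/MALE).
#' @export
read_phenotypes <- function(path, dialect = phenotype_dialect()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(dialect$sample, dialect$group, dialect$sex)
  if (!all(need %in% names(df)))
    stop("phenotype table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) {
    warning("phenotype table has no rows")
    return(new_cohort(character(0), character(0), character(0)))
  }
  ids <- as.character(df[[dialect$sample]])
  if (anyDuplicated(ids))
    stop("duplicated sample_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(is.na(df[[dialect$sex]]) | df[[dialect$sex]] == ""))
    stop("missing sex for sample(s): ",
         paste(ids[is.na(df[[dialect$sex]]) | df[[dialect$sex]] == ""], collapse = ", "))
  group <- .map_tokens(df[[dialect$group]],
                       list(CASE = dialect$case_labels, CONTROL = dialect$control_labels),
                       "group")
  sex <- .map_tokens(df[[dialect$sex]],
                     list(MALE = dialect$male_labels, FEMALE = dialect$female_labels),
                     "sex")
  cohort <- new_cohort(ids, group, sex)
  message(sprintf("cohort: %d CASE / %d CONTROL; %d FEMALE / %d MALE",
                  sum(group == "CASE"), sum(group == "CONTROL"),
                  sum(sex == "FEMALE"), sum(sex == "MALE")))
  cohort
}

new_cohort <- function(sample_id, group, sex) {
  structure(data.frame(sample_id = as.character(sample_id),
                       group = factor(group, levels = c("CASE", "CONTROL")),
                       sex = factor(sex, levels = c("FEMALE", "MALE")),
                       stringsAsFactors = FALSE),
            class = c("cnv_cohort", "data.frame"))
}

AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

#' Vocabulary dialect for CNV call tables
#'
#' @param chrom,start,end,sample,dosage,control_freq column names
#'   (`control_freq` optional in the file).
#' @param del_labels,dup_labels dosage tokens mapped to DEL / DUP.
#' @export
cnv_dialect <- function(chrom = "chrom", start = "start", end = "end",
                        sample = "sample", dosage = "dosage",
                        control_freq = "control_freq",
                        del_labels = c("DEL", "loss", "deletion"),
                        dup_labels = c("DUP", "gain", "duplication")) {
  list(chrom = chrom, start = start, end = end, sample = sample,
       dosage = dosage, control_freq = control_freq,
       del_labels = tolower(del_labels), dup_labels = tolower(dup_labels))
}

#' Read rare CNV calls
#'
#' Coordinates are normalised to 0-based half-open at the boundary; calls
#' shorter than `min_len_bp` (default 10 kb, the rarity pipeline's floor) are
#' dropped with a logged count, and non-autosomal calls are dropped with a
#' warning.  When a control-frequency column is present, rows exceeding
#' `max_control_freq` are rejected: population rarity is upstream provenance
#' that is validated, not computed, here.
#'
#' @param path TSV with columns chrom, start, end, sample, dosage
#'   (`[, control_freq]`).
#' @param phenotypes optional `cnv_cohort`; unknown sample ids then error.
#' @param min_len_bp minimum call length in bp after normalisation.
#' @param coordinate_dialect `"BED0"` (0-based half-open) or
#'   `"ONE_BASED_INCLUSIVE"`.
#' @param dialect a [cnv_dialect()].
#' @param max_control_freq rarity threshold checked when the frequency column
#'   exists.
#' @return Data frame `sample_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `dosage` (factor DEL/DUP), `length_bp`.
#' @export
read_cnvs <- function(path, phenotypes = NULL, min_len_bp = 10000,
                      coordinate_dialect = c("BED0", "ONE_BASED_INCLUSIVE"),
                      dialect = cnv_dialect(), max_control_freq = 0.001) {
  coordinate_dialect <- match.arg(coordinate_dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(dialect$chrom, dialect$start, dialect$end, dialect$sample, dialect$dosage)
  if (!all(need %in% names(df)))
    stop("CNV table missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  start <- as.integer(df[[dialect$start]])
  end <- as.integer(df[[dialect$end]])
  if (anyNA(start) || anyNA(end)) stop("non-integer CNV coordinates")
  if (coordinate_dialect == "ONE_BASED_INCLUSIVE") start <- start - 1L
  if (any(start >= end))
    stop("start >= end after normalisation at row(s): ",
         paste(which(start >= end), collapse = ", "))
  dosage <- .map_tokens(df[[dialect$dosage]],
                        list(DEL = dialect$del_labels, DUP = dialect$dup_labels),
                        "dosage")
  out <- data.frame(sample_id = as.character(df[[dialect$sample]]),
                    chrom = as.character(df[[dialect$chrom]]),
                    start = start, end = end,
                    dosage = factor(dosage, levels = c("DEL", "DUP")),
                    stringsAsFactors = FALSE)
  out$length_bp <- out$end - out$start
  if (!is.null(phenotypes)) {
    unk <- setdiff(out$sample_id, phenotypes$sample_id)
    if (length(unk)) stop("CNV sample id(s) absent from phenotypes: ",
                          paste(unk, collapse = ", "))
  }
  non_auto <- !(out$chrom %in% AUTOSOMES)
  if (any(non_auto)) {
    warning(sprintf("dropped %d non-autosomal call(s)", sum(non_auto)))
    out <- out[!non_auto, , drop = FALSE]
  }
  short <- out$length_bp < min_len_bp
  if (any(short)) message(sprintf("dropped %d call(s) < %d bp", sum(short), min_len_bp))
  out <- out[!short, , drop = FALSE]
  if (dialect$control_freq %in% names(df)) {
    freq <- as.numeric(df[[dialect$control_freq]])[!non_auto]
    freq <- freq[!short]
    common <- !is.na(freq) & freq >= max_control_freq
    if (any(common)) {
      message(sprintf("dropped %d call(s) with control frequency >= %g",
                      sum(common), max_control_freq))
      out <- out[!common, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Write normalised CNV calls (BED0 coordinates)
#'
#' @param cnvs output of [read_cnvs()] or the synthetic generator.
#' @param path destination TSV.
#' @export
write_cnvs <- function(cnvs, path) {
  utils::write.table(
    data.frame(chrom = cnvs$chrom, start = cnvs$start, end = cnvs$end,
               sample = cnvs$sample_id, dosage = as.character(cnvs$dosage)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-coding gene annotation
#'
#' Gene spans are the full gene body (TSS through TES, introns and UTRs
#' included), matching a genic-CNV criterion of >= 1 bp overlap with exonic,
#' intronic or untranslated sequence.  Non-protein-coding genes are kept in
#' the returned table but flagged excluded from analyses.
#'
#' @param path GFF3 file (gene features with ID/gene_id and a biotype
#'   attribute) or BED file.
#' @param format `"GFF3"` or `"BED"`.
#' @param bed_biotype for BED input without a biotype column, the biotype
#'   assumed for every record.
#' @return Data frame `gene_id`, `symbol`, `chrom`, `start`, `end` (0-based
#'   half-open union span per gene), `biotype`.
#' @export
read_gene_annotation <- function(path, format = c("GFF3", "BED"),
                                 bed_biotype = "protein_coding") {
  format <- match.arg(format)
  if (format == "GFF3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    md <- S4Vectors::mcols(gr)
    gene_id <- if ("gene_id" %in% names(md)) md$gene_id else md$ID
    if (is.null(gene_id) || anyNA(gene_id))
      stop("GFF3 gene feature without an ID/gene_id attribute")
    biotype <- if ("gene_biotype" %in% names(md)) md$gene_biotype
               else if ("biotype" %in% names(md)) md$biotype
               else rep("protein_coding", length(gr))
    symbol <- if ("Name" %in% names(md)) md$Name else gene_id
    ann <- data.frame(gene_id = as.character(gene_id),
                      symbol = as.character(symbol),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,  # GFF3 is 1-based
                      end = GenomicRanges::end(gr),
                      biotype = as.character(biotype),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED annotation needs >= 4 columns (chrom,start,end,name)")
    ann <- data.frame(gene_id = as.character(df[[4]]),
                      symbol = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                      biotype = if (ncol(df) >= 7) as.character(df[[7]])
                                else rep(bed_biotype, nrow(df)),
                      stringsAsFactors = FALSE)
  }
  if (any(ann$start >= ann$end)) stop("gene with start >= end in annotation")
  # Two features of one gene collapse to the union span.
  if (anyDuplicated(ann$gene_id)) {
    sp <- split(seq_len(nrow(ann)), ann$gene_id)
    ann <- do.call(rbind, lapply(sp, function(i) {
      r <- ann[i, , drop = FALSE]
      if (length(unique(r$chrom)) > 1)
        stop("gene ", r$gene_id[1], " spans multiple chromosomes")
      data.frame(gene_id = r$gene_id[1], symbol = r$symbol[1], chrom = r$chrom[1],
                 start = min(r$start), end = max(r$end), biotype = r$biotype[1],
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(ann) <- NULL
  n_pc <- sum(ann$biotype == "protein_coding")
  if (n_pc < nrow(ann))
    message(sprintf("%d of %d genes are protein_coding; others flagged excluded",
                    n_pc, nrow(ann)))
  ann
}

#' Restrict an annotation to protein-coding genes
#' @param annotation output of [read_gene_annotation()].
#' @export
protein_coding <- function(annotation) {
  annotation[annotation$biotype == "protein_coding", , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, members...).
#' @param categories named character vector mapping set name to a category
#'   label (e.g. neuro-functional, mouse-neuro, brain expression, mouse body
#'   systems); sets without an entry get category `"uncategorized"`.
#' @param annotation optional gene annotation; unresolved members are then
#'   reported (not dropped).
#' @return A `gene_set_collection`: list with `sets` (named list of gene-id
#'   vectors) and `category` (named character vector).
#' @export
read_gene_sets <- function(path, categories = NULL, annotation = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  gene_set_collection(sets, categories = categories, annotation = annotation)
}

#' Construct a gene-set collection from a named list
#' @param sets named list of gene-id character vectors.
#' @inheritParams read_gene_sets
#' @export
gene_set_collection <- function(sets, categories = NULL, annotation = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  category <- stats::setNames(rep("uncategorized", length(sets)), names(sets))
  if (!is.null(categories)) {
    hit <- intersect(names(categories), names(sets))
    category[hit] <- categories[hit]
  }
  if (!is.null(annotation)) {
    for (nm in names(sets)) {
      unresolved <- setdiff(sets[[nm]], annotation$gene_id)
      if (length(unresolved))
        message(sprintf("set %s: %d unresolved member(s)", nm, length(unresolved)))
    }
  }
  empty <- lengths(sets) == 0
  if (any(empty)) message(sprintf("%d empty set(s) flagged; excluded from testing",
                                  sum(empty)))
  structure(list(sets = sets, category = category), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x$sets)))
  print(table(x$category))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path destination file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$category[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
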