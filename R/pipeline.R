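#' Fisher check on subset selection
#'
#' Tests whether selection into the genic-CNV subset differed by group:
#' selected vs not-selected individuals per group.
#'
#' @param n_selected_case,n_total_case selected and total counts, case group.
#' @param n_selected_control,n_total_control same for the control group.
#' @return An `exact_test_result`.
#' @examples
#' run_subset_check(100, 158, 118, 171)  # OR 0.775, p 0.2948
#' @export
run_subset_check <- function(n_selected_case, n_total_case,
                             n_selected_control, n_total_control) {
  stopifnot(n_selected_case <= n_total_case,
            n_selected_control <= n_total_control)
  exact_test_2x2(contingency_2x2(
    n_selected_case, n_total_case - n_selected_case,
    n_selected_control, n_total_control - n_selected_control))
}

#' Fisher check on the sex imbalance between groups
#'
#' Oriented so the odds ratio is female-in-control vs female-in-case:
#' (females in control, males in control, females in case, males in case).
#'
#' @param cohort a `cnv_cohort`, or NULL when counts are given directly.
#' @param counts optional integer vector `c(a, b, c, d)` in the orientation
#'   above, overriding `cohort`.
#' @return An `exact_test_result`.
#' @export
run_sex_check <- function(cohort = NULL, counts = NULL) {
  t <- if (!is.null(counts)) as_contingency_2x2(counts) else {
    ctrl <- cohort$group == "CONTROL"
    contingency_2x2(sum(ctrl & cohort$sex == "FEMALE"),
                    sum(ctrl & cohort$sex == "MALE"),
                    sum(!ctrl & cohort$sex == "FEMALE"),
                    sum(!ctrl & cohort$sex == "MALE"))
  }
  exact_test_2x2(t)
}

.digest_file <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Sequences: catalog build (full and differential-expression-restricted),
#' headline burden on both catalogs (unadjusted Fisher + adjusted logistic),
#' dosage-stratified burden, self-contained and competitive gene-set
#' enrichment, miRNA attribution (broad and exclusive), and optional
#' single-miRNA queries; writes result TSVs, a JSON provenance file, and a
#' run manifest.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `phenotypes`, `cnvs`, `annotation`, `interactions`, `conserved`,
#'   `de_list`, `gene_sets` (file paths); optional `gene_set_categories`
#'   (named list set -> category), `annotation_format`, `coordinate_dialect`,
#'   `min_len_bp`, `query_mirnas`, `background` (path; defaults to all
#'   protein-coding annotation genes).
#' @param out_dir output directory.
#' @return The run manifest (invisibly a list), with all results attached.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  needed <- c("phenotypes", "cnvs", "annotation", "interactions", "conserved",
              "de_list", "gene_sets")
  missing_in <- needed[!vapply(needed, function(k)
    !is.null(config[[k]]) && file.exists(config[[k]]), logical(1))]
  if (length(missing_in))
    stop("missing input(s): ", paste(missing_in, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- read_phenotypes(config$phenotypes)
  cnvs <- read_cnvs(config$cnvs, phenotypes = cohort,
                    min_len_bp = config$min_len_bp %||% 10000,
                    coordinate_dialect = config$coordinate_dialect %||% "BED0")
  genes <- read_gene_annotation(config$annotation,
                                format = config$annotation_format %||% "GFF3")
  interactions <- utils::read.delim(config$interactions, stringsAsFactors = FALSE)
  conserved <- readLines(config$conserved)
  de_list <- utils::read.delim(config$de_list, stringsAsFactors = FALSE)
  cats <- config$gene_set_categories
  sets <- read_gene_sets(config$gene_sets,
                         categories = if (is.null(cats)) NULL else unlist(cats),
                         annotation = genes)

  filtered <- filter_interactions(interactions)
  catalog <- restrict_to_conserved(filtered, conserved)
  de_catalog <- build_de_subcatalog(catalog, de_list)

  overlaps <- overlap_genes(cnvs, genes)
  cohort <- cohort_covariates(cohort, cnvs, overlaps)
  background <- if (!is.null(config$background)) readLines(config$background)
                else protein_coding(genes)$gene_id

  burden_one <- function(cat_obj, dosage = "ALL") {
    carr <- carrier_indicator(overlaps, cat_obj, cohort$sample_id, dosage)
    t <- burden_table(cohort, carr)
    list(table = t, unadjusted = exact_test_2x2(t),
         adjusted = tryCatch(fit_logistic_burden(cohort, carr),
                             error = function(e) NULL))
  }
  burden <- list(full = burden_one(catalog),
                 de_restricted = burden_one(de_catalog),
                 full_del = burden_one(catalog, "DEL_ONLY"),
                 full_dup = burden_one(catalog, "DUP_ONLY"))

  self_res <- self_contained_enrichment(cohort, overlaps, catalog, sets)
  comp_res <- competitive_enrichment(overlaps, catalog, sets, background, cohort)
  report <- enrichment_report(self_res, comp_res)

  classified <- classify_mirnas(overlaps, catalog, cohort)
  broad <- test_broad(classified, cohort)
  exclusive <- test_exclusive(classified, cohort)
  queries <- lapply(config$query_mirnas %||% character(0), function(m)
    single_mirna_burden(overlaps, catalog, cohort, m))
  names(queries) <- config$query_mirnas %||% character(0)

  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  et_row <- function(name, x) data.frame(
    analysis = name, a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    or = x$unadjusted$or, ci_low = x$unadjusted$ci_low,
    ci_high = x$unadjusted$ci_high, p = x$unadjusted$p,
    adj_or = if (is.null(x$adjusted)) NA else carrier_effect(x$adjusted)$or,
    adj_p = if (is.null(x$adjusted)) NA else carrier_effect(x$adjusted)$p,
    stringsAsFactors = FALSE)
  paths <- c(
    burden = tsv(do.call(rbind, Map(et_row, names(burden), burden)), "burden.tsv"),
    self_enrichment = tsv(self_res, "enrichment_self.tsv"),
    competitive_enrichment = tsv(comp_res, "enrichment_competitive.tsv"),
    convergence = tsv(report, "enrichment_convergence.tsv"),
    mirna_broad = tsv(broad, "mirna_broad.tsv"),
    mirna_exclusive = tsv(exclusive, "mirna_exclusive.tsv"),
    mirna_classified = tsv(classified, "mirna_classified.tsv"))

  manifest <- list(
    config = config,
    input_digests = vapply(needed, function(k) .digest_file(config[[k]]),
                           character(1)),
    catalog_provenance = catalog$provenance,
    de_catalog_size = length(de_catalog$genes),
    n_case = sum(cohort$group == "CASE"),
    n_control = sum(cohort$group == "CONTROL"),
    background_size = length(unique(background)),
    result_paths = as.list(paths),
    package_version = as.character(utils::packageVersion("mirCNVburden")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest,
              list(burden = burden, self_enrichment = self_res,
                   competitive_enrichment = comp_res, convergence = report,
                   broad = broad, exclusive = exclusive, queries = queries,
                   catalog = catalog, de_catalog = de_catalog,
                   cohort = cohort, overlaps = overlaps)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
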