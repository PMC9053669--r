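#' Synthetic-cohort generator configuration
#'
#' Defaults mirror the study conditions the pipeline is built for: groups of
#' 100 cases / 118 controls, female proportions 0.48 / 0.64, a baseline
#' (control-group) catalog-carrier rate of 0.49 with a carrier odds ratio of
#' 2.3 under the alternative (1.0 gives the null), CNV lengths log-uniform
#' between a 10 kb floor and 2 Mb.  Annotation size and miRNA wiring are
#' desk-scale stand-ins for the licensed databases.
#'
#' @param n_case,n_control group sizes.
#' @param p_female_case,p_female_control female proportions per group.
#' @param n_genes protein-coding annotation size.
#' @param p_noncoding fraction of additional non-protein-coding genes.
#' @param p_catalog fraction of protein-coding genes in the target catalog.
#' @param base_carrier_rate control-group probability of carrying a CNV over
#'   a catalog gene.
#' @param carrier_or target carrier odds ratio (case vs control).
#' @param cnv_rate mean number of background (non-catalog) CNVs per
#'   individual (Poisson).
#' @param cnv_len_min,cnv_len_max CNV length bounds in bp (log-uniform).
#' @param n_mirnas,targets_per_mirna catalog wiring.
#' @param n_studies number of differential-expression model studies emulated.
#' @param seed RNG seed; identical seed + config give identical outputs.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_case = 100, n_control = 118,
                             p_female_case = 0.48, p_female_control = 0.64,
                             n_genes = 300, p_noncoding = 0.05,
                             p_catalog = 0.4,
                             base_carrier_rate = 0.49, carrier_or = 2.3,
                             cnv_rate = 1.2,
                             cnv_len_min = 1e4, cnv_len_max = 2e6,
                             n_mirnas = 25, targets_per_mirna = 8,
                             n_studies = 5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_case > 0, n_control > 0, n_genes > 0, n_mirnas > 0,
            p_female_case >= 0, p_female_case <= 1,
            p_female_control >= 0, p_female_control <= 1,
            p_catalog > 0, p_catalog <= 1,
            base_carrier_rate > 0, base_carrier_rate < 1,
            carrier_or > 0, cnv_len_min >= 1e4, cnv_len_max >= cnv_len_min)
  structure(cfg, class = "generator_config")
}

#' Solve group-wise carrier probabilities from a base rate and odds ratio
#'
#' The control-group probability is the base rate; the case-group probability
#' is obtained analytically from the odds ratio, so the generator is exactly
#' calibrated rather than calibrated by rejection.
#'
#' @param base_rate control-group carrier probability.
#' @param or carrier odds ratio.
#' @return `c(p_case, p_control)`.
#' @export
solve_carrier_probs <- function(base_rate, or) {
  stopifnot(base_rate > 0, base_rate < 1, or > 0, is.finite(or))
  odds_case <- or * base_rate / (1 - base_rate)
  p_case <- odds_case / (1 + odds_case)
  if (p_case <= 0 || p_case >= 1)
    stop("infeasible base_rate / carrier_or combination")
  c(p_case = p_case, p_control = base_rate)
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gene layout: genes every 3 Mb along autosomes so a CNV anchored inside one
# gene (max length 2 Mb) can never spill into the next; gene bodies are 50 kb.
.gene_layout <- function(n_total) {
  per_chrom <- ceiling(n_total / 22)
  idx <- seq_len(n_total) - 1L
  chrom <- paste0("chr", idx %% 22 + 1)
  slot <- idx %/% 22
  start <- 1e6 + slot * 3e6
  data.frame(gene_id = sprintf("GENE%04d", seq_len(n_total)),
             symbol = sprintf("G%d", seq_len(n_total)),
             chrom = chrom, start = as.integer(start),
             end = as.integer(start + 5e4),
             stringsAsFactors = FALSE)
}

.place_cnv <- function(gene_row, len) {
  start <- gene_row$start + sample.int(5e4, 1) - 1L
  data.frame(chrom = gene_row$chrom, start = as.integer(start),
             end = as.integer(start + len), stringsAsFactors = FALSE)
}

.draw_len <- function(n, cfg) {
  as.integer(round(exp(stats::runif(n, log(cfg$cnv_len_min), log(cfg$cnv_len_max)))))
}

#' Generate a complete synthetic study
#'
#' Produces the seven mutually consistent artifacts the pipeline consumes:
#' phenotypes, CNV calls, gene annotation, miRNA-gene interaction table,
#' conserved-gene list, differential-expression miRNA list, and gene sets.
#' Carrier status is induced by placing >= 1 CNV over a catalog gene with
#' group-dependent probability solved from (`base_carrier_rate`,
#' `carrier_or`); background CNVs land on non-catalog genes only, so intended
#' carrier status is exactly recoverable by the overlap pipeline.  Covariates
#' (total CNV bp, genes overlapped) arise from group-independent
#' distributions.
#'
#' @param cfg a [generator_config()].
#' @param dir optional directory; when given, all artifacts are also written
#'   in the file dialects the readers consume.
#' @return List: `phenotypes` (`cnv_cohort`), `cnvs`, `genes`, `interactions`,
#'   `conserved`, `de_list`, `gene_sets`, `catalog_genes`, `carrier`
#'   (intended status), `config`, and `paths` when `dir` is given.
#' @export
generate_cohort <- function(cfg = generator_config(), dir = NULL) {
  with_preserved_seed(cfg$seed, {
    probs <- solve_carrier_probs(cfg$base_carrier_rate, cfg$carrier_or)
    n <- cfg$n_case + cfg$n_control
    ids <- sprintf("S%03d", seq_len(n))
    group <- c(rep("CASE", cfg$n_case), rep("CONTROL", cfg$n_control))
    sex <- ifelse(stats::runif(n) < ifelse(group == "CASE", cfg$p_female_case,
                                           cfg$p_female_control),
                  "FEMALE", "MALE")
    phenotypes <- new_cohort(ids, group, sex)

    n_nc <- max(0L, round(cfg$p_noncoding * cfg$n_genes))
    genes <- .gene_layout(cfg$n_genes + n_nc)
    genes$biotype <- c(rep("protein_coding", cfg$n_genes), rep("lincRNA", n_nc))
    pc <- genes$gene_id[genes$biotype == "protein_coding"]

    n_cat <- max(1L, round(cfg$p_catalog * length(pc)))
    catalog_genes <- sort(sample(pc, n_cat))
    noncat <- setdiff(pc, catalog_genes)

    # miRNA wiring: every catalog gene gets >= 1 miRNA, then extra targets
    mirnas <- sprintf("hsa-miR-sim%d-5p", seq_len(cfg$n_mirnas))
    pairs <- data.frame(mirna = sample(mirnas, n_cat, replace = TRUE),
                        gene_id = catalog_genes, stringsAsFactors = FALSE)
    extra <- data.frame(
      mirna = rep(mirnas, each = cfg$targets_per_mirna),
      gene_id = sample(catalog_genes, cfg$n_mirnas * cfg$targets_per_mirna,
                       replace = TRUE),
      stringsAsFactors = FALSE)
    pairs <- unique(rbind(pairs, extra))
    sym <- stats::setNames(genes$symbol, genes$gene_id)
    interactions <- data.frame(mirna = pairs$mirna, gene_id = pairs$gene_id,
                               gene_symbol = unname(sym[pairs$gene_id]),
                               species = "human",
                               method = "luciferase reporter assay",
                               direction = "DOWN", stringsAsFactors = FALSE)
    conserved <- sort(c(catalog_genes, sample(noncat, min(10, length(noncat)))))

    de_list <- do.call(rbind, lapply(seq_len(cfg$n_studies), function(s) {
      picked <- sample(mirnas, max(1L, round(length(mirnas) / 3)))
      data.frame(mirna = picked, study = sprintf("study%d", s),
                 direction = sample(c("DOWN", "UP"), length(picked),
                                    replace = TRUE, prob = c(0.8, 0.2)),
                 stringsAsFactors = FALSE)
    }))

    set_names <- c("neuro_set1", "neuro_set2", "brain_set1", "mouse_set1")
    categories <- stats::setNames(c("neuro-functional", "neuro-functional",
                                    "brain expression", "mouse body systems"),
                                  set_names)
    gene_sets <- gene_set_collection(
      stats::setNames(lapply(set_names, function(nm)
        sort(sample(pc, max(5L, round(length(pc) / 10))))), set_names),
      categories = categories)

    carrier <- stats::runif(n) < ifelse(group == "CASE",
                                        probs[["p_case"]], probs[["p_control"]])
    names(carrier) <- ids
    gene_rows <- stats::setNames(split(genes, genes$gene_id), genes$gene_id)

    cnv_list <- list()
    for (i in seq_len(n)) {
      targets <- character(0)
      if (carrier[i]) targets <- sample(catalog_genes, 1)
      n_bg <- stats::rpois(1, cfg$cnv_rate)
      # every individual has >= 1 genic CNV (the cohort is the genic-CNV subset)
      if (!carrier[i]) n_bg <- max(1L, n_bg)
      if (n_bg > 0) targets <- c(targets, sample(noncat, n_bg, replace = FALSE))
      lens <- .draw_len(length(targets), cfg)
      calls <- do.call(rbind, Map(function(g, l) .place_cnv(gene_rows[[g]], l),
                                  targets, lens))
      calls$sample_id <- ids[i]
      calls$dosage <- sample(c("DEL", "DUP"), nrow(calls), replace = TRUE)
      cnv_list[[i]] <- calls
    }
    cnvs <- do.call(rbind, cnv_list)
    cnvs <- data.frame(sample_id = cnvs$sample_id, chrom = cnvs$chrom,
                       start = cnvs$start, end = cnvs$end,
                       dosage = factor(cnvs$dosage, levels = c("DEL", "DUP")),
                       length_bp = cnvs$end - cnvs$start,
                       stringsAsFactors = FALSE)
    rownames(cnvs) <- NULL

    out <- list(phenotypes = phenotypes, cnvs = cnvs, genes = genes,
                interactions = interactions, conserved = conserved,
                de_list = de_list, gene_sets = gene_sets,
                catalog_genes = catalog_genes, carrier = carrier,
                config = cfg)
    if (!is.null(dir)) out$paths <- write_study(out, dir)
    out
  })
}

#' Write a generated study to disk in the reader dialects
#' @param study output of [generate_cohort()].
#' @param dir destination directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
         cnvs = file.path(dir, "cnvs.tsv"),
         genes = file.path(dir, "genes.gff3"),
         interactions = file.path(dir, "interactions.tsv"),
         conserved = file.path(dir, "conserved.txt"),
         de_list = file.path(dir, "de_mirnas.tsv"),
         gene_sets = file.path(dir, "gene_sets.gmt"))
  utils::write.table(data.frame(sample = study$phenotypes$sample_id,
                                group = as.character(study$phenotypes$group),
                                sex = as.character(study$phenotypes$sex)),
                     p["phenotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chrom = study$cnvs$chrom, start = study$cnvs$start,
                                end = study$cnvs$end, sample = study$cnvs$sample_id,
                                dosage = as.character(study$cnvs$dosage)),
                     p["cnvs"], sep = "\t", quote = FALSE, row.names = FALSE)
  g <- study$genes
  gff <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s;gene_biotype=%s",
                 g$chrom, g$start + 1L, g$end, g$gene_id, g$symbol, g$biotype)
  writeLines(c("##gff-version 3", gff), p["genes"])
  utils::write.table(study$interactions, p["interactions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(study$conserved, p["conserved"])
  utils::write.table(study$de_list, p["de_list"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(study$gene_sets, p["gene_sets"])
  p
}

#' Draw one carrier 2x2 table from the generator's carrier mechanism
#'
#' The fast path used for calibration studies: binomial carrier counts per
#' group at the probabilities solved from the configured base rate and odds
#' ratio, skipping CNV placement.
#'
#' @param cfg a [generator_config()].
#' @return A [contingency_2x2()].
#' @export
simulate_carrier_table <- function(cfg = generator_config()) {
  probs <- solve_carrier_probs(cfg$base_carrier_rate, cfg$carrier_or)
  a <- stats::rbinom(1, cfg$n_case, probs[["p_case"]])
  c_ <- stats::rbinom(1, cfg$n_control, probs[["p_control"]])
  contingency_2x2(a, cfg$n_case - a, c_, cfg$n_control - c_)
}

#' Minimal deterministic cohort reproducing a given 2x2 carrier table
#'
#' Carriers receive exactly one CNV over a designated catalog gene;
#' non-carriers receive one CNV over a non-catalog gene (so every individual
#' is in the genic-CNV subset).  Running the overlap pipeline on the fixture
#' returns exactly `(a, b, c, d)`.
#'
#' @param a,b,c,d carrier/non-carrier counts by group.
#' @param mirna miRNA name wired to the catalog gene.
#' @return List: `cohort` (with covariates), `cnvs`, `genes`, `catalog`.
#' @export
fixture_from_table <- function(a, b, c, d, mirna = "hsa-miR-sim1-5p") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  ids <- sprintf("S%03d", seq_len(n))
  group <- c(rep("CASE", a + b), rep("CONTROL", c + d))
  cohort <- new_cohort(ids, group, rep(c("FEMALE", "MALE"), length.out = n))
  genes <- data.frame(gene_id = c("GENE0001", "GENE0002"),
                      symbol = c("G1", "G2"),
                      chrom = c("chr1", "chr2"),
                      start = c(1000000L, 1000000L),
                      end = c(1050000L, 1050000L),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  is_carrier <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  target <- ifelse(is_carrier, "GENE0001", "GENE0002")
  gi <- match(target, genes$gene_id)
  cnvs <- data.frame(sample_id = ids, chrom = genes$chrom[gi],
                     start = genes$start[gi], end = genes$start[gi] + 20000L,
                     dosage = factor("DEL", levels = c("DEL", "DUP")),
                     length_bp = 20000L, stringsAsFactors = FALSE)
  if (n == 0) cnvs <- cnvs[0, , drop = FALSE]
  catalog <- structure(list(genes = "GENE0001",
                            gene_to_mirnas = list(GENE0001 = mirna),
                            provenance = list(source = "fixture_from_table")),
                       class = "target_catalog")
  ov <- overlap_genes(cnvs, genes)
  list(cohort = cohort_covariates(cohort, cnvs, ov), cnvs = cnvs,
       genes = genes, catalog = catalog, overlaps = ov)
}

#' Generate labelled interaction rows violating each filter criterion
#'
#' Constructed ground truth for the catalog filters: each row carries a label
#' saying whether its (miRNA, gene) pair should survive
#' [filter_interactions()] and, if not, why.
#'
#' @param n_pass pairs with one low-throughput DOWN human record.
#' @param n_two_high pairs with two distinct high-throughput DOWN human
#'   records (pass).
#' @param n_fail_single_high pairs with only one high-throughput record.
#' @param n_fail_direction pairs whose only record is UP.
#' @param n_fail_species pairs whose records are mouse.
#' @return Data frame of interaction rows with a `label` column
#'   (`pass_low`, `pass_two_high`, `fail_single_high`, `fail_direction`,
#'   `fail_species`).
#' @export
generate_interaction_noise <- function(n_pass = 10, n_two_high = 5,
                                       n_fail_single_high = 5,
                                       n_fail_direction = 5,
                                       n_fail_species = 5) {
  gene_at <- function(i) sprintf("NOISE%04d", i)
  i <- 0
  mk <- function(k, label, method, direction, species, dup_high = FALSE) {
    if (k == 0) return(NULL)
    rows <- lapply(seq_len(k), function(j) {
      i <<- i + 1
      base <- data.frame(mirna = sprintf("hsa-miR-noise%d-5p", i %% 7 + 1),
                         gene_id = gene_at(i), gene_symbol = gene_at(i),
                         species = species, method = method,
                         direction = direction, label = label,
                         stringsAsFactors = FALSE)
      if (dup_high) {
        second <- base; second$method <- "par-clip"
        base <- rbind(base, second)
      }
      base
    })
    do.call(rbind, rows)
  }
  out <- rbind(
    mk(n_pass, "pass_low", "luciferase reporter assay", "DOWN", "human"),
    mk(n_two_high, "pass_two_high", "clip-seq", "DOWN", "human", dup_high = TRUE),
    mk(n_fail_single_high, "fail_single_high", "clip-seq", "DOWN", "human"),
    mk(n_fail_direction, "fail_direction", "luciferase reporter assay", "UP", "human"),
    mk(n_fail_species, "fail_species", "luciferase reporter assay", "DOWN", "mouse"))
  rownames(out) <- NULL
  out
}
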