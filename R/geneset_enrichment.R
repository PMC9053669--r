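#' Self-contained gene-set enrichment
#'
#' For each gene set: compare, between groups, the proportion of individuals
#' with a rare CNV overlapping a catalog gene that also belongs to the set
#' (two-sided Fisher exact test with conditional-MLE OR and exact CI), plus
#' the covariate-adjusted logistic burden model.  BH FDR is applied within
#' each gene-set category.  Sets with no catalog overlap are flagged
#' untestable and excluded from the FDR family.
#'
#' @param cohort a `cnv_cohort` with covariates (see [cohort_covariates()]).
#' @param overlaps an `overlap_matrix`.
#' @param catalog a `target_catalog`.
#' @param sets a `gene_set_collection`.
#' @param adjust fit the logistic model per set (default TRUE).
#' @return Data frame, one row per set: counts, OR, CI, p, FDR, the adjusted
#'   carrier OR/CI/p, and a `testable` flag.
#' @export
self_contained_enrichment <- function(cohort, overlaps, catalog, sets,
                                      adjust = TRUE) {
  rows <- lapply(names(sets$sets), function(nm) {
    members <- sets$sets[[nm]]
    testable <- length(intersect(members, catalog$genes)) > 0
    carr <- carrier_indicator_geneset(overlaps, catalog, members,
                                      cohort$sample_id)
    t <- burden_table(cohort, carr)
    if (testable && (t$a + t$c) > 0) {
      et <- exact_test_2x2(t)
      adj <- if (adjust && t$a + t$c > 0 && t$b + t$d > 0)
        tryCatch(carrier_effect(fit_logistic_burden(cohort, carr)),
                 error = function(e) NULL) else NULL
    } else {
      testable <- FALSE
      et <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = 1)
      adj <- NULL
    }
    data.frame(set = nm, category = unname(sets$category[nm]),
               a = t$a, b = t$b, c = t$c, d = t$d,
               or = et$or, ci_low = et$ci_low, ci_high = et$ci_high, p = et$p,
               adj_or = if (is.null(adj)) NA_real_ else adj$or,
               adj_ci_low = if (is.null(adj)) NA_real_ else adj$ci_low,
               adj_ci_high = if (is.null(adj)) NA_real_ else adj$ci_high,
               adj_p = if (is.null(adj)) NA_real_ else adj$p,
               testable = testable, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (cat in unique(res$category)) {
    i <- which(res$category == cat & res$testable)
    if (length(i)) res$fdr[i] <- bh_fdr(res$p[i])
  }
  res
}

#' Competitive gene-set enrichment against a genome background
#'
#' Genes overlapped by CNVs are divided into four subgroups (case/control x
#' catalog target / non-target); each subgroup is tested for
#' over-representation in each gene set with a one-sided upper-tail
#' hypergeometric test against the protein-coding background.  Genes are
#' counted once per subgroup regardless of how many individuals' CNVs hit
#' them, and a gene overlapped in both groups appears in both groups'
#' subgroups.  Sets are intersected with the background before testing; BH
#' FDR is applied within each (subgroup x category) family.
#'
#' @param overlaps an `overlap_matrix`.
#' @param catalog a `target_catalog`.
#' @param sets a `gene_set_collection`.
#' @param background character vector of protein-coding gene ids (the
#'   background genome).
#' @param cohort a `cnv_cohort` giving each sample's group.
#' @return Data frame, one row per (set, subgroup): the hypergeometric 2x2
#'   partition (a, b, c, d), sample OR, one-sided p, FDR.
#' @export
competitive_enrichment <- function(overlaps, catalog, sets, background, cohort) {
  ov_genes <- unique(overlaps$gene_id)
  if (!all(ov_genes %in% background))
    stop("background does not contain all CNV-overlapped genes")
  if (!all(unlist(sets$sets) %in% background))
    message("gene-set members outside the background are ignored")
  grp <- stats::setNames(as.character(cohort$group), cohort$sample_id)
  ovg <- grp[overlaps$sample_id]
  subgroups <- list(
    CASE_TARGET = intersect(unique(overlaps$gene_id[ovg == "CASE"]), catalog$genes),
    CASE_NONTARGET = setdiff(unique(overlaps$gene_id[ovg == "CASE"]), catalog$genes),
    CONTROL_TARGET = intersect(unique(overlaps$gene_id[ovg == "CONTROL"]), catalog$genes),
    CONTROL_NONTARGET = setdiff(unique(overlaps$gene_id[ovg == "CONTROL"]), catalog$genes))
  N <- length(unique(background))
  rows <- list()
  for (sub in names(subgroups)) {
    sg <- subgroups[[sub]]
    for (nm in names(sets$sets)) {
      set_bg <- intersect(sets$sets[[nm]], background)
      a <- length(intersect(sg, set_bg))
      b <- length(sg) - a
      cc <- length(set_bg) - a
      d <- N - a - b - cc
      # upper-tail hypergeometric: P(X >= a) drawing |sg| genes from N with
      # |set_bg| marked
      p <- stats::phyper(a - 1, length(set_bg), N - length(set_bg), length(sg),
                         lower.tail = FALSE)
      or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
      if (a == 0 && (b == 0 || cc == 0)) or <- NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(set = nm, category = unname(sets$category[nm]),
                   subgroup = sub, a = a, b = b, c = cc, d = d,
                   or = or, p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (key in unique(paste(res$subgroup, res$category))) {
    i <- which(paste(res$subgroup, res$category) == key)
    res$fdr[i] <- bh_fdr(res$p[i])
  }
  res
}

#' Convergence report across the two enrichment approaches
#'
#' Classifies each gene set by whether it reaches significance under the
#' self-contained approach (nominal p), the competitive approach (FDR, any
#' case-target subgroup), both, or neither.
#'
#' @param self_results output of [self_contained_enrichment()].
#' @param competitive_results output of [competitive_enrichment()].
#' @param alpha significance threshold.
#' @param subgroup competitive subgroup to report against (default
#'   `"CASE_TARGET"`).
#' @return Data frame `set`, `self_significant`, `competitive_significant`,
#'   `agreement` in both/self-only/competitive-only/neither.
#' @export
enrichment_report <- function(self_results, competitive_results, alpha = 0.05,
                              subgroup = "CASE_TARGET") {
  if (nrow(self_results) == 0)
    return(data.frame(set = character(0), self_significant = logical(0),
                      competitive_significant = logical(0),
                      agreement = character(0), stringsAsFactors = FALSE))
  comp <- competitive_results[competitive_results$subgroup == subgroup, , drop = FALSE]
  sets <- union(self_results$set, comp$set)
  self_sig <- stats::setNames(rep(FALSE, length(sets)), sets)
  comp_sig <- self_sig
  ok <- self_results$testable & !is.na(self_results$p)
  self_sig[self_results$set[ok]] <- self_results$p[ok] < alpha
  okc <- !is.na(comp$fdr)
  comp_sig[comp$set[okc]] <- comp$fdr[okc] < alpha
  agreement <- ifelse(self_sig & comp_sig, "both",
               ifelse(self_sig, "self-only",
               ifelse(comp_sig, "competitive-only", "neither")))
  data.frame(set = sets, self_significant = unname(self_sig),
             competitive_significant = unname(comp_sig),
             agreement = unname(agreement), stringsAsFactors = FALSE)
}
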