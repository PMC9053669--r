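#' Classify catalog miRNAs by the groups their targets contribute to
#'
#' For every miRNA with >= 1 catalog target gene, counts the individuals per
#' group carrying a CNV over one of its targets, and assigns: BROAD
#' (>= 1 carrier in both groups), EXCLUSIVE_CASE / EXCLUSIVE_CONTROL (carriers
#' in exactly one group), or NONE.
#'
#' @param overlaps an `overlap_matrix`.
#' @param catalog a `target_catalog`.
#' @param cohort a `cnv_cohort`.
#' @return Data frame `mirna`, `n_case`, `n_control`, `category`.
#' @export
classify_mirnas <- function(overlaps, catalog, cohort) {
  mirnas <- catalog_mirnas(catalog)
  case_ids <- cohort$sample_id[cohort$group == "CASE"]
  ctrl_ids <- cohort$sample_id[cohort$group == "CONTROL"]
  # invert gene -> miRNAs once; per-miRNA carrier sets from the overlap rows
  g2m <- catalog$gene_to_mirnas
  ov <- overlaps[overlaps$gene_id %in% names(g2m), , drop = FALSE]
  pair_m <- g2m[ov$gene_id]
  long <- data.frame(sample_id = rep(ov$sample_id, lengths(pair_m)),
                     mirna = unlist(pair_m, use.names = FALSE),
                     stringsAsFactors = FALSE)
  long <- unique(long)
  rows <- lapply(mirnas, function(m) {
    carriers <- long$sample_id[long$mirna == m]
    nc <- sum(case_ids %in% carriers)
    nn <- sum(ctrl_ids %in% carriers)
    category <- if (nc >= 1 && nn >= 1) "BROAD"
                else if (nc >= 1) "EXCLUSIVE_CASE"
                else if (nn >= 1) "EXCLUSIVE_CONTROL"
                else "NONE"
    data.frame(mirna = m, n_case = nc, n_control = nn, category = category,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.attr_test <- function(res, n_case, n_control) {
  tests <- lapply(seq_len(nrow(res)), function(i) {
    t <- contingency_2x2(res$n_case[i], n_case - res$n_case[i],
                         res$n_control[i], n_control - res$n_control[i])
    exact_test_2x2(t)
  })
  res$or <- vapply(tests, function(x) x$or, numeric(1))
  res$ci_low <- vapply(tests, function(x) x$ci_low, numeric(1))
  res$ci_high <- vapply(tests, function(x) x$ci_high, numeric(1))
  res$p <- vapply(tests, function(x) x$p, numeric(1))
  res
}

.attr_order <- function(res) {
  # deterministic reporting: ascending p, then descending OR, then name
  res[order(res$p, -res$or, res$mirna), , drop = FALSE]
}

#' Test broadly targeting miRNAs
#'
#' Two-sided Fisher exact test per BROAD miRNA on carrier counts versus group
#' sizes, with BH FDR across the whole BROAD family (all miRNAs with carriers
#' in both groups, not only the significant ones).
#'
#' @param classified output of [classify_mirnas()].
#' @param cohort a `cnv_cohort`.
#' @return The BROAD rows with `or`, `ci_low`, `ci_high`, `p`, `fdr` and
#'   `fdr_family_size`, ordered by ascending p.
#' @export
test_broad <- function(classified, cohort) {
  res <- classified[classified$category == "BROAD", , drop = FALSE]
  if (nrow(res) == 0) return(cbind(res, or = numeric(0), ci_low = numeric(0),
                                   ci_high = numeric(0), p = numeric(0),
                                   fdr = numeric(0), fdr_family_size = integer(0)))
  res <- .attr_test(res, sum(cohort$group == "CASE"), sum(cohort$group == "CONTROL"))
  res$fdr <- bh_fdr(res$p)
  res$fdr_family_size <- nrow(res)
  r <- .attr_order(res)
  rownames(r) <- NULL
  r
}

#' A-priori minimal carrier count for an exclusively targeting miRNA
#'
#' Smallest k such that a two-sided Fisher test on (k, n_group - k, 0,
#' n_other) falls below `alpha`; this is the count an exclusively targeting
#' miRNA must reach before testing is worthwhile (sub-threshold counts cannot
#' be significant by construction).
#'
#' @param n_group size of the group carrying the signal.
#' @param n_other size of the other group (all non-carriers).
#' @param alpha significance threshold.
#' @return Integer k, or `NA` with a message if no k can reach `alpha`.
#' @export
min_exclusive_count <- function(n_group, n_other, alpha = 0.05) {
  stopifnot(n_group >= 1, n_other >= 1, alpha > 0, alpha < 1)
  for (k in seq_len(n_group)) {
    if (fisher_two_sided(contingency_2x2(k, n_group - k, 0, n_other)) < alpha)
      return(k)
  }
  message("no exclusive count reaches alpha = ", alpha)
  NA_integer_
}

#' Test exclusively targeting miRNAs
#'
#' Only miRNAs meeting the a-priori minimal count for their group are tested
#' (Fisher against zero carriers in the other group); BH FDR is computed
#' within each reported exclusive family (case-exclusive and
#' control-exclusive separately).
#'
#' @param classified output of [classify_mirnas()].
#' @param cohort a `cnv_cohort`.
#' @param alpha threshold used both for the a-priori minimum and reporting.
#' @return Tested exclusive rows with test columns, `fdr` and
#'   `fdr_family_size`, ordered by ascending p.
#' @export
test_exclusive <- function(classified, cohort, alpha = 0.05) {
  n_case <- sum(cohort$group == "CASE")
  n_control <- sum(cohort$group == "CONTROL")
  k_case <- min_exclusive_count(n_case, n_control, alpha)
  k_control <- min_exclusive_count(n_control, n_case, alpha)
  keep <- (classified$category == "EXCLUSIVE_CASE" &
             !is.na(k_case) & classified$n_case >= k_case) |
          (classified$category == "EXCLUSIVE_CONTROL" &
             !is.na(k_control) & classified$n_control >= k_control)
  res <- classified[keep, , drop = FALSE]
  if (nrow(res) == 0) return(cbind(res, or = numeric(0), ci_low = numeric(0),
                                   ci_high = numeric(0), p = numeric(0),
                                   fdr = numeric(0), fdr_family_size = integer(0)))
  res <- .attr_test(res, n_case, n_control)
  res$fdr <- NA_real_
  res$fdr_family_size <- NA_integer_
  for (cat in unique(res$category)) {
    i <- which(res$category == cat)
    res$fdr[i] <- bh_fdr(res$p[i])
    res$fdr_family_size[i] <- length(i)
  }
  r <- .attr_order(res)
  rownames(r) <- NULL
  r
}

#' Burden test for one named miRNA
#'
#' Same machinery as the broadly-targeting test for a single miRNA of
#' interest (no FDR) — e.g. the one miRNA downregulated in all experimental
#' models.
#'
#' @param overlaps an `overlap_matrix`.
#' @param catalog a `target_catalog`.
#' @param cohort a `cnv_cohort`.
#' @param mirna mature miRNA name.
#' @return List with the `contingency_2x2` and the `exact_test_result`.
#' @export
single_mirna_burden <- function(overlaps, catalog, cohort, mirna) {
  carr <- carrier_indicator_mirna(overlaps, catalog, mirna, cohort$sample_id)
  t <- burden_table(cohort, carr)
  list(table = t, test = exact_test_2x2(t))
}
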