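enrich_fixture <- function() {
  # carriers of GENE0001 reproduce the FMRP-style margins 11/100 vs 4/118
  fx <- fixture_from_table(11, 89, 4, 114)
  sets <- gene_set_collection(
    list(fmrp_like = c("GENE0001", "GENE0099"),
         catalog_copy = fx$catalog$genes,
         disjoint = "GENE0500"),
    categories = c(fmrp_like = "neuro-functional",
                   catalog_copy = "neuro-functional",
                   disjoint = "brain expression"))
  list(fx = fx, sets = sets)
}

test_that("self-contained enrichment reproduces set-restricted carrier tests", {
  ef <- enrich_fixture()
  res <- self_contained_enrichment(ef$fx$cohort, ef$fx$overlaps, ef$fx$catalog,
                                   ef$sets, adjust = FALSE)
  fmrp <- res[res$set == "fmrp_like", ]
  expect_equal(c(fmrp$a, fmrp$b, fmrp$c, fmrp$d), c(11, 89, 4, 114))
  expect_equal(round(fmrp$or, 2), 3.50)
  expect_equal(round(fmrp$p, 4), 0.0327)

  # set equal to the catalog reproduces the headline row
  head_row <- res[res$set == "catalog_copy", ]
  expect_equal(c(head_row$a, head_row$c), c(11, 4))

  # zero-overlap set is untestable and outside the FDR family
  dis <- res[res$set == "disjoint", ]
  expect_false(dis$testable)
  expect_true(is.na(dis$fdr))
  fam <- res[res$category == "neuro-functional" & res$testable, ]
  expect_equal(fam$fdr, bh_fdr(fam$p))
})

test_that("set-restricted carrier counts never exceed the all-catalog counts", {
  st <- suppressMessages(generate_cohort(generator_config(
    n_case = 40, n_control = 40, n_genes = 120, seed = 31)))
  ov <- overlap_genes(st$cnvs, st$genes)
  co <- cohort_covariates(st$phenotypes, st$cnvs, ov)
  filt <- filter_interactions(st$interactions)
  catalog <- restrict_to_conserved(filt, st$conserved)
  res <- self_contained_enrichment(co, ov, catalog, st$gene_sets, adjust = FALSE)
  all_t <- burden_table(co, carrier_indicator(ov, catalog, co$sample_id))
  expect_true(all(res$a <= all_t$a))
  expect_true(all(res$c <= all_t$c))
})

test_that("competitive tables partition the background for every result", {
  st <- suppressMessages(generate_cohort(generator_config(
    n_case = 30, n_control = 30, n_genes = 150, seed = 8)))
  ov <- overlap_genes(st$cnvs, st$genes)
  co <- st$phenotypes
  filt <- filter_interactions(st$interactions)
  catalog <- restrict_to_conserved(filt, st$conserved)
  background <- protein_coding(st$genes)$gene_id
  res <- competitive_enrichment(ov, catalog, st$gene_sets, background, co)
  expect_setequal(unique(res$subgroup),
                  c("CASE_TARGET", "CASE_NONTARGET",
                    "CONTROL_TARGET", "CONTROL_NONTARGET"))
  N <- length(background)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$a[i] + res$b[i] + res$c[i] + res$d[i], N)
    set_bg <- intersect(st$gene_sets$sets[[res$set[i]]], background)
    expect_equal(res$a[i] + res$c[i], length(set_bg))
  }
  # FDR families are (subgroup x category)
  for (key in unique(paste(res$subgroup, res$category))) {
    i <- paste(res$subgroup, res$category) == key
    expect_equal(res$fdr[i], bh_fdr(res$p[i]))
  }
})

test_that("competitive p-values match the closed-form hypergeometric tail", {
  # subgroup of 10 genes all inside a 10-gene set, background 1000
  genes <- data.frame(gene_id = sprintf("B%04d", 1:1000),
                      symbol = sprintf("B%04d", 1:1000),
                      chrom = "chr1",
                      start = seq(0L, by = 100000L, length.out = 1000),
                      end = seq(50000L, by = 100000L, length.out = 1000),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  background <- genes$gene_id
  sub_genes <- background[1:10]
  co <- new_cohort_for_test(c("A", "B"))
  co$group <- factor(c("CASE", "CONTROL"), levels = c("CASE", "CONTROL"))
  ov <- structure(data.frame(sample_id = "A", gene_id = sub_genes,
                             dosage = factor("DEL", levels = c("DEL", "DUP")),
                             stringsAsFactors = FALSE),
                  class = c("overlap_matrix", "data.frame"))
  catalog <- structure(list(genes = sub_genes,
                            gene_to_mirnas = stats::setNames(
                              rep(list("hsa-miR-x-5p"), 10), sub_genes),
                            provenance = list()), class = "target_catalog")
  sets <- gene_set_collection(list(hit10 = sub_genes, none = background[900:950]))
  res <- competitive_enrichment(ov, catalog, sets, background, co)
  hit <- res[res$set == "hit10" & res$subgroup == "CASE_TARGET", ]
  expect_equal(hit$p, 1 / choose(1000, 10), tolerance = 1e-12)
  none <- res[res$set == "none" & res$subgroup == "CASE_TARGET", ]
  expect_gt(none$p, 0.4)

  # background smaller than inputs is a hard error
  expect_error(competitive_enrichment(ov, catalog, sets, background[1:5], co),
               "background")
})

test_that("competitive null draws reject at close to the nominal rate", {
  set.seed(77)
  N <- 2000; K <- 200; n_draw <- 60; reps <- 600
  rej <- 0
  for (r in seq_len(reps)) {
    a <- sum(sample.int(N, n_draw) <= K)
    p <- stats::phyper(a - 1, K, N - K, n_draw, lower.tail = FALSE)
    if (p <= 0.05) rej <- rej + 1
  }
  mc_margin <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lte(rej / reps, 0.05 + mc_margin)
})

test_that("convergence report classifies agreement between approaches", {
  self_res <- data.frame(set = c("s1", "s2", "s3", "s4"),
                         p = c(0.01, 0.2, 0.01, 0.6),
                         testable = TRUE, stringsAsFactors = FALSE)
  comp_res <- data.frame(set = c("s1", "s2", "s3", "s4"),
                         subgroup = "CASE_TARGET",
                         fdr = c(0.01, 0.01, 0.9, 0.9),
                         stringsAsFactors = FALSE)
  rep_ <- enrichment_report(self_res, comp_res)
  expect_equal(rep_$agreement[match(c("s1", "s2", "s3", "s4"), rep_$set)],
               c("both", "competitive-only", "self-only", "neither"))
  expect_equal(nrow(enrichment_report(self_res[0, ], comp_res[0, ])), 0)
})
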