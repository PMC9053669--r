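test_that("interaction filter enforces the evidence, direction and species rules", {
  rec <- function(mirna, gene, method, direction, species)
    data.frame(mirna = mirna, gene_id = gene, gene_symbol = gene,
               species = species, method = method, direction = direction,
               stringsAsFactors = FALSE)
  records <- rbind(
    rec("hsa-miR-1-5p", "G1", "luciferase reporter assay", "DOWN", "human"),
    rec("hsa-miR-1-5p", "G2", "clip-seq", "DOWN", "human"),        # 1 HIGH: out
    rec("hsa-miR-1-5p", "G3", "clip-seq", "DOWN", "human"),        # 2 distinct HIGH
    rec("hsa-miR-1-5p", "G3", "par-clip", "DOWN", "human"),
    rec("hsa-miR-1-5p", "G4", "clip-seq", "DOWN", "human"),        # same method x2
    rec("hsa-miR-1-5p", "G4", "clip-seq", "DOWN", "human"),
    rec("hsa-miR-1-5p", "G5", "luciferase reporter assay", "UP", "human"),
    rec("hsa-miR-1-5p", "G6", "clip-seq", "DOWN", "mouse"),
    rec("hsa-miR-1-5p", "G6", "par-clip", "DOWN", "mouse"),
    rec("hsa-miR-1-5p", "G7", "crystal ball", "DOWN", "human"))
  expect_message(f <- filter_interactions(records), "unclassified")
  got <- sort(unique(f$pairs$gene_id))
  expect_equal(got, c("G1", "G3"))
  expect_equal(f$unclassified_methods, "crystal ball")
  expect_equal(f$provenance$n_pairs_out, 2)
})

test_that("labelled noise fixtures are filtered exactly as constructed", {
  noise <- generate_interaction_noise(n_pass = 10, n_two_high = 5,
                                      n_fail_single_high = 6,
                                      n_fail_direction = 40, n_fail_species = 7)
  f <- filter_interactions(noise[, setdiff(names(noise), "label")])
  should_pass <- unique(noise$gene_id[grepl("^pass", noise$label)])
  expect_setequal(unique(f$pairs$gene_id), should_pass)
  expect_equal(f$provenance$n_records_not_down, 40)
  expect_equal(f$provenance$n_records_nonhuman, 7)
  expect_equal(f$provenance$n_pairs_insufficient_evidence, 6)
})

test_that("monotone filtering: provenance telescopes and catalogs nest", {
  noise <- generate_interaction_noise()
  f <- filter_interactions(noise[, setdiff(names(noise), "label")])
  all_genes <- unique(f$pairs$gene_id)
  conserved <- all_genes[seq_len(ceiling(length(all_genes) / 2))]
  cat_full <- restrict_to_conserved(f, c(all_genes, "EXTRA1"))
  cat_cons <- restrict_to_conserved(f, conserved)
  expect_setequal(cat_full$genes, all_genes)           # superset case: identity
  expect_true(all(cat_cons$genes %in% cat_full$genes)) # restriction nests
  expect_true(all(cat_cons$genes %in% conserved))
  expect_equal(cat_cons$provenance$n_genes_catalog, length(cat_cons$genes))

  # disjoint conserved list -> warning + valid empty catalog
  expect_warning(cat0 <- restrict_to_conserved(f, "NOTHING"), "empty")
  expect_length(cat0$genes, 0)

  # every catalog gene keeps >= 1 supporting miRNA
  expect_true(all(lengths(cat_full$gene_to_mirnas[cat_full$genes]) >= 1))
})

test_that("nomenclature harmonisation retains one-to-many maps and reports misses", {
  ref <- mirna_reference(data.frame(
    name = c("hsa-miR-17-5p", "hsa-miR-17-3p", "hsa-miR-185-5p"),
    accession = c("MIMAT0000070", "MIMAT0000071", "MIMAT0000455"),
    sequence = c("CAAAGUGCUUACAGUGCAGGUAG", "ACUGCAGUGAAGGCACUUGUAG",
                 "UGGAGAGAAAGGCAGUUCCUGA"),
    stringsAsFactors = FALSE))
  alias <- data.frame(old_name = c("miR-17", "miR-17"),
                      new_name = c("hsa-miR-17-5p", "hsa-miR-17-3p"),
                      stringsAsFactors = FALSE)
  expect_message(
    h <- harmonize_names(c("miR-17", "hsa-miR-185-5p", "HSA-MIR-185-5P",
                           "miR-notreal"), ref, alias),
    "miR-notreal")
  expect_setequal(h$map[["miR-17"]], c("hsa-miR-17-5p", "hsa-miR-17-3p"))
  expect_equal(h$map[["hsa-miR-185-5p"]], "hsa-miR-185-5p")
  expect_equal(h$map[["HSA-MIR-185-5P"]], "hsa-miR-185-5p")  # case-insensitive
  expect_equal(h$unmapped, "miR-notreal")
})

test_that("seed extraction and the mouse-to-human seed filter", {
  ref <- mirna_reference(data.frame(
    name = c("hsa-miR-9-5p", "mmu-miR-9-5p", "hsa-miR-7-5p", "mmu-miR-7-5p",
             "mmu-miR-99-3p"),
    accession = paste0("ACC", 1:5),
    sequence = c("UAGCUUAUCAGACUGAUGUUGA",  # seed AGCUUA
                 "UAGCUUAUCAGACUGAUGUUGA",
                 "UGGAAGACUAGUGAUUUUGUUGU",
                 "UCGAAGACUAGUGAUUUUGUUGU",  # seed differs at one position
                 "AAAAAAAAAA"),
    stringsAsFactors = FALSE))
  expect_equal(ref$seed6[ref$name == "hsa-miR-9-5p"], "AGCUUA")
  expect_equal(ref$arm, rep(c("FIVE_P"), 4) |> c("THREE_P"))
  # seed6 is recomputable from the stored sequence for every record
  expect_identical(ref$seed6, substr(toupper(ref$sequence), 2, 7))

  expect_message(
    kept <- seed_filter_mouse(c("mmu-miR-9-5p", "mmu-miR-7-5p", "mmu-miR-99-3p"),
                              ref),
    "no human counterpart")
  expect_equal(as.character(kept), "hsa-miR-9-5p")
  expect_equal(attr(kept, "excluded_seed_mismatch"), "mmu-miR-7-5p")
  expect_equal(attr(kept, "excluded_no_counterpart"), "mmu-miR-99-3p")
})

test_that("differential-expression subcatalog is an exact membership restriction", {
  g2m <- list(G1 = c("hsa-miR-1-5p"), G2 = c("hsa-miR-2-5p"),
              G3 = c("hsa-miR-1-5p", "hsa-miR-3-5p"))
  catalog <- structure(list(genes = c("G1", "G2", "G3"), gene_to_mirnas = g2m,
                            provenance = list()), class = "target_catalog")
  sub <- build_de_subcatalog(catalog, c("hsa-miR-1-5p"))
  expect_setequal(sub$genes, c("G1", "G3"))
  expect_true(all(sub$genes %in% catalog$genes))
  expect_setequal(build_de_subcatalog(catalog, catalog_mirnas(catalog))$genes,
                  catalog$genes)                         # full cover: identity
  expect_length(build_de_subcatalog(catalog, "hsa-miR-none")$genes, 0)

  # brute-force membership check on a synthetic catalog
  set.seed(9)
  genes <- sprintf("G%02d", 1:20)
  mirnas <- sprintf("hsa-miR-%d-5p", 1:6)
  g2m <- lapply(genes, function(g) sample(mirnas, sample(1:3, 1)))
  names(g2m) <- genes
  cat2 <- structure(list(genes = genes, gene_to_mirnas = g2m,
                         provenance = list()), class = "target_catalog")
  de <- mirnas[1:2]
  expected <- genes[vapply(g2m, function(m) any(m %in% de), logical(1))]
  expect_setequal(build_de_subcatalog(cat2, de)$genes, expected)
})

test_that("study convergence counts studies, directions and discordance", {
  de <- data.frame(
    mirna = c(rep("hsa-miR-185-5p", 5), "hsa-miR-17-5p", "hsa-miR-22-3p",
              "hsa-miR-22-3p"),
    study = c(paste0("study", 1:5), "study1", "study1", "study2"),
    direction = c(rep("DOWN", 5), "UP", "UP", "DOWN"),
    stringsAsFactors = FALSE)
  sc <- study_convergence(de)
  m185 <- sc$per_mirna[sc$per_mirna$mirna == "hsa-miR-185-5p", ]
  expect_equal(m185$n_studies, 5)
  expect_equal(m185$direction, "DOWN")
  expect_equal(sc$per_mirna$n_studies[sc$per_mirna$mirna == "hsa-miR-17-5p"], 1)
  expect_equal(sc$per_mirna$direction[sc$per_mirna$mirna == "hsa-miR-22-3p"],
               "discordant")
  expect_equal(sc$overall$n_single_study, 1)
})
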