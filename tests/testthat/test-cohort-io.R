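make_pheno_file <- function(n_case = 3, n_control = 4) {
  df <- data.frame(
    sample = sprintf("S%02d", seq_len(n_case + n_control)),
    group = c(rep("schizophrenia", n_case), rep("non-psychotic", n_control)),
    sex = rep(c("F", "M"), length.out = n_case + n_control))
  write_tsv_fixture(df, name = paste0("pheno", n_case, n_control, ".tsv"))
}

test_that("phenotype reader maps vocabularies and enforces invariants", {
  path <- make_pheno_file(3, 4)
  co <- suppressMessages(read_phenotypes(path))
  expect_s3_class(co, "cnv_cohort")
  expect_equal(as.vector(table(co$group)), c(3, 4))
  expect_equal(sum(as.vector(table(co$group))), nrow(co))
  expect_setequal(levels(co$sex), c("FEMALE", "MALE"))

  # header-only file -> empty cohort with a warning
  empty <- write_tsv_fixture(data.frame(sample = character(0),
                                        group = character(0),
                                        sex = character(0)),
                             name = "empty.tsv")
  expect_warning(co0 <- read_phenotypes(empty), "no rows")
  expect_equal(nrow(co0), 0)

  dup <- write_tsv_fixture(data.frame(sample = c("A", "A"),
                                      group = c("CASE", "CONTROL"),
                                      sex = c("F", "M")), name = "dup.tsv")
  expect_error(read_phenotypes(dup), "A")

  badtok <- write_tsv_fixture(data.frame(sample = "A", group = "maybe", sex = "F"),
                              name = "badtok.tsv")
  expect_error(read_phenotypes(badtok), "maybe")

  nosex <- write_tsv_fixture(data.frame(sample = "A", group = "CASE", sex = ""),
                             name = "nosex.tsv")
  expect_error(read_phenotypes(nosex), "sex")
})

test_that("CNV reader normalises coordinates and filters by length and rarity", {
  df <- data.frame(chrom = c("chr1", "chr1", "chr2", "chrX"),
                   start = c(1000, 1001, 5000, 100),
                   end = c(21000, 21000, 14999, 30000),
                   sample = "S01",
                   dosage = c("DEL", "loss", "gain", "DUP"))
  p0 <- write_tsv_fixture(df, name = "cnv0.tsv")
  expect_warning(
    got <- suppressMessages(read_cnvs(p0, min_len_bp = 10000)),
    "non-autosomal")
  # chr2 call is 9999 bp -> filtered; chrX dropped; both chr1 calls kept
  expect_equal(nrow(got), 2)
  expect_equal(got$length_bp, c(20000, 19999))
  expect_equal(as.character(got$dosage), c("DEL", "DEL"))

  one_based <- write_tsv_fixture(
    data.frame(chrom = "chr1", start = 1001, end = 21000,
               sample = "S01", dosage = "DEL"), name = "cnv1.tsv")
  got1 <- suppressMessages(read_cnvs(one_based,
                                     coordinate_dialect = "ONE_BASED_INCLUSIVE"))
  expect_equal(got1$start, 1000)
  expect_equal(got1$end, 21000)

  bad <- write_tsv_fixture(
    data.frame(chrom = "chr1", start = 21000, end = 1000,
               sample = "S01", dosage = "DEL"), name = "cnvbad.tsv")
  expect_error(read_cnvs(bad), "start >= end")

  freq <- write_tsv_fixture(
    data.frame(chrom = "chr1", start = c(0, 0), end = c(20000, 20000),
               sample = c("S01", "S02"), dosage = "DEL",
               control_freq = c(0.0005, 0.01)), name = "cnvfreq.tsv")
  gotf <- suppressMessages(read_cnvs(freq))
  expect_equal(gotf$sample_id, "S01")

  pheno <- suppressMessages(read_phenotypes(make_pheno_file()))
  unknown <- write_tsv_fixture(
    data.frame(chrom = "chr1", start = 0, end = 20000,
               sample = "NOPE", dosage = "DEL"), name = "cnvunk.tsv")
  expect_error(read_cnvs(unknown, phenotypes = pheno), "NOPE")
})

test_that("normalised CNV tables round-trip bit-exactly", {
  st <- suppressMessages(generate_cohort(generator_config(
    n_case = 8, n_control = 8, n_genes = 40, seed = 5)))
  path <- file.path(tempdir(), "roundtrip.tsv")
  write_cnvs(st$cnvs, path)
  back <- suppressMessages(read_cnvs(path))
  ord <- function(d) {
    d <- d[order(d$sample_id, d$chrom, d$start, d$end), c(
      "sample_id", "chrom", "start", "end", "length_bp")]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(back), ord(st$cnvs))
})

test_that("gene annotation readers honour conventions and union spans", {
  gff <- file.path(tempdir(), "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t5000\t8000\t.\t+\t.\tID=GA;Name=GA;gene_biotype=protein_coding",
    "chr1\tsrc\tgene\t9000\t9500\t.\t+\t.\tID=GB;Name=GB;gene_biotype=lincRNA",
    "chr2\tsrc\tgene\t100\t200\t.\t+\t.\tID=GC;Name=GC;gene_biotype=protein_coding",
    "chr2\tsrc\tgene\t150\t400\t.\t+\t.\tID=GC;Name=GC;gene_biotype=protein_coding"),
    gff)
  ann <- suppressMessages(read_gene_annotation(gff))
  ga <- ann[ann$gene_id == "GA", ]
  expect_equal(c(ga$start, ga$end), c(4999, 8000))  # 1-based -> half-open
  gc_ <- ann[ann$gene_id == "GC", ]
  expect_equal(c(gc_$start, gc_$end), c(99, 400))   # union of two features
  expect_false("GB" %in% protein_coding(ann)$gene_id)
  expect_true("GB" %in% ann$gene_id)                # retained, flagged excluded

  bed <- file.path(tempdir(), "ann.bed")
  writeLines("chr1\t100\t500\tGX", bed)
  annb <- read_gene_annotation(bed, format = "BED")
  expect_equal(annb$biotype, "protein_coding")
  expect_equal(c(annb$start, annb$end), c(100, 500))
})

test_that("GMT reading keeps shared members, flags empties, rejects collisions", {
  gmt <- file.path(tempdir(), "sets.gmt")
  writeLines(c("setA\tdesc\tG1\tG2",
               "setB\tdesc\tG2\tG3",
               "setC\tdesc"), gmt)
  expect_message(sc <- read_gene_sets(gmt, categories = c(setA = "neuro-functional")),
                 "empty")
  expect_true("G2" %in% sc$sets$setA && "G2" %in% sc$sets$setB)
  expect_equal(unname(sc$category["setA"]), "neuro-functional")
  expect_equal(unname(sc$category["setB"]), "uncategorized")

  gmt2 <- file.path(tempdir(), "sets2.gmt")
  writeLines(c("setA\td\tG1", "setA\td\tG2"), gmt2)
  expect_error(read_gene_sets(gmt2), "duplicated")
})
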