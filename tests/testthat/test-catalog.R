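test_that("TSV round-trip ingests well-formed rows and sorts genome-wide", {
  build <- toy_build()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    chrom = c("X", "I", "I"),
    pos_bp = c(5e6, 2e6, 1e6),
    size_change_bp = c(50L, 100L, 700L),
    isolates = c("A", "A;B", "B")
  ), path)
  cat <- read_indel_tsv(path, build)
  expect_equal(nrow(cat), 3)
  expect_equal(cat$variant_id, c("v3", "v2", "v1"))  # I:1e6, I:2e6, X:5e6
  expect_equal(cat$n_isolates, c(1L, 2L, 1L))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_indel_tsv(cat, out)
  expect_equal(read_indel_tsv(out, build)$pos_bp, cat$pos_bp)
})

test_that("VCF ingestion computes |len(ref) - len(alt)| and carrier sets", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tCB4856\tJU258",
    "I\t100\tid1\tACGT\tA\t.\tPASS\t.\tGT\t1/1\t0/0",
    "I\t500\tid2\tA\tACCCCGGGGTTTTAAAACCCCGGGGTTTTAAAACCCCGGGGTTTT\t.\tPASS\t.\tGT\t1/1\t1/1"
  ), path)
  skip_if_not_installed("vcfR")
  cat <- read_indel_vcf(path, toy_build())
  expect_equal(cat$size_change_bp, c(3L, 44L))
  expect_equal(cat$isolates, c("CB4856", "CB4856;JU258"))
  expect_equal(cat$longer_allele, c("N2", "isolate"))
})

test_that("rows on unknown chromosomes are rejected with a warning", {
  df <- tibble::tibble(variant_id = "v1", chrom = "VII", pos_bp = 1e6,
                       size_change_bp = 100L)
  expect_warning(cat <- as_indel_catalog(df, toy_build()), "VII")
  expect_equal(nrow(cat), 0)
})

test_that("malformed positions are rejected naming the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tchrom\tpos_bp\tsize_change_bp",
               "v1\tI\t100\t50",
               "v2\tI\tnot_a_number\t60"), path)
  expect_error(suppressWarnings(read_indel_tsv(path, toy_build())), "line 3")
})

test_that("size filter keeps the closed [40, 699] range and is idempotent", {
  cat <- toy_catalog(tibble::tibble(
    chrom = "I", pos_bp = c(1e6, 2e6, 3e6, 4e6),
    size_change_bp = c(39L, 40L, 699L, 700L)
  ))
  f <- filter_i40_699(cat)
  expect_setequal(f$size_change_bp, c(40L, 699L))
  expect_identical(filter_i40_699(f)$variant_id, f$variant_id)
  expect_true(all(f$variant_id %in% cat$variant_id))
  expect_error(filter_i40_699(cat, min_bp = 100, max_bp = 50), "min_bp")
})

test_that("nearest-gene annotation picks minimum distance, ties to lower coordinate", {
  cat <- toy_catalog(tibble::tibble(chrom = "I", pos_bp = 1e6,
                                    size_change_bp = 100L))
  genes <- tibble::tibble(gene_id = c("far", "near"), chrom = "I",
                          pos_bp = c(1.2e6, 0.9e6))
  expect_equal(annotate_nearest_gene(cat, genes)$gene_id, "near")
  tie <- tibble::tibble(gene_id = c("hi", "lo"), chrom = "I",
                        pos_bp = c(1.01e6, 0.99e6))
  expect_equal(annotate_nearest_gene(cat, tie)$gene_id, "lo")
})

test_that("nearest-gene annotation matches the exhaustive pairwise scan", {
  withr::local_seed(11)
  build <- toy_build()
  vars <- toy_catalog(tibble::tibble(
    chrom = sample(c("I", "X"), 200, replace = TRUE),
    pos_bp = sample.int(8e6, 200), size_change_bp = 100L
  ), build)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:50),
    chrom = sample(c("I", "X"), 50, replace = TRUE),
    pos_bp = sample.int(8e6, 50)
  )
  ann <- annotate_nearest_gene(vars, genes)
  expect_equal(ann$gene_id, oracle_nearest_gene(ann, genes))
})

test_that("variants on a gene-less chromosome are left unannotated with a warning", {
  cat <- toy_catalog(tibble::tibble(chrom = c("I", "X"), pos_bp = c(1e6, 1e6),
                                    size_change_bp = 100L))
  genes <- tibble::tibble(gene_id = "g1", chrom = "I", pos_bp = 2e6)
  expect_warning(ann <- annotate_nearest_gene(cat, genes), "X")
  expect_true(is.na(ann$gene_id[as.character(ann$chrom) == "X"]))
})

test_that("presence summary counts carriers and unique carriers", {
  cat <- toy_catalog(tibble::tibble(
    chrom = "I", pos_bp = c(1e6, 2e6, 3e6), size_change_bp = 100L,
    isolates = c("A", "A;B", "B")
  ))
  ps <- presence_summary(cat)
  expect_equal(ps$n_indels[ps$isolate == "A"], 2L)
  expect_equal(ps$n_unique[ps$isolate == "A"], 1L)
  expect_equal(ps$n_indels[ps$isolate == "B"], 2L)
  expect_equal(ps$n_unique[ps$isolate == "B"], 1L)
  # single-carrier catalogs: every indel is unique to its carrier
  solo <- toy_catalog(tibble::tibble(chrom = "I", pos_bp = c(1e6, 2e6),
                                     size_change_bp = 100L,
                                     isolates = c("A", "B")))
  pss <- presence_summary(solo)
  expect_equal(pss$n_unique, pss$n_indels)
  # sum of unique counts can never exceed the catalog size
  expect_lte(sum(ps$n_unique), nrow(cat))
})
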