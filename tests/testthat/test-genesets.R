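test_that("catalog gene-set selection is trait-insensitive and boundary-inclusive", {
  rec <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                    trait = c("Multiple Sclerosis", "multiple sclerosis",
                              "multiple sclerosis", "stroke"),
                    assoc_p = c(5e-6, 6e-6, 1e-9, 1e-9),
                    stringsAsFactors = FALSE)
  rec$mapped_genes <- list("A", "B", c("C", "D"), "E")
  gs <- build_gwas_geneset(rec, "multiple sclerosis")
  expect_setequal(gs$symbols, c("A", "C", "D"))
  expect_identical(attr(gs, "n_snps"), 2L)
  expect_warning(build_gwas_geneset(rec, "lupus"), "no catalog SNPs")
})

test_that("simulated catalog reproduces the planted 805 SNP / 543 gene set", {
  cfg <- sim_config(seed = 21L)
  sim <- simulate_gwas_catalog(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gs <- build_gwas_geneset(read_gwas_catalog(path), "multiple sclerosis")
  expect_identical(attr(gs, "n_snps"), 805L)
  expect_identical(length(gs$symbols), 543L)
  expect_setequal(gs$symbols, sim$truth)
})

test_that("intersection is commutative, idempotent and bounded", {
  a <- gene_set("a", c("A", "B", "C"))
  b <- gene_set("b", c("B", "C", "D"))
  ab <- geneset_intersect(a, b)
  expect_setequal(ab$symbols, c("B", "C"))
  expect_setequal(geneset_intersect(b, a)$symbols, ab$symbols)
  expect_setequal(geneset_intersect(a, a)$symbols, a$symbols)
  expect_length(geneset_intersect(a, gene_set("d", "Z"))$symbols, 0L)
  expect_lte(length(ab), min(length(a), length(b)))
})

test_that("planted overlap between catalog and DE sets is recovered exactly", {
  set.seed(8)
  overlap <- sprintf("OV%02d", 1:18)
  gwas <- gene_set("gwas", c(overlap, sprintf("CAT%03d", 1:525)))
  de <- gene_set("de", c(overlap, sprintf("DE%03d", 1:905)))
  expect_setequal(geneset_intersect(gwas, de)$symbols, overlap)
  expect_length(geneset_intersect(gwas, de), 18L)
})

test_that("coding/ncRNA partition is exact and total", {
  s <- gene_set("s", sprintf("X%02d", 1:18))
  cmap <- setNames(c(rep("coding", 16L), rep("ncRNA", 2L)), s$symbols)
  parts <- partition_by_class(s, cmap)
  expect_length(parts$coding, 16L)
  expect_length(parts$ncRNA, 2L)
  expect_setequal(c(parts$coding$symbols, parts$ncRNA$symbols), s$symbols)
  expect_error(partition_by_class(s, cmap[-1L]), "X01",
               class = "varfunnel_validation_error")
  empty <- partition_by_class(gene_set("e", character()), c(A = "coding"))
  expect_length(empty$coding, 0L)
  expect_length(empty$ncRNA, 0L)
  # partition sizes always sum to the set size
  set.seed(12)
  for (rep in 1:5) {
    syms <- sprintf("R%03d", sample.int(500L, 40L))
    s2 <- gene_set("r", syms)
    cm <- setNames(sample(c("coding", "ncRNA"), length(s2$symbols), TRUE),
                   s2$symbols)
    pp <- partition_by_class(s2, cm)
    expect_identical(length(pp$coding) + length(pp$ncRNA), length(s2))
  }
})

test_that("gene sets round-trip through their text serialization", {
  s <- gene_set("my set", c("B", "A"), provenance = "somewhere, filtered")
  path <- withr::local_tempfile(fileext = ".txt")
  write_geneset(s, path)
  back <- read_geneset(path)
  expect_identical(back$symbols, s$symbols)
  expect_identical(back$name, s$name)
  expect_identical(back$provenance, s$provenance)
})
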