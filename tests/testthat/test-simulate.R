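test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 6L, n_genes = 500L, n_de = 30L,
                    catalog_snps = 60L, catalog_genes = 40L,
                    catalog_decoys = 20L,
                    n_planted_segregating = 4L, n_background_variants = 20L)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  fa <- simulate_families(cfg)
  fb <- simulate_families(cfg)
  expect_identical(fa$vt$geno, fb$vt$geno)
  qa <- simulate_frequencies(cfg)
  qb <- simulate_frequencies(cfg)
  expect_identical(qa$pf, qb$pf)
  ta <- simulate_transcripts(cfg, gene_ids = c("X1", "X2"))
  tb <- simulate_transcripts(cfg, gene_ids = c("X1", "X2"))
  expect_identical(ta$X1$sequence, tb$X1$sequence)
  expect_identical(ta$X2$exons, tb$X2$exons)
})

test_that("planted differential expression is recovered by the DE stage", {
  cfg <- sim_config(seed = 19L, n_genes = 4000L, n_de = 180L,
                    catalog_genes = 100L, catalog_snps = 150L)
  sim <- simulate_expression(cfg)
  res <- moderated_t(sim$matrix)
  hits <- select_de(res)
  truth <- sim$truth$gene[sim$truth$effect != 0]
  # every planted gene is recovered; false discoveries stay within the
  # FDR-controlled trickle the selection rule permits
  expect_length(setdiff(truth, hits), 0L)
  expect_lte(length(setdiff(hits, truth)),
             ceiling(0.01 * (4000L - length(truth))))
})

test_that("a null expression simulation yields almost no selections", {
  sizes <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_genes = 1500L, n_de = 0L,
                      catalog_genes = 100L, catalog_snps = 150L)
    sim <- simulate_expression(cfg)
    length(select_de(moderated_t(sim$matrix)))
  }, numeric(1L))
  expect_lte(mean(sizes), 0.05 * 1500L)
  expect_lte(max(sizes), 5L)
})

test_that("family genotypes are Mendelian-consistent for every variant", {
  cfg <- sim_config(seed = 27L, n_planted_segregating = 8L,
                    n_background_variants = 60L)
  sim <- simulate_families(cfg)
  ped <- sim$ped
  for (i in seq_len(n_variants(sim$vt))) {
    g <- sim$vt$geno[i, ]
    for (j in which(!is_founder(ped))) {
      child <- g[ped$individual_id[j]]
      dad <- g[ped$father_id[j]]
      mum <- g[ped$mother_id[j]]
      if (anyNA(c(child, dad, mum))) next
      # a child allele count must be attainable from one allele per parent
      from_dad <- unique(c(if (dad >= 1L) 1L, if (dad <= 1L) 0L))
      from_mum <- unique(c(if (mum >= 1L) 1L, if (mum <= 1L) 0L))
      expect_true(child %in% outer(from_dad, from_mum, "+"),
                  info = sprintf("variant %d child %s", i,
                                 ped$individual_id[j]))
    }
  }
})

test_that("zero planted variants leaves the transmission filter empty", {
  cfg <- sim_config(seed = 2L, n_planted_segregating = 0L,
                    n_background_variants = 50L)
  sim <- simulate_families(cfg)
  out <- transmission_filter(sim$vt, sim$ped)
  expect_identical(n_variants(out$variants), 0L)
})

test_that("simulated allele counts respect their allele numbers", {
  sim <- simulate_frequencies(sim_config(seed = 15L))
  expect_true(all(sim$pf$allele_count <= sim$pf$allele_number))
  expect_true(all(sim$pf$allele_count >= 0))
  expect_setequal(unique(sim$pf$population),
                  c("affected", "control_tsi", "control_nfe"))
})

test_that("a simulated study writes mutually consistent inputs", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 33L, n_genes = 1200L, n_de = 40L,
                    catalog_genes = 60L, catalog_snps = 90L,
                    catalog_decoys = 30L,
                    msgwas_intronic = 10L, msgwas_common_nonintronic = 4L,
                    msgwas_lowfreq_nonintronic = 3L,
                    partner_intronic = 5L, partner_nonintronic = 4L,
                    n_assoc_msgwas = 1L, n_assoc_partner = 1L,
                    n_background_variants = 40L)
  sim <- simulate_study(cfg, dir)
  # the files parse back into the in-memory objects
  ped <- read_ped(sim$paths$ped)
  expect_identical(ped, sim$ped)
  vt <- read_vcf(sim$paths$vcf, ped = ped)
  expect_identical(vt$variants$key, sim$vt$variants$key)
  expect_identical(vt$geno, sim$vt$geno)
  em <- read_expression(sim$paths$expression)
  expect_equal(em$values, sim$expression$values, tolerance = 1e-10)
  models <- read_transcripts(sim$paths$transcripts_tsv,
                             sim$paths$transcripts_fasta)
  expect_identical(names(models), names(sim$models))
  pf <- read_frequencies(sim$paths$frequencies)
  expect_identical(pf$allele_count, sim$pf$allele_count)
  # every planned variant's VCF ref allele matches its transcript model
  ann <- annotate_consequences(vt_subset(vt, sim$plan$key), models)
  expect_identical(ann$class, sim$plan$class)
})
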