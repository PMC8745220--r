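test_that("canonical dominant transmission verdicts", {
  fam <- quad_family()
  rule <- transmission_rule()
  # affected parent and child both carry, unaffected sibs do not -> pass
  expect_identical(
    evaluate_family(c(dad = 1L, mum = 0L, kid1 = 1L, kid2 = 0L), fam,
                    rule)$verdict, "pass")
  # affected child does not carry -> fail
  res <- evaluate_family(c(dad = 1L, mum = 0L, kid1 = 0L, kid2 = 0L), fam,
                         rule)
  expect_identical(res$verdict, "fail")
  expect_identical(res$reason, "affected_noncarrier")
  # carriers but no affected parent-child pair (only the child carries... )
  res2 <- evaluate_family(c(dad = 1L, mum = 0L, kid1 = 1L, kid2 = 0L), fam,
                          transmission_rule(require_all_affected_carriers = FALSE))
  expect_identical(res2$verdict, "pass")
  # a family with no affected members is not evaluable
  fam_none <- pedigree("N", c("a", "b"), affection = "unaffected")
  expect_identical(evaluate_family(c(a = 1L, b = 1L), fam_none,
                                   rule)$verdict, "not_evaluable")
})

test_that("verdicts match exhaustive brute-force enumeration on a quad family", {
  fam <- quad_family()
  states <- list(0L, 1L, 2L, NA_integer_)
  grid <- expand.grid(dad = states, mum = states, kid1 = states,
                      kid2 = states)
  rules <- list(
    transmission_rule(),
    transmission_rule(exclude_if_unaffected_carrier = TRUE),
    transmission_rule(missing_policy = "treat_as_noncarrier"),
    transmission_rule(require_parent_child_transmission = FALSE),
    transmission_rule(require_all_affected_carriers = FALSE,
                      exclude_if_unaffected_carrier = TRUE)
  )
  for (rule in rules) {
    for (i in seq_len(nrow(grid))) {
      g <- unlist(grid[i, ])
      expect_identical(evaluate_family(g, fam, rule)$verdict,
                       oracle_family_verdict(g, fam, rule),
                       info = sprintf("genotypes [%s]",
                                      paste(g, collapse = ",")))
    }
  }
})

test_that("missing genotypes follow the per-status policy", {
  fam <- quad_family()
  g <- c(dad = 1L, mum = NA_integer_, kid1 = 1L, kid2 = NA_integer_)
  # missing calls in unaffected members never fail the family
  expect_identical(evaluate_family(g, fam, transmission_rule())$verdict,
                   "pass")
  g2 <- c(dad = 1L, mum = 0L, kid1 = NA_integer_, kid2 = 0L)
  expect_identical(evaluate_family(g2, fam, transmission_rule())$reason,
                   "missing_affected_genotype")
  expect_identical(
    evaluate_family(g2, fam,
                    transmission_rule(missing_policy = "treat_as_noncarrier")
                    )$reason, "affected_noncarrier")
})

test_that("transmission filter retains exactly the planted variants", {
  cfg <- sim_config(seed = 4L, n_planted_segregating = 10L,
                    n_background_variants = 120L)
  sim <- simulate_families(cfg)
  out <- transmission_filter(sim$vt, sim$ped)
  expect_setequal(out$variants$variants$key,
                  sim$truth$key[sim$truth$planted])
  expect_identical(nrow(out$report),
                   n_variants(sim$vt) * 3L)
})

test_that("filtering is order-independent and empty input is handled", {
  cfg <- sim_config(seed = 9L, n_planted_segregating = 5L,
                    n_background_variants = 40L)
  sim <- simulate_families(cfg)
  out1 <- transmission_filter(sim$vt, sim$ped)
  set.seed(1)
  perm <- sample.int(n_variants(sim$vt))
  out2 <- transmission_filter(vt_subset(sim$vt, perm), sim$ped)
  expect_setequal(out1$variants$variants$key, out2$variants$variants$key)
  empty <- vt_subset(sim$vt, integer(0))
  expect_identical(n_variants(transmission_filter(empty, sim$ped)$variants),
                   0L)
})

test_that("tightening rule flags yields a subset of the default output", {
  cfg <- sim_config(seed = 13L, n_planted_segregating = 15L,
                    n_background_variants = 60L)
  sim <- simulate_families(cfg)
  base <- transmission_filter(sim$vt, sim$ped)$variants$variants$key
  for (rule in list(
    transmission_rule(exclude_if_unaffected_carrier = TRUE),
    transmission_rule(min_families_passing = 2L))) {
    tight <- transmission_filter(sim$vt, sim$ped, rule)$variants$variants$key
    expect_true(all(tight %in% base))
  }
})

test_that("a universally carried variant passes unless exclusion is on", {
  ped <- default_pedigree()
  geno <- matrix(1L, 1L, nrow(ped),
                 dimnames = list(NULL, ped$individual_id))
  vt <- variant_table(data.frame(chrom = "chr1", pos = 1000L, ref = "A",
                                 alt = "G"), geno)
  expect_identical(n_variants(transmission_filter(vt, ped)$variants), 1L)
  strict <- transmission_rule(exclude_if_unaffected_carrier = TRUE)
  expect_identical(n_variants(transmission_filter(vt, ped,
                                                  strict)$variants), 0L)
})

test_that("the gene-set funnel restricts to the intersection and reports counts", {
  cfg <- sim_config(seed = 31L, n_planted_segregating = 12L,
                    n_background_variants = 30L)
  sim <- simulate_families(cfg)
  keys <- sim$truth$key[sim$truth$planted]
  gene_map <- setNames(rep(c("A", "B", "C", "D"), 3L), keys)
  gwas <- gene_set("gwas", c("A", "B", "X"))
  de <- gene_set("de", c("B", "C", "Y"))
  fun <- variant_funnel(sim$vt, sim$ped, transmission_rule(), gwas, de,
                        gene_map)
  # only gene B is in both sets -> its 3 planted variants survive
  expect_identical(unname(fun$counts["post_geneset_variants"]), 3L)
  expect_identical(fun$genes, "B")
  expect_identical(unname(fun$counts["post_transmission"]), 12L)
  # empty intersection -> zero variants
  fun0 <- variant_funnel(sim$vt, sim$ped, transmission_rule(), gwas,
                         gene_set("d", "Z"), gene_map)
  expect_identical(unname(fun0$counts["post_geneset_variants"]), 0L)
  # removing the transmission stage never decreases the output count
  lax <- transmission_rule(require_all_affected_carriers = FALSE,
                           require_parent_child_transmission = FALSE)
  fun_lax <- variant_funnel(sim$vt, sim$ped, lax, gwas, de, gene_map)
  expect_gte(fun_lax$counts[["post_geneset_variants"]],
             fun$counts[["post_geneset_variants"]])
})
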