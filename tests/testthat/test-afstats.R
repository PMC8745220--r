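test_that("equal proportions give z = 0, p = 1; extremes are detected", {
  res <- two_proportion_z(5, 50, 10, 100)
  expect_equal(res$z, 0)
  expect_equal(res$p_two_sided, 1)
  big <- two_proportion_z(0, 10, 10, 10)
  expect_gt(abs(big$z), 3.8)
  expect_lt(big$p_two_sided, 1e-4)
  degen <- two_proportion_z(0, 100, 0, 50)
  expect_true(degen$degenerate)
  expect_equal(degen$p_two_sided, 1)
  expect_error(two_proportion_z(1, 0, 1, 10),
               class = "varfunnel_validation_error")
  expect_error(two_proportion_z(11, 10, 1, 10),
               class = "varfunnel_validation_error")
})

test_that("z^2 equals the Pearson chi-square without continuity correction", {
  set.seed(101)
  checked <- 0L
  while (checked < 1000L) {
    n1 <- sample(20:3000, 1L)
    n2 <- sample(20:3000, 1L)
    p <- runif(1L, 0.01, 0.99)
    x1 <- rbinom(1L, n1, p)
    x2 <- rbinom(1L, n2, p)
    if ((x1 + x2) == 0L || (x1 + x2) == (n1 + n2)) next
    tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
    if (any(colSums(tab) == 0L)) next
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    z <- two_proportion_z(x1, n1, x2, n2)
    expect_equal(z$z^2, unname(chi$statistic), tolerance = 1e-10)
    expect_equal(z$p_two_sided, chi$p.value, tolerance = 1e-10)
    checked <- checked + 1L
  }
})

test_that("the z-test is antisymmetric in its two samples", {
  set.seed(55)
  for (rep in 1:50) {
    n1 <- sample(50:500, 1L)
    n2 <- sample(50:500, 1L)
    x1 <- sample.int(n1, 1L)
    x2 <- sample.int(n2, 1L)
    a <- two_proportion_z(x1, n1, x2, n2)
    b <- two_proportion_z(x2, n2, x1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  }
})

test_that("Bonferroni thresholds and significance tiers follow the printed scheme", {
  expect_equal(bonferroni_threshold(0.05, 25), 0.002)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 50), 0.001)
  t <- 0.002
  expect_identical(af_tier(0.0001, t), "significant")
  expect_identical(af_tier(0.0093, t), "borderline")
  expect_identical(af_tier(0.0067, t), "borderline")
  expect_identical(af_tier(0.0287, t), "nominal")
  expect_identical(af_tier(0.2, t), "ns")
  # boundary: p exactly at the threshold is borderline (strict <)
  expect_identical(af_tier(t, t), "borderline")
})

test_that("test families use the distinct-variant multiplicity convention", {
  cfg <- sim_config(seed = 41L, n_assoc_msgwas = 1L, n_assoc_partner = 2L)
  sim <- simulate_frequencies(cfg)
  comparisons <- list(c("affected", "control_tsi"),
                      c("affected", "control_nfe"))
  res <- run_af_tests(unique(sim$truth$variant), sim$pf, comparisons)
  expect_identical(attr(res, "m"), 25L)
  expect_equal(attr(res, "threshold"), 0.002)
  expect_identical(nrow(res), 50L)
  # missing population rows yield not_evaluable, empty input an empty frame
  res2 <- run_af_tests("chr1:1:A:G", sim$pf, comparisons)
  expect_identical(unique(res2$tier), "not_evaluable")
  expect_identical(nrow(run_af_tests(character(), sim$pf, comparisons)), 0L)
})

test_that("planted frequency differences are exactly the significant calls", {
  cfg <- sim_config(seed = 41L, n_assoc_msgwas = 1L, n_assoc_partner = 2L)
  sim <- simulate_frequencies(cfg)
  res <- run_af_tests(unique(sim$truth$variant), sim$pf,
                      list(c("affected", "control_nfe")))
  hits <- unique(res$key[res$evaluable &
                           res$p_two_sided < attr(res, "threshold")])
  expect_setequal(hits, sim$truth$variant[sim$truth$assoc])
})
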